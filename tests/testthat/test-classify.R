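mkProfile <- function(v) {
  CNAProfile(v, chromosome = rep("chr1", nrow(v)), start = seq_len(nrow(v)))
}

test_that("burden is the mean squared profile and permutation-invariant", {
  v <- matrix(c(0, 0, 1, -1, 2, 2), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  b <- cnaBurden(mkProfile(v))
  expect_equal(unname(b), c(0, 1, 4))
  perm <- v[c(2, 1), ]
  expect_equal(cnaBurden(perm), b)
})

test_that("reference building selects ceil(fraction * n) top-burden cells", {
  set.seed(2)
  v <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:20)))
  prof <- mkProfile(v)
  refs <- buildReferenceProfiles(prof, colnames(v), colnames(v)[1:5],
                                 classifierParams(topFraction = 0.05))
  expect_length(refs$topCells, 1)           # ceil(0.05 * 20) = 1
  expect_identical(refs$topCells, names(which.max(cnaBurden(prof))))
  all10 <- buildReferenceProfiles(prof, colnames(v)[1:10], colnames(v)[1:5],
                                  classifierParams(topFraction = 1))
  expect_equal(all10$malignantRef, rowMeans(v[, 1:10]))
  expect_equal(all10$normalRef, rowMeans(v[, 1:5]))
  expect_error(buildReferenceProfiles(prof, character(), colnames(v)),
               "empty")
})

test_that("burden ties resolve by cell id, making references deterministic", {
  v <- matrix(c(1, -1, -1, 1, 1, 1), 2, 3,
              dimnames = list(c("g1", "g2"), c("cB", "cA", "cC")))
  prof <- mkProfile(v)
  refs <- buildReferenceProfiles(prof, colnames(v), colnames(v),
                                 classifierParams(topFraction = 1 / 3))
  expect_identical(refs$topCells, "cA")
})

test_that("dual correlation matches hand Pearson and handles edge cases", {
  v <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "cell"))
  prof <- mkProfile(v)
  res <- dualCorrelation(prof, malignantRef = c(1, 2, 4),
                         normalRef = c(3, 2, 1))
  expect_equal(res$r_malignant, 0.98198, tolerance = 1e-5)
  expect_equal(res$r_normal, -1)
  res2 <- dualCorrelation(prof, malignantRef = c(1, 2, 3),
                          normalRef = -c(1, 2, 3))
  expect_equal(res2$r_malignant, 1)
  expect_equal(res2$r_normal, -1)
  expect_error(dualCorrelation(prof, c(1, 1, 1), c(1, 2, 3)), "constant")
  flat <- mkProfile(matrix(0, 3, 2, dimnames = list(paste0("g", 1:3),
                                                    c("a", "b"))))
  expect_warning(res3 <- dualCorrelation(flat, c(1, 2, 3), c(3, 2, 1)),
                 "constant profile")
  expect_equal(res3$r_malignant, c(0, 0))
})

test_that("the median rule calls the documented toy table", {
  corr <- data.frame(cell_id = paste0("c", 1:4),
                     r_malignant = c(0.9, 0.8, 0.1, 0.0),
                     r_normal = c(0.0, 0.1, 0.8, 0.9))
  calls <- classifyCells(corr, classifierParams(rule = "median"))
  expect_identical(calls$call, c("malignant", "malignant", "normal",
                                 "normal"))
  # identical cells: nothing strictly exceeds the median
  same <- data.frame(cell_id = c("a", "b"), r_malignant = c(0.5, 0.5),
                     r_normal = c(0.2, 0.2))
  expect_true(all(classifyCells(same)$call == "normal"))
  expect_error(classifyCells(same[1, , drop = FALSE]), "2 cells")
})

test_that("cells failing exactly one condition are flagged ambiguous", {
  # medians: r_malignant 0.475, r_normal 0.55; c3 passes only r_malignant
  corr <- data.frame(cell_id = paste0("c", 1:4),
                     r_malignant = c(0.9, 0.1, 0.85, 0.0),
                     r_normal = c(0.0, 0.6, 0.9, 0.5))
  calls <- classifyCells(corr, classifierParams(flagAmbiguous = TRUE))
  expect_identical(calls$call[1], "malignant")   # passes both
  expect_identical(calls$call[3], "ambiguous")   # passes r_mal only
  off <- classifyCells(corr, classifierParams(flagAmbiguous = FALSE))
  expect_identical(off$call[3], "normal")
})

test_that("the mean_sd rule thresholds at mean + k sd / mean - k sd", {
  corr <- data.frame(cell_id = paste0("c", 1:5),
                     r_malignant = c(0.95, 0.1, 0.2, 0.15, 0.1),
                     r_normal = c(-0.9, 0.5, 0.6, 0.55, 0.5))
  p <- classifierParams(rule = "mean_sd", sdMultiplier = 1,
                        flagAmbiguous = FALSE)
  calls <- classifyCells(corr, p)
  cutMal <- mean(corr$r_malignant) + sd(corr$r_malignant)
  cutNorm <- mean(corr$r_normal) - sd(corr$r_normal)
  expect_identical(calls$call,
                   ifelse(corr$r_malignant > cutMal &
                          corr$r_normal < cutNorm, "malignant", "normal"))
  expect_identical(calls$call[1], "malignant")
})

test_that("classification is invariant to cell ordering", {
  set.seed(8)
  corr <- data.frame(cell_id = sprintf("c%02d", 1:30),
                     r_malignant = runif(30, -1, 1),
                     r_normal = runif(30, -1, 1))
  a <- classifyCells(corr)
  perm <- sample(30)
  b <- classifyCells(corr[perm, ])
  expect_identical(a$call[match(b$cell_id, a$cell_id)], b$call)
})

test_that("the full chain recovers planted malignant cells", {
  calls <- classifierFixture()$calls
  ss <- sensSpec(calls)
  expect_gte(ss["sensitivity"], 0.90)
  expect_gte(ss["specificity"], 0.90)
})

test_that("sensitivity does not decrease as the planted dosage grows", {
  sens <- sapply(c(1.2, 1.5, 1.8), function(mult) {
    vapply(1:5, function(s) {
      cfg <- simConfig(
        states = list(t = list(nReplicates = 1L, cellsPerReplicate = 900L,
          proportions = c(epithelial = 0.5, fibroblast = 0.3,
                          immune = 0.2))),
        malignantFraction = c(t = 0.4),
        cnaSegments = data.frame(chromosome = c("chr1", "chr2"),
                                 startGene = 1L, endGene = 200L,
                                 multiplier = c(mult, 1 / mult)),
        nGenes = 2000L, dyingCellFraction = 0, seed = 300L + s)
      sensSpec(runClassifierChain(simulateExperiment(cfg)))["sensitivity"]
    }, numeric(1))
  })
  med <- apply(sens, 2, median)
  expect_true(all(diff(med) >= 0))
})

test_that("per-sample mode classifies within each sample", {
  cfg <- simConfig(
    states = list(t = list(nReplicates = 2L, cellsPerReplicate = 700L,
      proportions = c(epithelial = 0.5, fibroblast = 0.3, immune = 0.2))),
    malignantFraction = c(t = 0.4), dyingCellFraction = 0, seed = 77L)
  sce <- simulateExperiment(cfg)
  truth <- simTruth(sce)
  norm <- logNormalize(sce)
  ref <- truth$cell_id[truth$cell_type != "epithelial"]
  prof <- inferCNA(norm, params = cnaParams(referenceCells = ref))
  epi <- truth$cell_id[truth$cell_type == "epithelial"]
  nrm <- truth$cell_id[truth$cell_type == "epithelial" &
                         !truth$is_malignant]
  sampleIds <- setNames(truth$sample_id, truth$cell_id)
  calls <- callMalignantCells(prof, epi, nrm, sampleIds = sampleIds)
  expect_setequal(calls$cell_id, epi)
  calls$truth_malignant <- truth$is_malignant[match(calls$cell_id,
                                                    truth$cell_id)]
  ss <- sensSpec(calls)
  expect_gte(ss["sensitivity"], 0.85)
  expect_gte(ss["specificity"], 0.85)
})
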