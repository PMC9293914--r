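toyCounts <- function() {
  # 5 genes x 4 cells; g5 detected in only 2 cells
  m <- matrix(c(
    4, 2, 3, 1,
    5, 1, 2, 2,
    0, 3, 1, 4,
    2, 2, 2, 2,
    1, 0, 3, 0), 5, 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  m
}

test_that("gene-level QC drops genes detected in too few cells", {
  res <- filterQC(toyCounts(), qcThresholds(minCellsPerGene = 3,
                                            minGenesPerCell = 0,
                                            maxMitoPercent = 100))
  expect_false("g5" %in% rownames(res$counts))
  expect_setequal(rownames(res$counts), c("g1", "g2", "g3", "g4"))
  expect_identical(res$report$genesRemovedLowCells, "g5")
})

test_that("all-zero thresholds leave the matrix unchanged", {
  m <- toyCounts()
  res <- filterQC(m, qcThresholds(0, 0, 100))
  expect_equal(as.matrix(res$counts), m)
})

test_that("high-mito cells are removed before the gene filter and logged", {
  m <- toyCounts()
  rownames(m)[5] <- "mt-1"
  m["mt-1", "c3"] <- 200   # c3 is ~95% mitochondrial
  res <- filterQC(m, qcThresholds(minCellsPerGene = 0, minGenesPerCell = 0,
                                  maxMitoPercent = 10, mitoGenes = "mt-1"))
  expect_false("c3" %in% colnames(res$counts))
  expect_identical(res$report$cellsRemovedHighMito, "c3")
  expect_error(
    filterQC(m, qcThresholds(mitoGenes = "absent_gene")), "absent")
})

test_that("QC on the standard fixture is idempotent and errors when
           everything dies", {
  sce <- simulateExperiment(simConfig(seed = 21L))
  mito <- rownames(sce)[rowData(sce)$is_mito]
  thr <- qcThresholds(minCellsPerGene = 3, minGenesPerCell = 200,
                      maxMitoPercent = 10, mitoGenes = mito)
  once <- filterQC(sce, thr)
  expect_gt(metadata(once)$qcReport$nCellsRemoved, 0)
  thr2 <- qcThresholds(3, 200, 10,
                       mitoGenes = intersect(mito, rownames(once)))
  twice <- filterQC(once, thr2)
  expect_identical(dim(twice), dim(once))
  expect_error(filterQC(sce, qcThresholds(minGenesPerCell = 1e6)),
               "every cell")
})

test_that("log-normalization follows the stated formula", {
  m <- matrix(c(10, 90, 0, 100), 2, 2,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- logNormalize(m, scaleFactor = 1e4)
  expect_equal(norm["g1", "c1"], log(1 + 10 / 100 * 1e4))  # ln(1001)
  expect_equal(norm["g1", "c1"], 6.908755, tolerance = 1e-6)
  expect_equal(norm["g1", "c2"], 0)   # zeros stay zero
  # doubling all counts of a cell changes nothing
  m2 <- m; m2[, "c1"] <- m2[, "c1"] * 2
  expect_equal(logNormalize(m2, 1e4)[, "c1"], norm[, "c1"])
  # zero-total cell is an error naming the cell
  m3 <- m; m3[, "c2"] <- 0
  expect_error(logNormalize(m3), "c2")
})

test_that("sparse log-normalization preserves the zero pattern", {
  sce <- simulateExperiment(simConfig(nGenes = 100L,
    states = list(s = list(nReplicates = 1L, cellsPerReplicate = 50L,
      proportions = c(epithelial = 1, fibroblast = 0, immune = 0))),
    malignantFraction = c(s = 0), seed = 13L))
  counts <- assay(sce, "counts")
  norm <- logNormalize(counts)
  expect_s4_class(norm, "sparseMatrix")
  expect_identical(as.matrix(norm) == 0, as.matrix(counts) == 0)
  expect_equal(as.matrix(norm), as.matrix(logNormalize(as.matrix(counts))))
})

test_that("gene scaling gives zero-mean unit-variance rows with clipping", {
  m <- matrix(c(0, 2, 5, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  z <- scaleGenes(m, cap = 10)
  # sample SD of (0, 2) is sqrt(2): z = (+-1)/sqrt(2)
  expect_equal(z["g1", ], c(c1 = -0.70711, c2 = 0.70711), tolerance = 1e-5)
  expect_equal(z["g2", ], c(c1 = 0, c2 = 0))  # zero variance -> zeros
  zc <- scaleGenes(matrix(c(rep(0, 9), 100), 1, 10,
                          dimnames = list("g", paste0("c", 1:10))), cap = 1)
  expect_true(all(abs(zc) <= 1))
})

test_that("scaled rows have mean within numerical zero before clipping", {
  sce <- standardFixture()
  z <- assay(sce, "scaled")
  unclipped <- rowSums(abs(z) == 10) == 0
  expect_true(all(abs(rowMeans(z[unclipped, ])) < 1e-8))
})

test_that("variable-gene selection recovers a planted variable program", {
  ids <- sprintf("G%05d", 1:2000)
  recovered <- vapply(c(3L, 7L), function(s) {
    cfg <- simConfig(
      states = list(s = list(nReplicates = 1L, cellsPerReplicate = 2000L,
        proportions = c(epithelial = 1, fibroblast = 0, immune = 0))),
      malignantFraction = c(s = 0.3), cnaSegments = noSegments(),
      signaturePrograms = list(prog = list(genes = ids[901:1000],
        target = "malignant", fold = 8)),
      dyingCellFraction = 0, seed = s)
    sce <- simulateExperiment(cfg)
    sum(ids[901:1000] %in% selectHVG(assay(sce, "counts"), 200))
  }, numeric(1))
  expect_true(all(recovered >= 90))
})

test_that("variable-gene selection is total, deterministic and
           order-invariant", {
  sce <- simulateExperiment(simConfig(nGenes = 150L,
    states = list(s = list(nReplicates = 1L, cellsPerReplicate = 120L,
      proportions = c(epithelial = 0.5, fibroblast = 0.3, immune = 0.2))),
    malignantFraction = c(s = 0.3), seed = 6L))
  counts <- as.matrix(assay(sce, "counts"))
  expect_setequal(selectHVG(counts, nrow(counts)), rownames(counts))
  expect_error(selectHVG(counts, nrow(counts) + 1), "exceeds")
  perm <- sample(ncol(counts))
  expect_identical(selectHVG(counts, 30), selectHVG(counts[, perm], 30))
  # duplicated gene rows tie and resolve by identifier
  dup <- rbind(counts, counts["G00001", , drop = FALSE])
  rownames(dup)[nrow(dup)] <- "G00001b"
  hv <- selectHVG(dup, nrow(dup))
  expect_equal(which(hv == "G00001b") - which(hv == "G00001"), 1)
})

test_that("marker argmax typing matches hand scores and simulator truth", {
  scaled <- matrix(c(2, 2, -1, -1,
                     -1, -1, 2, 2), 4, 2,
                   dimnames = list(c("e1", "e2", "f1", "f2"),
                                   c("cellA", "cellB")))
  sigs <- list(geneSignature("epithelial", c("e1", "e2")),
               geneSignature("fibroblast", c("f1", "f2")))
  res <- assignCellTypes(scaled, sigs)
  expect_identical(res$cell_type, c("epithelial", "fibroblast"))
  expect_equal(res$epithelial, c(2, -1))

  single <- assignCellTypes(scaled, sigs[1])
  expect_true(all(single$cell_type == "epithelial"))

  expect_error(assignCellTypes(scaled, list(geneSignature("x", "nope"))),
               "'x'")

  sce <- standardFixture()
  truth <- simTruth(sce)
  progs <- metadata(sce)$config@signaturePrograms
  markers <- lapply(c("epithelial", "fibroblast", "immune"), function(t)
    geneSignature(t, progs[[paste0(t, "_markers")]]$genes))
  res <- assignCellTypes(assay(sce, "scaled"), markers)
  expect_gte(mean(res$cell_type == truth$cell_type), 0.95)
})
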