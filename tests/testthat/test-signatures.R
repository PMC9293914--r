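test_that("signature scores reduce to the documented identities", {
  set.seed(1)
  scaled <- matrix(rnorm(30), 5, 6,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  one <- scoreSignature(scaled, geneSignature("solo", "g3"))
  expect_equal(one$score, unname(scaled["g3", ]))
  all <- scoreSignature(scaled, geneSignature("all", rownames(scaled)))
  expect_equal(all$score, unname(colMeans(scaled)))
  two <- scoreSignature(matrix(c(1, -0.5), 2, 1,
                               dimnames = list(c("a", "b"), "c1")),
                        geneSignature("pair", c("a", "b")))
  expect_equal(two$score, 0.25)
  # missing genes are dropped and reported; zero overlap errors
  part <- scoreSignature(scaled, geneSignature("p", c("g1", "nope")))
  expect_equal(part$n_genes_used[1], 1)
  expect_identical(attr(part, "missing_genes"), "nope")
  expect_error(scoreSignature(scaled, geneSignature("none", "zzz")), "none")
})

test_that("signature scoring is linear in the matrix", {
  set.seed(2)
  a <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8),
                                               paste0("c", 1:5)))
  b <- matrix(rnorm(40), 8, 5, dimnames = dimnames(a))
  sig <- geneSignature("s", c("g2", "g5", "g7"))
  expect_equal(scoreSignature(a + b, sig)$score,
               scoreSignature(a, sig)$score + scoreSignature(b, sig)$score)
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  # canonical extreme split: {1,2,3,4} vs {5,6,7,8} -> p = 2/70
  m <- matrix(c(1:8), 1, 8,
              dimnames = list("g", paste0("c", 1:8)))
  de <- wilcoxonDE(log1p(m), paste0("c", 1:4), paste0("c", 5:8),
                   logfcThreshold = 0, minPct = 0)
  expect_equal(de$p_value, 0.028571, tolerance = 1e-4)  # 2/70
  expect_equal(de$p_value, bruteRankSumP(1:4, 5:8), tolerance = 1e-9)

  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- sample(1000, n1 + n2)   # tie-free
    g1 <- sprintf("a%d", seq_len(n1)); g2 <- sprintf("b%d", seq_len(n2))
    m <- matrix(vals, 1, dimnames = list("g", c(g1, g2)))
    de <- wilcoxonDE(log1p(m), g1, g2, logfcThreshold = 0, minPct = 0)
    expect_equal(de$p_value, bruteRankSumP(vals[seq_len(n1)],
                                           vals[-seq_len(n1)]),
                 tolerance = 1e-9)
  }
})

test_that("the large-sample approximation agrees with wilcox.test", {
  set.seed(12)
  n1 <- 40; n2 <- 35
  vals <- c(rnbinom(n1, mu = 3, size = 2), rnbinom(n2, mu = 5, size = 2))
  g1 <- sprintf("a%d", 1:n1); g2 <- sprintf("b%d", 1:n2)
  m <- matrix(vals, 1, dimnames = list("g", c(g1, g2)))
  de <- wilcoxonDE(log1p(m), g1, g2, logfcThreshold = 0, minPct = 0)
  ref <- suppressWarnings(
    wilcox.test(vals[1:n1], vals[-(1:n1)], correct = TRUE))$p.value
  expect_equal(de$p_value, ref, tolerance = 1e-9)
})

test_that("DE prefilters by fold change and detection, reports both
           fractions, and nulls stay null", {
  set.seed(44)
  n <- 60
  counts <- matrix(rnbinom(100 * 2 * n, mu = 2, size = 2), 100,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   sprintf("c%03d", 1:(2 * n))))
  counts["g001", 1:n] <- counts["g001", 1:n] + 20   # strong planted shift
  norm <- logNormalize(counts)
  g1 <- colnames(counts)[1:n]; g2 <- colnames(counts)[-(1:n)]
  de <- wilcoxonDE(norm, g1, g2)
  expect_identical(de$gene[1], "g001")
  expect_lt(de$p_adjusted[1], 1e-6)
  expect_true(all(abs(de$log_fc) >= 0.25))
  expect_true(all(pmax(de$pct_group1, de$pct_group2) >= 0.1))
  expect_true(all(de$p_adjusted >= de$p_value))
  # relabeled null: no discoveries beyond the false-positive rate
  perm <- sample(colnames(norm))
  deNull <- wilcoxonDE(norm, perm[1:n], perm[(n + 1):(2 * n)],
                       logfcThreshold = 0)
  expect_lt(mean(deNull$p_adjusted < 0.05), 0.05)
  expect_error(wilcoxonDE(norm, g1, c(g1[1], g2)), "overlap")
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(1:1000, 1))
    expect_equal(p.adjust(p, "BH"), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("top markers rank by adjusted p then fold change with id ties", {
  res <- data.frame(
    gene = c("gB", "gA", "gC", "gD", "gE"),
    log_fc = c(1, 1, 2, -3, 0.5),
    p_value = c(0.01, 0.01, 0.02, 0.001, 0.04),
    p_adjusted = c(0.02, 0.02, 0.03, 0.005, 0.05))
  expect_identical(rankTopMarkers(res, 3), c("gA", "gB", "gC"))
  expect_identical(rankTopMarkers(res, 100), c("gA", "gB", "gC", "gE"))
})

test_that("conserved markers require every condition to agree", {
  set.seed(66)
  n <- 40
  mk <- function(shiftA, shiftB, shiftC) {
    counts <- matrix(rnbinom(50 * 6 * n, mu = 3, size = 2), 50,
                     dimnames = list(sprintf("g%02d", 1:50),
                                     sprintf("c%03d", 1:(6 * n))))
    # conditions A, B, C each hold one target + one background block
    counts["g01", 1:n] <- counts["g01", 1:n] + shiftA
    counts["g01", (2 * n + 1):(3 * n)] <-
      counts["g01", (2 * n + 1):(3 * n)] + shiftB
    counts["g01", (4 * n + 1):(5 * n)] <-
      counts["g01", (4 * n + 1):(5 * n)] + shiftC
    counts
  }
  cells <- sprintf("c%03d", 1:(6 * n))
  grp <- cells[c(1:n, (2 * n + 1):(3 * n), (4 * n + 1):(5 * n))]
  cond <- setNames(rep(c("A", "A", "B", "B", "C", "C"), each = n), cells)
  # up in all three conditions -> qualifies
  allUp <- conservedMarkers(logNormalize(mk(25, 25, 25)), grp, cond)
  expect_true("g01" %in% allUp$gene)
  row <- allUp[allUp$gene == "g01", ]
  expect_gt(row$min_log_fc, 0.25)
  # up in only two conditions -> excluded
  twoUp <- conservedMarkers(logNormalize(mk(25, 25, 0)), grp, cond)
  expect_false("g01" %in% twoUp$gene)
  # a condition missing the group errors
  expect_error(conservedMarkers(logNormalize(mk(5, 5, 5)),
                                grp[1:(2 * n)], cond), "'C'")
})

test_that("conserved markers recover a program active in every state", {
  # epithelial-only states: the out-group shares the program genes'
  # baseline, so recovery isolates the conserved-marker machinery from
  # stromal marker-specificity effects
  ids <- sprintf("G%05d", 1:1000)
  progGenes <- ids[801:850]
  mk <- function() list(nReplicates = 1L, cellsPerReplicate = 600L,
    proportions = c(epithelial = 1, fibroblast = 0, immune = 0))
  cfg <- simConfig(nGenes = 1000L,
    states = list(prepuberty = mk(), dcis = mk(), tumor = mk()),
    malignantFraction = c(prepuberty = 0.4, dcis = 0.4, tumor = 0.4),
    signaturePrograms = list(prog = list(genes = progGenes,
                                         target = "malignant", fold = 6)),
    dyingCellFraction = 0, seed = 52L)
  sce <- logNormalize(simulateExperiment(cfg))
  truth <- simTruth(sce)
  cond <- setNames(truth$state, truth$cell_id)
  res <- conservedMarkers(assay(sce, "logcounts"),
                          truth$cell_id[truth$is_malignant], cond)
  expect_gte(mean(progGenes %in% res$gene), 0.9)
})

test_that("ortholog mapping honors the one-to-one policy", {
  tab <- data.frame(
    source_symbol = c("Krt8", "Krt18", "Multi", "Multi", "Shared1",
                      "Shared2"),
    target_symbol = c("KRT8", "KRT18", "M1", "M2", "SAME", "SAME"))
  sig <- geneSignature("epi", c("Krt8", "Krt18", "Multi", "Shared1",
                                "Absent"))
  mapped <- mapSignatureOrthologs(sig, tab)
  expect_setequal(sigGenes(mapped), c("KRT8", "KRT18"))
  expect_setequal(attr(mapped, "unmapped"),
                  c("Multi", "Shared1", "Absent"))
  loose <- mapSignatureOrthologs(sig, tab, policy = "any")
  expect_setequal(sigGenes(loose), c("KRT8", "KRT18", "M1", "M2", "SAME"))
  expect_error(mapSignatureOrthologs(geneSignature("x", "Absent"), tab),
               "mapped")
})

test_that("bulk preparation scales upper quartiles to the geometric mean", {
  # sample A upper quartile 40, sample B 10 -> target 20: A x0.5, B x2
  counts <- matrix(c(40, 40, 40, 8, 10, 10, 10, 2), 4, 2,
                   dimnames = list(paste0("g", 1:4), c("A", "B")))
  uqA <- quantile(counts[counts[, 1] > 0, 1], 0.75, names = FALSE)
  uqB <- quantile(counts[counts[, 2] > 0, 2], 0.75, names = FALSE)
  expect_equal(c(uqA, uqB), c(40, 10))
  prep <- bulkPrepare(counts)
  raw <- log2(1 + sweep(counts, 2, sqrt(uqA * uqB) / c(uqA, uqB), "*"))
  expect_equal(prep, raw - apply(raw, 1, median))
  # every gene row has median 0
  expect_true(all(apply(prep, 1, median) == 0))
  # identical samples normalize identically
  dup <- cbind(A = counts[, 1], B = counts[, 1])
  prep2 <- bulkPrepare(dup)
  expect_equal(prep2[, "A"], prep2[, "B"])
  expect_error(bulkPrepare(cbind(counts, Z = 0)), "degenerate")
})

test_that("group comparison reproduces the hand Welch t-test", {
  scores <- data.frame(unit_id = paste0("s", 1:6), signature = "sig",
                       score = c(1, 2, 3, 4, 5, 6))
  groups <- setNames(rep(c("lo", "hi"), each = 3), scores$unit_id)
  res <- compareGroups(scores, groups)
  expect_equal(abs(res$t), 3.674, tolerance = 1e-3)
  expect_equal(res$p_value, t.test(1:3, 4:6)$p.value)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(res$p_adjusted, res$p_value)   # single pair: BH is identity
  # identical groups: t = 0, p = 1
  same <- data.frame(unit_id = paste0("s", 1:4), signature = "sig",
                     score = c(1, 2, 1, 2))
  gsame <- setNames(rep(c("a", "b"), each = 2), same$unit_id)
  res2 <- compareGroups(same, gsame)
  expect_equal(res2$t, 0)
  expect_equal(res2$p_value, 1)
  expect_error(compareGroups(scores, setNames(c("a", rep("b", 5)),
                                              scores$unit_id)), "fewer")
})

test_that("planted program genes score highest in their target cells", {
  sce <- standardFixture()
  truth <- simTruth(sce)
  progGenes <- metadata(sce)$config@signaturePrograms$proliferation$genes
  scores <- scoreSignature(assay(sce, "scaled"),
                           geneSignature("proliferation", progGenes))
  inTarget <- truth$is_malignant[match(scores$unit_id, truth$cell_id)]
  wt <- wilcox.test(scores$score[inTarget], scores$score[!inTarget],
                    alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})
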