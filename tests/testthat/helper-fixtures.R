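# Shared synthetic fixtures, generated in code and cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, make) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- make()
  .fixtureCache[[key]]
}

# Empty segment table: the no-CNA null.
noSegments <- function() {
  data.frame(chromosome = character(), startGene = integer(),
             endGene = integer(), multiplier = numeric())
}

# Single-sample tumor config at the canonical classifier scale:
# 3,000 cells, 2,000 genes, half epithelial, 40% of epithelial malignant
# (20% of all cells), one 200-gene gain at 1.5x and one 200-gene loss at
# 0.5x.
classifierConfig <- function(seed = 11L, cells = 3000L) {
  simConfig(
    states = list(tumor = list(
      nReplicates = 1L, cellsPerReplicate = as.integer(cells),
      proportions = c(epithelial = 0.5, fibroblast = 0.3, immune = 0.2))),
    malignantFraction = c(tumor = 0.4),
    dyingCellFraction = 0, seed = seed)
}

# Matching null: no segments, no programs, same composition.
nullConfig <- function(seed, cells = 1200L, nGenes = 1000L) {
  simConfig(
    states = list(tumor = list(
      nReplicates = 1L, cellsPerReplicate = as.integer(cells),
      proportions = c(epithelial = 0.5, fibroblast = 0.3, immune = 0.2))),
    malignantFraction = c(tumor = 0.4),
    cnaSegments = noSegments(), signaturePrograms = list(),
    nGenes = as.integer(nGenes), dyingCellFraction = 0, seed = seed)
}

# Full CNA chain + dual-correlation classifier on a simulated experiment.
# Non-epithelial cells are the presumed-diploid centering reference,
# epithelial cells the candidates, truth normal epithelial cells the
# normal pole (the simulator's stand-in for marker-identified normals).
runClassifierChain <- function(sce, params = classifierParams()) {
  truth <- simTruth(sce)
  sce <- logNormalize(sce)
  ref <- truth$cell_id[truth$cell_type != "epithelial"]
  prof <- inferCNA(sce, params = cnaParams(referenceCells = ref))
  epi <- truth$cell_id[truth$cell_type == "epithelial"]
  nrm <- truth$cell_id[truth$cell_type == "epithelial" & !truth$is_malignant]
  calls <- callMalignantCells(prof, epi, nrm, params = params)
  calls$truth_malignant <- truth$is_malignant[match(calls$cell_id,
                                                    truth$cell_id)]
  calls
}

sensSpec <- function(calls) {
  called <- calls$call == "malignant"
  c(sensitivity = sum(called & calls$truth_malignant) /
      sum(calls$truth_malignant),
    specificity = mean(!called[!calls$truth_malignant]))
}

# Canonical multi-state experiment (package defaults), cached.
standardFixture <- function() {
  .cached("standard", function() {
    sce <- simulateExperiment(simConfig(seed = 42L))
    scaleGenes(logNormalize(sce))
  })
}

# Classifier-scale fixture, cached.
classifierFixture <- function() {
  .cached("classifier", function() {
    sce <- simulateExperiment(classifierConfig())
    list(sce = sce, calls = runClassifierChain(sce))
  })
}

# Brute-force chromosome-wise windowed mean: the O(G*W) smoothing oracle.
bruteSmooth <- function(x, chrom, window) {
  half <- (window - 1) %/% 2
  out <- x
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    for (i in seq_along(idx)) {
      lo <- max(1, i - half)
      hi <- min(length(idx), i + half)
      out[idx[i], ] <- colMeans(x[idx[lo:hi], , drop = FALSE])
    }
  }
  out
}

# Brute-force BH: sorted cumulative minimum of p * m / rank.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Exact two-sided rank-sum p by enumeration of all group-1 rank splits.
bruteRankSumP <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  U <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(vals), n1)
  Us <- apply(splits, 2, function(ix)
    sum(rank(vals)[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
}
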