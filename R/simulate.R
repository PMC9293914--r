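#' @include AllClasses.R AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the single-cell count simulator
#'
#' Describes a multi-sample scRNA-seq experiment over several disease
#' states: per-cell-type baseline expression (independent Gamma-distributed
#' mean profiles), disease states with replicate samples and cell-type
#' proportions, a malignant subset of epithelial cells carrying planted
#' arm-level CNA dosage segments, fold-effect signature programs targeted at
#' cell types or at the malignant subpopulation, lognormal library sizes,
#' negative-binomial counts with a shared dispersion, flagged mitochondrial
#' genes with a "dying cell" subpopulation, and an optional per-sample
#' multiplicative lognormal batch effect.
#'
#' @slot nGenes integer(1) total genes.
#' @slot genesPerChromosome named integer vector summing to \code{nGenes}.
#' @slot cellTypeProfiles named list; per cell type a list with Gamma
#'   \code{shape} and \code{scale} of the baseline mean profile.
#' @slot states named list; per disease state a list with
#'   \code{nReplicates}, \code{cellsPerReplicate} and \code{proportions}
#'   (a simplex over cell types).
#' @slot malignantFraction named numeric; per state, the fraction of
#'   epithelial cells that are malignant.
#' @slot epithelialType character(1), name of the epithelial cell type.
#' @slot cnaSegments data.frame with columns \code{chromosome},
#'   \code{startGene}, \code{endGene} (1-based within-chromosome gene
#'   indices) and \code{multiplier} (> 0) applied to malignant cells.
#' @slot signaturePrograms named list; per program a list with
#'   \code{genes}, \code{target} (a cell type or \code{"malignant"}) and
#'   \code{fold} (> 0).
#' @slot librarySizeMeanlog,librarySizeSdlog lognormal library-size
#'   parameters.
#' @slot nbDispersion numeric(1) > 0, shared NB size parameter.
#' @slot mitoGeneFraction numeric(1) in [0, 1), fraction of genes flagged
#'   mitochondrial (the trailing block of the last chromosome).
#' @slot dyingCellFraction numeric(1) in [0, 1], fraction of cells with
#'   boosted mitochondrial expression.
#' @slot mitoBoost numeric(1) >= 1, mitochondrial mean multiplier in dying
#'   cells.
#' @slot batchSigma numeric(1) >= 0, sd of the per-sample lognormal gene
#'   factor (0 disables the batch effect).
#' @slot seed integer(1) RNG seed; identical config + seed gives
#'   bit-identical output.
#'
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig",
  representation(
    nGenes             = "integer",
    genesPerChromosome = "integer",
    cellTypeProfiles   = "list",
    states             = "list",
    malignantFraction  = "numeric",
    epithelialType     = "character",
    cnaSegments        = "data.frame",
    signaturePrograms  = "list",
    librarySizeMeanlog = "numeric",
    librarySizeSdlog   = "numeric",
    nbDispersion       = "numeric",
    mitoGeneFraction   = "numeric",
    dyingCellFraction  = "numeric",
    mitoBoost          = "numeric",
    batchSigma         = "numeric",
    seed               = "integer"
  )
)

#' Gene identifiers of a simulated universe
#' @param config a [SimConfig-class].
#' @return character vector of gene ids, in genomic order.
#' @export
simGeneIds <- function(config) {
  sprintf("G%05d", seq_len(config@nGenes))
}

setValidity("SimConfig", function(object) {
  msg <- character()
  types <- names(object@cellTypeProfiles)
  if (sum(object@genesPerChromosome) != object@nGenes)
    msg <- c(msg, "'genesPerChromosome' must sum to 'nGenes'")
  if (is.null(names(object@genesPerChromosome)) ||
      anyDuplicated(names(object@genesPerChromosome)))
    msg <- c(msg, "'genesPerChromosome' must have unique chromosome names")
  if (is.null(types) || anyDuplicated(types))
    msg <- c(msg, "'cellTypeProfiles' must be a uniquely named list")
  for (t in types) {
    p <- object@cellTypeProfiles[[t]]
    if (!is.list(p) || !all(c("shape", "scale") %in% names(p)) ||
        p$shape <= 0 || p$scale <= 0)
      msg <- c(msg, sprintf("profile of '%s' needs positive shape and scale", t))
  }
  if (!object@epithelialType %in% types)
    msg <- c(msg, "'epithelialType' must be one of the cell types")
  if (is.null(names(object@states)) || anyDuplicated(names(object@states)))
    msg <- c(msg, "'states' must be a uniquely named list")
  for (s in names(object@states)) {
    st <- object@states[[s]]
    if (!all(c("nReplicates", "cellsPerReplicate", "proportions") %in%
             names(st))) {
      msg <- c(msg, sprintf(
        "state '%s' needs nReplicates, cellsPerReplicate and proportions", s))
      next
    }
    pr <- st$proportions
    if (!setequal(names(pr), types) || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-9)
      msg <- c(msg, sprintf(
        "proportions of state '%s' must be a simplex over the cell types", s))
    if (st$nReplicates < 1L || st$cellsPerReplicate < 1L)
      msg <- c(msg, sprintf("state '%s' needs >= 1 replicate and cell", s))
  }
  mf <- object@malignantFraction
  if (!setequal(names(mf), names(object@states)) || any(mf < 0 | mf > 1))
    msg <- c(msg, "'malignantFraction' must give a value in [0,1] per state")
  seg <- object@cnaSegments
  need <- c("chromosome", "startGene", "endGene", "multiplier")
  if (!all(need %in% colnames(seg))) {
    msg <- c(msg, paste("'cnaSegments' needs columns",
                        paste(need, collapse = ", ")))
  } else if (nrow(seg)) {
    bad <- !seg$chromosome %in% names(object@genesPerChromosome)
    if (any(bad)) msg <- c(msg, "segment on unknown chromosome")
    if (any(seg$multiplier <= 0))
      msg <- c(msg, "dosage multipliers must be > 0")
    for (i in which(!bad)) {
      gmax <- object@genesPerChromosome[[seg$chromosome[i]]]
      if (seg$startGene[i] < 1L || seg$endGene[i] > gmax ||
          seg$startGene[i] > seg$endGene[i])
        msg <- c(msg, sprintf("segment %d exceeds its chromosome", i))
    }
  }
  universe <- sprintf("G%05d", seq_len(object@nGenes))
  for (p in names(object@signaturePrograms)) {
    pg <- object@signaturePrograms[[p]]
    if (!all(c("genes", "target", "fold") %in% names(pg))) {
      msg <- c(msg, sprintf("program '%s' needs genes, target and fold", p))
      next
    }
    if (!all(pg$genes %in% universe))
      msg <- c(msg, sprintf("program '%s' uses genes outside the universe", p))
    if (!pg$target %in% c(types, "malignant"))
      msg <- c(msg, sprintf("program '%s' has unknown target '%s'", p,
                            pg$target))
    if (pg$fold <= 0)
      msg <- c(msg, sprintf("program '%s' needs a positive fold", p))
  }
  if (object@librarySizeSdlog < 0) msg <- c(msg, "'librarySizeSdlog' >= 0")
  if (object@nbDispersion <= 0) msg <- c(msg, "'nbDispersion' must be > 0")
  if (object@mitoGeneFraction < 0 || object@mitoGeneFraction >= 1)
    msg <- c(msg, "'mitoGeneFraction' must be in [0, 1)")
  if (object@dyingCellFraction < 0 || object@dyingCellFraction > 1)
    msg <- c(msg, "'dyingCellFraction' must be in [0, 1]")
  if (object@mitoBoost < 1) msg <- c(msg, "'mitoBoost' must be >= 1")
  if (object@batchSigma < 0) msg <- c(msg, "'batchSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulator configuration
#'
#' The defaults describe the canonical experiment the package is exercised
#' on: 2,000 genes over 10 chromosomes; epithelial, fibroblast and immune
#' cells; three disease states (prepuberty, DCIS, tumor) with two replicate
#' samples of 500 cells each; a whole-chromosome gain (1.5x on chr1) and
#' loss (0.5x on chr2) in malignant epithelial cells whose per-state
#' fraction rises along progression (0.02, 0.15, 0.60); a proliferation
#' program in malignant cells and one marker program per cell type; and a
#' mild per-sample batch effect.
#'
#' @param nGenes number of genes.
#' @param genesPerChromosome named integer vector of genes per chromosome
#'   (default: 10 equal chromosomes \code{chr1..chr10}).
#' @param cellTypeProfiles named list of Gamma \code{shape}/\code{scale}
#'   baseline descriptors, one per cell type.
#' @param states named list of disease states (see [SimConfig-class]).
#' @param malignantFraction named per-state fraction of epithelial cells
#'   that are malignant.
#' @param epithelialType which cell type is epithelial.
#' @param cnaSegments data.frame of planted dosage segments.
#' @param signaturePrograms named list of fold-effect programs.
#' @param librarySizeMeanlog,librarySizeSdlog lognormal library-size
#'   parameters (default meanlog log(5000), sdlog 0.35).
#' @param nbDispersion shared negative-binomial size parameter (default 2).
#' @param mitoGeneFraction fraction of genes flagged mitochondrial
#'   (default 0.05).
#' @param dyingCellFraction fraction of cells with boosted mitochondrial
#'   expression (default 0.02).
#' @param mitoBoost mitochondrial mean multiplier in dying cells
#'   (default 25).
#' @param batchSigma sd of the per-sample lognormal gene factor
#'   (default 0.1; 0 disables).
#' @param seed RNG seed.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      genesPerChromosome = NULL,
                      cellTypeProfiles = NULL,
                      states = NULL,
                      malignantFraction = NULL,
                      epithelialType = "epithelial",
                      cnaSegments = NULL,
                      signaturePrograms = NULL,
                      librarySizeMeanlog = log(5000),
                      librarySizeSdlog = 0.35,
                      nbDispersion = 2,
                      mitoGeneFraction = 0.05,
                      dyingCellFraction = 0.02,
                      mitoBoost = 25,
                      batchSigma = 0.1,
                      seed = 1L) {
  nGenes <- as.integer(nGenes)
  if (is.null(genesPerChromosome)) {
    nchrom <- 10L
    base <- nGenes %/% nchrom
    genesPerChromosome <- rep(base, nchrom)
    genesPerChromosome[nchrom] <- nGenes - base * (nchrom - 1L)
    names(genesPerChromosome) <- paste0("chr", seq_len(nchrom))
  }
  if (is.null(cellTypeProfiles)) {
    cellTypeProfiles <- list(
      epithelial = list(shape = 0.6, scale = 1),
      fibroblast = list(shape = 0.6, scale = 1),
      immune     = list(shape = 0.6, scale = 1))
  }
  types <- names(cellTypeProfiles)
  if (is.null(states)) {
    mk <- function(p) list(nReplicates = 2L, cellsPerReplicate = 500L,
                           proportions = p)
    states <- list(
      prepuberty = mk(c(epithelial = 0.45, fibroblast = 0.35, immune = 0.20)),
      dcis       = mk(c(epithelial = 0.50, fibroblast = 0.30, immune = 0.20)),
      tumor      = mk(c(epithelial = 0.60, fibroblast = 0.20, immune = 0.20)))
  }
  if (is.null(malignantFraction)) {
    defaults <- c(prepuberty = 0.02, dcis = 0.15, tumor = 0.60)
    malignantFraction <-
      if (setequal(names(states), names(defaults))) defaults
      else stats::setNames(rep(0.2, length(states)), names(states))
  }
  chromEnd <- cumsum(genesPerChromosome)
  chromStart <- chromEnd - genesPerChromosome + 1L
  if (is.null(cnaSegments)) {
    cnaSegments <- if (length(genesPerChromosome) >= 2L) {
      data.frame(
        chromosome = names(genesPerChromosome)[1:2],
        startGene  = c(1L, 1L),
        endGene    = as.integer(genesPerChromosome[1:2]),
        multiplier = c(1.5, 0.5))
    } else {
      data.frame(chromosome = names(genesPerChromosome)[1], startGene = 1L,
                 endGene = max(1L, genesPerChromosome[[1]] %/% 4L),
                 multiplier = 1.5)
    }
  }
  if (is.null(signaturePrograms)) {
    ids <- sprintf("G%05d", seq_len(nGenes))
    len <- max(1L, as.integer(round(nGenes * 0.025)))
    block <- function(at) ids[seq.int(at, length.out = len)]
    starts <- pmin(as.integer(round(nGenes * c(0.40, 0.50, 0.60, 0.70))) + 1L,
                   nGenes - len + 1L)
    signaturePrograms <- list(
      proliferation = list(genes = block(starts[1]), target = "malignant",
                           fold = 3),
      epithelial_markers = list(genes = block(starts[2]),
                                target = epithelialType, fold = 6))
    extra <- setdiff(types, epithelialType)
    for (i in seq_along(extra)) {
      if (i + 2L > length(starts)) break
      signaturePrograms[[paste0(extra[i], "_markers")]] <-
        list(genes = block(starts[i + 2L]), target = extra[i], fold = 6)
    }
  }
  new("SimConfig",
      nGenes             = nGenes,
      genesPerChromosome = stats::setNames(as.integer(genesPerChromosome),
                                           names(genesPerChromosome)),
      cellTypeProfiles   = cellTypeProfiles,
      states             = states,
      malignantFraction  = malignantFraction[names(states)],
      epithelialType     = epithelialType,
      cnaSegments        = cnaSegments,
      signaturePrograms  = signaturePrograms,
      librarySizeMeanlog = as.numeric(librarySizeMeanlog),
      librarySizeSdlog   = as.numeric(librarySizeSdlog),
      nbDispersion       = as.numeric(nbDispersion),
      mitoGeneFraction   = as.numeric(mitoGeneFraction),
      dyingCellFraction  = as.numeric(dyingCellFraction),
      mitoBoost          = as.numeric(mitoBoost),
      batchSigma         = as.numeric(batchSigma),
      seed               = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  nc <- sum(vapply(object@states,
                   function(s) s$nReplicates * s$cellsPerReplicate, 0))
  cat("SimConfig:", object@nGenes, "genes over",
      length(object@genesPerChromosome), "chromosomes;",
      length(object@states), "states;", nc, "cells total\n")
  cat("  cell types:", paste(names(object@cellTypeProfiles), collapse = ", "),
      "\n")
  cat("  CNA segments:", nrow(object@cnaSegments), "; programs:",
      length(object@signaturePrograms), "; seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## simulateExperiment
## ---------------------------------------------------------------------------

#' Simulate a multi-sample scRNA-seq experiment with planted truth
#'
#' Draws counts for every cell as NB(mean = librarySize * lambda_gene *
#' dosage * program * batch, size = nbDispersion), where the baseline
#' profile lambda of each cell type is an independent Gamma draw normalized
#' to sum to one, dosage applies the configured segment multipliers in
#' malignant epithelial cells, program applies fold effects to targeted
#' subpopulations, and batch is an optional per-sample lognormal gene
#' factor. Output is deterministic given the config seed.
#'
#' @param config a [SimConfig-class].
#' @return A \linkS4class{SingleCellExperiment} with a sparse
#'   \code{counts} assay; \code{rowRanges} carrying the genomic position of
#'   every gene plus \code{gene_id} and \code{is_mito}; \code{colData} truth
#'   columns \code{cell_id}, \code{sample_id}, \code{state},
#'   \code{replicate}, \code{cell_type}, \code{is_malignant},
#'   \code{is_dying}, \code{active_programs}; and \code{metadata} entries
#'   \code{config}, \code{typeMeans} (genes x types lambda matrix) and
#'   \code{dosage} (the per-gene malignant multiplier).
#' @examples
#' sce <- simulateExperiment(simConfig(seed = 7))
#' table(sce$state, sce$cell_type)
#' @importFrom stats rgamma rlnorm rnbinom rnorm runif setNames
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withr::with_seed(config@seed, .simulateExperiment(config))
}

.simulateExperiment <- function(config) {
  G <- config@nGenes
  geneIds <- simGeneIds(config)
  chrom <- rep(names(config@genesPerChromosome), config@genesPerChromosome)
  withinIdx <- unlist(lapply(config@genesPerChromosome, seq_len),
                      use.names = FALSE)
  start <- withinIdx * 1000L
  nMito <- as.integer(round(config@mitoGeneFraction * G))
  isMito <- seq_len(G) > G - nMito
  types <- names(config@cellTypeProfiles)

  ## baseline per-type mean profiles, normalized to sum 1
  lambda <- vapply(types, function(t) {
    p <- config@cellTypeProfiles[[t]]
    l <- rgamma(G, shape = p$shape, scale = p$scale)
    l / sum(l)
  }, numeric(G))
  rownames(lambda) <- geneIds

  ## malignant dosage per gene
  chromOffset <- cumsum(config@genesPerChromosome) -
    config@genesPerChromosome
  dosage <- rep(1, G)
  seg <- config@cnaSegments
  for (i in seq_len(nrow(seg))) {
    idx <- chromOffset[[seg$chromosome[i]]] + seg$startGene[i]:seg$endGene[i]
    dosage[idx] <- dosage[idx] * seg$multiplier[i]
  }

  progs <- config@signaturePrograms
  progMult <- lapply(progs, function(p) {
    v <- rep(1, G)
    v[match(p$genes, geneIds)] <- p$fold
    v
  })

  countsList <- list()
  cdList <- list()
  for (s in names(config@states)) {
    st <- config@states[[s]]
    for (r in seq_len(st$nReplicates)) {
      sampleId <- paste0(s, "_rep", r)
      nc <- st$cellsPerReplicate
      cellType <- sample(types, nc, replace = TRUE,
                         prob = st$proportions[types])
      isMal <- cellType == config@epithelialType &
        runif(nc) < config@malignantFraction[[s]]
      isDying <- runif(nc) < config@dyingCellFraction
      libsize <- rlnorm(nc, config@librarySizeMeanlog,
                        config@librarySizeSdlog)
      batch <- if (config@batchSigma > 0)
        exp(rnorm(G, 0, config@batchSigma)) else rep(1, G)

      M <- lambda[, match(cellType, types), drop = FALSE]
      M <- M * batch
      if (any(isMal)) M[, isMal] <- M[, isMal] * dosage
      active <- matrix(FALSE, nc, length(progs),
                       dimnames = list(NULL, names(progs)))
      for (p in names(progs)) {
        target <- progs[[p]]$target
        inTarget <- if (target == "malignant") isMal else cellType == target
        if (any(inTarget)) {
          M[, inTarget] <- M[, inTarget] * progMult[[p]]
          active[inTarget, p] <- TRUE
        }
      }
      if (any(isDying)) M[isMito, isDying] <- M[isMito, isDying] *
          config@mitoBoost
      M <- sweep(M, 2L, libsize, "*")
      cnt <- matrix(rnbinom(G * nc, mu = M, size = config@nbDispersion),
                    nrow = G)
      countsList[[sampleId]] <- cnt
      cdList[[sampleId]] <- S4Vectors::DataFrame(
        cell_id = sprintf("%s-c%04d", sampleId, seq_len(nc)),
        sample_id = sampleId, state = s, replicate = r,
        cell_type = cellType, is_malignant = isMal, is_dying = isDying,
        active_programs = vapply(seq_len(nc), function(i)
          paste(colnames(active)[active[i, ]], collapse = ","),
          character(1)))
    }
  }

  counts <- do.call(cbind, countsList)
  cd <- do.call(rbind, cdList)
  rownames(cd) <- cd$cell_id
  colnames(counts) <- cd$cell_id
  rownames(counts) <- geneIds
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  rr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = start, width = 1L),
    gene_id = geneIds, is_mito = isMito)
  names(rr) <- geneIds
  SingleCellExperiment(
    assays = list(counts = counts), rowRanges = rr, colData = cd,
    metadata = list(config = config, typeMeans = lambda, dosage = dosage))
}

#' Ground-truth table of a simulated experiment
#'
#' @param sce a \linkS4class{SingleCellExperiment} from
#'   [simulateExperiment()].
#' @return data.frame with one row per cell: \code{cell_id},
#'   \code{sample_id}, \code{state}, \code{replicate}, \code{cell_type},
#'   \code{is_malignant}, \code{is_dying}, \code{active_programs}.
#' @export
simTruth <- function(sce) {
  cols <- c("cell_id", "sample_id", "state", "replicate", "cell_type",
            "is_malignant", "is_dying", "active_programs")
  as.data.frame(colData(sce)[, cols, drop = FALSE])
}

#' Gene annotation of a simulated experiment
#'
#' @param sce a \linkS4class{SingleCellExperiment} from
#'   [simulateExperiment()].
#' @return data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{start}, \code{is_mito}, one row per gene.
#' @importFrom SummarizedExperiment rowRanges
#' @export
geneAnnotation <- function(sce) {
  rr <- rowRanges(sce)
  data.frame(
    gene_id = S4Vectors::mcols(rr)$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(rr)),
    start = GenomicRanges::start(rr),
    is_mito = S4Vectors::mcols(rr)$is_mito,
    row.names = names(rr), stringsAsFactors = FALSE)
}
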