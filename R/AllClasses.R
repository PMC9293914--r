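#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom SummarizedExperiment "assay<-"
NULL

## ---------------------------------------------------------------------------
## Parameter classes
## ---------------------------------------------------------------------------

#' Quality-control thresholds for cell and gene filtering
#'
#' Holds the filtering thresholds applied by [filterQC()]: genes must be
#' detected in at least \code{minCellsPerGene} cells, cells must express at
#' least \code{minGenesPerCell} genes, and cells whose mitochondrial counts
#' exceed \code{maxMitoPercent} percent of their total are removed as
#' presumed dying cells.
#'
#' @slot minCellsPerGene integer(1), minimum cells a gene must be detected in.
#' @slot minGenesPerCell integer(1), minimum detected genes per cell.
#' @slot maxMitoPercent numeric(1) in [0, 100], maximum mitochondrial percent.
#' @slot mitoGenes character, identifiers of mitochondrial genes.
#'
#' @seealso [qcThresholds()] for the user-facing constructor.
#' @export
setClass("QCThresholds",
  representation(
    minCellsPerGene = "integer",
    minGenesPerCell = "integer",
    maxMitoPercent  = "numeric",
    mitoGenes       = "character"
  )
)

setValidity("QCThresholds", function(object) {
  msg <- character()
  if (length(object@minCellsPerGene) != 1L || object@minCellsPerGene < 0L)
    msg <- c(msg, "'minCellsPerGene' must be a single non-negative integer")
  if (length(object@minGenesPerCell) != 1L || object@minGenesPerCell < 0L)
    msg <- c(msg, "'minGenesPerCell' must be a single non-negative integer")
  if (length(object@maxMitoPercent) != 1L ||
      object@maxMitoPercent < 0 || object@maxMitoPercent > 100)
    msg <- c(msg, "'maxMitoPercent' must be a single value in [0, 100]")
  if (anyDuplicated(object@mitoGenes))
    msg <- c(msg, "'mitoGenes' must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' Construct QC thresholds
#'
#' Defaults follow the conventional droplet scRNA-seq workflow: genes kept
#' when detected in at least 3 cells, cells kept with at least 200 detected
#' genes, and a mitochondrial ceiling of 10 percent (the upper end of the
#' commonly used 5--10 range).
#'
#' @param minCellsPerGene minimum number of cells a gene must be detected in.
#' @param minGenesPerCell minimum number of detected genes per cell.
#' @param maxMitoPercent maximum mitochondrial percent per cell, in [0, 100].
#' @param mitoGenes character vector of mitochondrial gene identifiers.
#' @return A [QCThresholds-class] object.
#' @examples
#' qcThresholds(minCellsPerGene = 3, minGenesPerCell = 200)
#' @export
qcThresholds <- function(minCellsPerGene = 3L, minGenesPerCell = 200L,
                         maxMitoPercent = 10, mitoGenes = character()) {
  new("QCThresholds",
      minCellsPerGene = as.integer(minCellsPerGene),
      minGenesPerCell = as.integer(minGenesPerCell),
      maxMitoPercent  = as.numeric(maxMitoPercent),
      mitoGenes       = as.character(mitoGenes))
}

#' Parameters of the CNA-profile computation
#'
#' Controls [inferCNA()]: genes with mean normalized expression below
#' \code{expressionCutoff} are removed, expression is centered on the mean of
#' \code{referenceCells} and clipped at \code{maxCenteredThreshold}, then
#' smoothed along each chromosome with an unweighted moving average of
#' \code{windowLength} genes, and finally each cell is recentered on its
#' median. Defaults are the standard settings of the reference-based
#' CNA-inference approach (cutoff 0.1, window 101, clip at 3).
#'
#' @slot expressionCutoff numeric(1) >= 0, mean-expression gene filter.
#' @slot windowLength odd integer(1) >= 1, smoothing window in genes.
#' @slot maxCenteredThreshold numeric(1) > 0, symmetric clipping bound.
#' @slot referenceCells character, presumed-diploid reference cell ids.
#' @slot centerStat either "mean" or "median", reference summary statistic.
#'
#' @seealso [cnaParams()]
#' @export
setClass("CNAParams",
  representation(
    expressionCutoff     = "numeric",
    windowLength         = "integer",
    maxCenteredThreshold = "numeric",
    referenceCells       = "character",
    centerStat           = "character"
  )
)

setValidity("CNAParams", function(object) {
  msg <- character()
  if (length(object@expressionCutoff) != 1L || object@expressionCutoff < 0)
    msg <- c(msg, "'expressionCutoff' must be a single non-negative value")
  if (length(object@windowLength) != 1L || object@windowLength < 1L ||
      object@windowLength %% 2L == 0L)
    msg <- c(msg, "'windowLength' must be a single odd integer >= 1")
  if (length(object@maxCenteredThreshold) != 1L ||
      object@maxCenteredThreshold <= 0)
    msg <- c(msg, "'maxCenteredThreshold' must be a single positive value")
  if (length(object@referenceCells) == 0L)
    msg <- c(msg, "'referenceCells' must name at least one cell")
  if (!object@centerStat %in% c("mean", "median"))
    msg <- c(msg, "'centerStat' must be \"mean\" or \"median\"")
  if (length(msg)) msg else TRUE
})

#' Construct CNA-inference parameters
#'
#' @param referenceCells character vector of presumed-diploid cell ids whose
#'   average expression defines the zero baseline.
#' @param expressionCutoff genes with mean normalized expression below this
#'   are dropped before centering (default 0.1).
#' @param windowLength odd number of genes in the chromosome-wise moving
#'   average (default 101).
#' @param maxCenteredThreshold symmetric bound at which reference-centered
#'   values are clipped before smoothing (default 3).
#' @param centerStat reference summary used for centering, \code{"mean"}
#'   (default) or \code{"median"}.
#' @return A [CNAParams-class] object.
#' @examples
#' cnaParams(referenceCells = c("cellA", "cellB"))
#' @export
cnaParams <- function(referenceCells, expressionCutoff = 0.1,
                      windowLength = 101L, maxCenteredThreshold = 3,
                      centerStat = c("mean", "median")) {
  new("CNAParams",
      expressionCutoff     = as.numeric(expressionCutoff),
      windowLength         = as.integer(windowLength),
      maxCenteredThreshold = as.numeric(maxCenteredThreshold),
      referenceCells       = as.character(referenceCells),
      centerStat           = match.arg(centerStat))
}

#' Parameters of the dual-correlation malignancy classifier
#'
#' The classifier ranks candidate cells by CNA burden, averages the top
#' \code{topFraction} into an aberrant reference profile, correlates every
#' cell with that profile and with the average profile of normal cells, and
#' calls a cell malignant when its aberrant correlation exceeds and its
#' normal correlation falls below the rule's cutoffs (medians by default,
#' mean +/- \code{sdMultiplier} standard deviations under \code{rule =
#' "mean_sd"}).
#'
#' @slot topFraction numeric(1) in (0, 1], fraction of highest-burden
#'   candidates averaged into the aberrant reference (default 0.05).
#' @slot rule either "median" or "mean_sd".
#' @slot sdMultiplier numeric(1) > 0, the k of mean +/- k sd (default 2).
#' @slot correlation either "pearson" or "spearman".
#' @slot flagAmbiguous logical(1); when TRUE, cells failing exactly one of
#'   the two conditions are labelled "ambiguous" instead of "normal".
#'
#' @seealso [classifierParams()]
#' @export
setClass("ClassifierParams",
  representation(
    topFraction   = "numeric",
    rule          = "character",
    sdMultiplier  = "numeric",
    correlation   = "character",
    flagAmbiguous = "logical"
  )
)

setValidity("ClassifierParams", function(object) {
  msg <- character()
  if (length(object@topFraction) != 1L || object@topFraction <= 0 ||
      object@topFraction > 1)
    msg <- c(msg, "'topFraction' must be a single value in (0, 1]")
  if (!object@rule %in% c("median", "mean_sd"))
    msg <- c(msg, "'rule' must be \"median\" or \"mean_sd\"")
  if (length(object@sdMultiplier) != 1L || object@sdMultiplier <= 0)
    msg <- c(msg, "'sdMultiplier' must be a single positive value")
  if (!object@correlation %in% c("pearson", "spearman"))
    msg <- c(msg, "'correlation' must be \"pearson\" or \"spearman\"")
  if (length(object@flagAmbiguous) != 1L || is.na(object@flagAmbiguous))
    msg <- c(msg, "'flagAmbiguous' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct classifier parameters
#'
#' @param topFraction fraction of highest-burden candidate cells averaged
#'   into the aberrant reference profile (default 0.05, i.e. the top 5%).
#' @param rule cutoff rule: \code{"median"} (default) thresholds both
#'   correlations at their medians over the classified set; \code{"mean_sd"}
#'   uses mean(r_malignant) + k sd and mean(r_normal) - k sd.
#' @param sdMultiplier the k of the \code{"mean_sd"} rule (default 2).
#' @param correlation correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param flagAmbiguous label cells failing exactly one condition as
#'   \code{"ambiguous"} (default TRUE).
#' @return A [ClassifierParams-class] object.
#' @examples
#' classifierParams(rule = "median")
#' @export
classifierParams <- function(topFraction = 0.05,
                             rule = c("median", "mean_sd"),
                             sdMultiplier = 2,
                             correlation = c("pearson", "spearman"),
                             flagAmbiguous = TRUE) {
  new("ClassifierParams",
      topFraction   = as.numeric(topFraction),
      rule          = match.arg(rule),
      sdMultiplier  = as.numeric(sdMultiplier),
      correlation   = match.arg(correlation),
      flagAmbiguous = as.logical(flagAmbiguous))
}

## ---------------------------------------------------------------------------
## GeneSignature
## ---------------------------------------------------------------------------

#' A named gene signature
#'
#' An ordered, duplicate-free set of gene symbols with a name and free-text
#' description, as parsed from one line of a GMT file.
#'
#' @slot name character(1) signature name.
#' @slot description character(1) free text.
#' @slot genes character vector of unique gene symbols.
#'
#' @seealso [geneSignature()], [readGMT()]
#' @export
setClass("GeneSignature",
  representation(name = "character", description = "character",
                 genes = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@description) != 1L)
    msg <- c(msg, "'description' must be a single string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "gene set must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene set must not contain duplicates")
  if (length(msg)) msg else TRUE
})

#' Construct a gene signature
#'
#' @param name signature name.
#' @param genes character vector of gene symbols; duplicates are removed
#'   with a warning.
#' @param description optional free-text description.
#' @return A [GeneSignature-class] object.
#' @examples
#' geneSignature("epithelial", c("Epcam", "Krt8", "Krt18"))
#' @export
geneSignature <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning("signature '", name, "': duplicate genes removed")
    genes <- unique(genes)
  }
  new("GeneSignature", name = as.character(name),
      description = as.character(description), genes = genes)
}

#' @describeIn GeneSignature-class Gene symbols of the signature.
#' @param x,object a \code{GeneSignature}.
#' @export
setMethod("names", "GeneSignature", function(x) x@name)

#' Genes of a signature
#' @param x a [GeneSignature-class].
#' @return character vector of gene symbols.
#' @export
sigGenes <- function(x) {
  stopifnot(is(x, "GeneSignature"))
  x@genes
}

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "' (", length(object@genes),
      " genes)\n", sep = "")
  preview <- utils::head(object@genes, 6L)
  cat("  ", paste(preview, collapse = ", "),
      if (length(object@genes) > 6L) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CentroidModel
## ---------------------------------------------------------------------------

#' A nearest-centroid subtype model
#'
#' A genes x subtypes matrix of centroid expression values, as used by
#' PAM50-style intrinsic subtyping. Centroid values are an external input:
#' the model ships with none and test fixtures use synthetic centroids.
#'
#' @slot centroids numeric matrix, genes in rows (rownames are gene ids),
#'   subtypes in columns (colnames are subtype labels).
#'
#' @seealso [centroidModel()], [nearestCentroid()]
#' @export
setClass("CentroidModel", representation(centroids = "matrix"))

setValidity("CentroidModel", function(object) {
  m <- object@centroids
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "centroid matrix must be numeric")
  if (anyNA(m)) msg <- c(msg, "centroid matrix must not contain missing values")
  if (ncol(m) < 2L) msg <- c(msg, "a centroid model needs >= 2 subtypes")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "centroid rows must carry unique gene identifiers")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "centroid columns must carry unique subtype labels")
  if (length(msg)) msg else TRUE
})

#' Construct a centroid model
#'
#' @param centroids numeric genes x subtypes matrix with gene rownames and
#'   subtype colnames.
#' @return A [CentroidModel-class] object.
#' @examples
#' m <- matrix(rnorm(10), 5, 2,
#'             dimnames = list(paste0("g", 1:5), c("A", "B")))
#' centroidModel(m)
#' @export
centroidModel <- function(centroids) {
  new("CentroidModel", centroids = as.matrix(centroids))
}

#' Centroid matrix of a model
#' @param x a [CentroidModel-class].
#' @return numeric genes x subtypes matrix.
#' @export
centroidMatrix <- function(x) {
  stopifnot(is(x, "CentroidModel"))
  x@centroids
}

#' Subtype labels of a centroid model
#' @param x a [CentroidModel-class].
#' @return character vector of subtype labels, in model order.
#' @export
subtypeLabels <- function(x) {
  stopifnot(is(x, "CentroidModel"))
  colnames(x@centroids)
}

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel:", nrow(object@centroids), "genes x",
      ncol(object@centroids), "subtypes\n")
  cat("  subtypes:", paste(colnames(object@centroids), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CNAProfile
## ---------------------------------------------------------------------------

#' Smoothed per-cell CNA profiles
#'
#' A \linkS4class{SummarizedExperiment} holding the genes x cells matrix of
#' smoothed, reference-centered relative-expression values (assay
#' \code{"cna"}) that stands in for per-cell copy-number state. Rows are
#' ordered genomically: chromosomes form contiguous blocks (in the order
#' they first appear in the annotation) and genes are sorted by start
#' coordinate within each block. \code{rowData} carries \code{chromosome}
#' and \code{start}.
#'
#' @seealso [inferCNA()], [cnaMatrix()], [chromosomeBoundaries()]
#' @export
setClass("CNAProfile", contains = "SummarizedExperiment")

setValidity("CNAProfile", function(object) {
  msg <- character()
  if (!"cna" %in% names(assays(object)))
    msg <- c(msg, "assay 'cna' is required")
  rd <- rowData(object)
  if (!all(c("chromosome", "start") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'chromosome' and 'start'")
  } else {
    chrom <- as.character(rd$chromosome)
    start <- as.numeric(rd$start)
    r <- rle(chrom)
    if (anyDuplicated(r$values))
      msg <- c(msg, "chromosomes must form contiguous blocks of rows")
    if (length(chrom)) {
      blocks <- split(start, factor(chrom, levels = unique(chrom)))
      if (!all(vapply(blocks, function(s) !is.unsorted(s), logical(1))))
        msg <- c(msg, "gene starts must be non-decreasing within chromosomes")
    }
  }
  if ("cna" %in% names(assays(object)) &&
      !all(is.finite(assay(object, "cna"))))
    msg <- c(msg, "all CNA values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CNAProfile
#'
#' Rows are reordered genomically (chromosome block order = order of first
#' appearance; start coordinate within chromosome, ties by gene id).
#'
#' @param values numeric genes x cells matrix with gene rownames and cell
#'   colnames.
#' @param chromosome character vector, chromosome per gene.
#' @param start numeric vector, start coordinate per gene.
#' @return A [CNAProfile-class] object.
#' @export
CNAProfile <- function(values, chromosome, start) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), length(chromosome) == nrow(values),
            length(start) == nrow(values))
  chromosome <- as.character(chromosome)
  start <- as.numeric(start)
  ord <- order(match(chromosome, unique(chromosome)), start, rownames(values))
  values <- values[ord, , drop = FALSE]
  new("CNAProfile", SummarizedExperiment(
    assays = list(cna = values),
    rowData = DataFrame(chromosome = chromosome[ord], start = start[ord],
                        row.names = rownames(values))))
}

setMethod("show", "CNAProfile", function(object) {
  b <- chromosomeBoundaries(object)
  cat("CNAProfile:", nrow(object), "genes x", ncol(object), "cells over",
      nrow(b), "chromosomes\n")
  v <- assay(object, "cna")
  cat(sprintf("  value range [%.3g, %.3g]\n", min(v), max(v)))
})
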