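#' @include AllClasses.R AllGenerics.R
NULL

#' Filter genes by mean normalized expression
#'
#' Retains genes whose mean normalized expression across all cells is at
#' least \code{cutoff} (the standard pre-filter of reference-based CNA
#' inference, default cutoff 0.1).
#'
#' @param norm genes x cells log-normalized matrix.
#' @param cutoff non-negative mean-expression cutoff.
#' @return Character vector of retained gene ids, in input order.
#' @export
filterByMeanExpression <- function(norm, cutoff = 0.1) {
  stopifnot(cutoff >= 0)
  keep <- Matrix::rowMeans(norm) >= cutoff
  if (!any(keep))
    stop("no gene passes the mean-expression cutoff of ", cutoff)
  rownames(norm)[keep]
}

#' Center expression on a diploid reference and clip
#'
#' Subtracts, per gene, the reference-cell summary (mean by default) from
#' every cell and clips the residuals at the symmetric bound
#' \code{maxCenteredThreshold}.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param params a [CNAParams-class]; uses \code{referenceCells},
#'   \code{maxCenteredThreshold} and \code{centerStat}.
#' @return Dense genes x cells matrix of clipped, reference-centered
#'   residuals.
#' @export
centerOnReference <- function(norm, params) {
  stopifnot(is(params, "CNAParams"))
  ref <- intersect(params@referenceCells, colnames(norm))
  if (!length(ref))
    stop("no reference cell is present in the matrix")
  refMat <- norm[, ref, drop = FALSE]
  center <- if (params@centerStat == "mean") Matrix::rowMeans(refMat)
            else apply(as.matrix(refMat), 1L, stats::median)
  out <- as.matrix(norm) - center
  thr <- params@maxCenteredThreshold
  out[out > thr] <- thr
  out[out < -thr] <- -thr
  out
}

#' Smooth centered expression along each chromosome
#'
#' Orders genes by (chromosome, start) and replaces every value by the
#' unweighted mean of the values inside a centered window of
#' \code{window} genes, truncated at chromosome ends (windows shrink near
#' edges); chromosomes are never mixed.
#'
#' @param centered genes x cells matrix of reference-centered values with
#'   gene rownames.
#' @param annotation data.frame with \code{gene_id}, \code{chromosome},
#'   \code{start} covering (at least) the genes of \code{centered}.
#' @param window odd window length in genes (default 101).
#' @param strict if TRUE (default), genes missing from the annotation are
#'   an error; if FALSE they are dropped with a warning.
#' @return A [CNAProfile-class] with rows in genomic order.
#' @export
smoothByChromosome <- function(centered, annotation, window = 101L,
                               strict = TRUE) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  centered <- as.matrix(centered)
  hit <- match(rownames(centered), annotation$gene_id)
  if (anyNA(hit)) {
    offenders <- rownames(centered)[is.na(hit)]
    if (strict)
      stop("gene(s) without annotation: ",
           paste(utils::head(offenders, 10L), collapse = ", "),
           if (length(offenders) > 10L) ", ..." else "")
    warning(length(offenders), " gene(s) without annotation dropped")
    centered <- centered[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  chrom <- as.character(annotation$chromosome)[hit]
  start <- as.numeric(annotation$start)[hit]
  ord <- order(match(chrom, unique(chrom)), start, rownames(centered))
  centered <- centered[ord, , drop = FALSE]
  chrom <- chrom[ord]
  start <- start[ord]

  out <- centered
  half <- (window - 1L) %/% 2L
  r <- rle(chrom)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  for (b in seq_along(begins)) {
    idx <- begins[b]:ends[b]
    g <- length(idx)
    block <- centered[idx, , drop = FALSE]
    cs <- rbind(0, apply(block, 2L, cumsum))
    pos <- seq_len(g)
    lo <- pmax(pos - half, 1L)
    hi <- pmin(pos + half, g)
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  CNAProfile(out, chromosome = chrom, start = start)
}

#' Recenter every cell on its median
#'
#' Subtracts the per-cell median from each column so that differences in
#' overall profile level between cells are removed.
#'
#' @param profile a [CNAProfile-class].
#' @return A [CNAProfile-class] with per-cell median zero.
#' @export
recenterCells <- function(profile) {
  stopifnot(is(profile, "CNAProfile"))
  v <- cnaMatrix(profile)
  v <- sweep(v, 2L, apply(v, 2L, stats::median), "-")
  rd <- rowData(profile)
  CNAProfile(v, chromosome = rd$chromosome, start = rd$start)
}

.inferCNAMatrix <- function(norm, annotation, params) {
  stopifnot(is(params, "CNAParams"))
  validObject(params)
  keep <- filterByMeanExpression(norm, params@expressionCutoff)
  norm <- norm[keep, , drop = FALSE]
  centered <- centerOnReference(norm, params)
  smoothed <- smoothByChromosome(centered, annotation,
                                 window = params@windowLength)
  recenterCells(smoothed)
}

#' Infer per-cell CNA profiles from normalized expression
#'
#' The full reference-based chain: drop weakly expressed genes
#' (mean normalized expression below \code{expressionCutoff}), center each
#' gene on the mean of the presumed-diploid reference cells, clip residuals
#' at \code{maxCenteredThreshold}, smooth along each chromosome with an
#' unweighted moving average of \code{windowLength} genes, and recenter
#' each cell on its median. Reference cells are retained in the output so
#' downstream correlation references can be built from them.
#'
#' @param x genes x cells log-normalized matrix, or a
#'   \linkS4class{SingleCellExperiment} with a \code{logcounts} assay.
#' @param annotation data.frame with \code{gene_id}, \code{chromosome},
#'   \code{start}; for a SingleCellExperiment it defaults to
#'   [geneAnnotation()] of the object.
#' @param params a [CNAParams-class].
#' @param ... unused.
#' @return A [CNAProfile-class].
#' @examples
#' sce <- simulateExperiment(simConfig(seed = 7))
#' sce <- logNormalize(sce)
#' ref <- sce$cell_id[sce$cell_type != "epithelial"]
#' prof <- inferCNA(sce, params = cnaParams(referenceCells = ref))
#' prof
#' @rdname inferCNA
#' @export
setMethod("inferCNA", signature(x = "ANY"),
  function(x, annotation, params, ...) {
    .inferCNAMatrix(x, annotation, params)
  })

#' @rdname inferCNA
#' @export
setMethod("inferCNA", signature(x = "SingleCellExperiment"),
  function(x, annotation, params, ...) {
    if (missing(annotation)) annotation <- geneAnnotation(x)
    .inferCNAMatrix(assay(x, "logcounts"), annotation, params)
  })
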