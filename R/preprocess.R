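#' @include AllClasses.R AllGenerics.R
NULL

.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
}

## ---------------------------------------------------------------------------
## QC filtering
## ---------------------------------------------------------------------------

.filterQCMatrix <- function(counts, thresholds) {
  stopifnot(is(thresholds, "QCThresholds"))
  validObject(thresholds)
  mito <- thresholds@mitoGenes
  bad <- setdiff(mito, rownames(counts))
  if (length(bad))
    stop("mitochondrial flags refer to genes absent from the matrix: ",
         paste(utils::head(bad, 5L), collapse = ", "))

  detectedPerCell <- Matrix::colSums(counts > 0)
  totals <- Matrix::colSums(counts)
  mitoPct <- if (length(mito)) {
    mt <- Matrix::colSums(counts[mito, , drop = FALSE])
    ifelse(totals > 0, 100 * mt / totals, 0)
  } else rep(0, ncol(counts))

  lowGenes <- detectedPerCell < thresholds@minGenesPerCell
  highMito <- mitoPct > thresholds@maxMitoPercent
  keepCells <- !(lowGenes | highMito)
  if (!any(keepCells))
    stop("QC removed every cell; check thresholds")

  kept <- counts[, keepCells, drop = FALSE]
  cellsPerGene <- Matrix::rowSums(kept > 0)
  keepGenes <- cellsPerGene >= thresholds@minCellsPerGene
  if (!any(keepGenes))
    stop("QC removed every gene; check thresholds")

  report <- list(
    nCellsIn = ncol(counts), nGenesIn = nrow(counts),
    cellsRemovedLowGenes = colnames(counts)[lowGenes],
    cellsRemovedHighMito = colnames(counts)[highMito & !lowGenes],
    genesRemovedLowCells = rownames(counts)[!keepGenes],
    nCellsRemoved = sum(!keepCells), nGenesRemoved = sum(!keepGenes),
    thresholds = thresholds)
  list(counts = kept[keepGenes, , drop = FALSE], report = report)
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells first (too few detected genes, or mitochondrial percent
#' above the ceiling), then genes detected in too few of the remaining
#' cells. The report lists every removed identifier and the reason.
#'
#' @param x genes x cells count matrix (dense or sparse) with dimnames, or
#'   a \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param thresholds a [QCThresholds-class] (default [qcThresholds()]).
#' @param ... unused.
#' @return For a matrix: \code{list(counts, report)}. For a
#'   SingleCellExperiment: the filtered object, with the report under
#'   \code{metadata(x)$qcReport}.
#' @examples
#' sce <- simulateExperiment(simConfig(seed = 7))
#' mito <- rownames(sce)[rowData(sce)$is_mito]
#' filt <- filterQC(sce, qcThresholds(mitoGenes = mito))
#' metadata(filt)$qcReport$nCellsRemoved
#' @rdname filterQC
#' @export
setMethod("filterQC", "ANY", function(x, thresholds = qcThresholds(), ...) {
  .filterQCMatrix(x, thresholds)
})

#' @rdname filterQC
#' @export
setMethod("filterQC", "SingleCellExperiment",
  function(x, thresholds = qcThresholds(), ...) {
    res <- .filterQCMatrix(assay(x, "counts"), thresholds)
    out <- x[rownames(res$counts), colnames(res$counts)]
    S4Vectors::metadata(out)$qcReport <- res$report
    out
  })

## ---------------------------------------------------------------------------
## Log-normalization and scaling
## ---------------------------------------------------------------------------

.logNormalizeMatrix <- function(counts, scaleFactor) {
  stopifnot(scaleFactor > 0)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cell(s) with zero total counts: ",
         paste(utils::head(colnames(counts)[totals == 0], 5L),
               collapse = ", "))
  if (is(counts, "sparseMatrix")) {
    m <- methods::as(counts, "CsparseMatrix")
    j <- rep.int(seq_len(ncol(m)), diff(m@p))
    m@x <- log1p(m@x / totals[j] * scaleFactor)
    m
  } else {
    log1p(sweep(as.matrix(counts), 2L, totals, "/") * scaleFactor)
  }
}

#' Log-normalize counts
#'
#' Per-cell library-size normalization followed by a log transform:
#' \code{value = ln(1 + count / total * scaleFactor)}. Zeros stay zero.
#'
#' @param x genes x cells count matrix, or a
#'   \linkS4class{SingleCellExperiment} with a \code{counts} assay.
#' @param scaleFactor positive scale factor (default 10,000).
#' @param ... unused.
#' @return Matrix input: the normalized matrix (sparse in, sparse out).
#'   SingleCellExperiment input: the object with a \code{logcounts} assay
#'   added.
#' @rdname logNormalize
#' @export
setMethod("logNormalize", "ANY", function(x, scaleFactor = 1e4, ...) {
  .logNormalizeMatrix(x, scaleFactor)
})

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "SingleCellExperiment",
  function(x, scaleFactor = 1e4, ...) {
    assay(x, "logcounts") <- .logNormalizeMatrix(assay(x, "counts"),
                                                 scaleFactor)
    x
  })

.scaleGenesMatrix <- function(norm, cap) {
  stopifnot(cap > 0)
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  sd <- sqrt(.rowVars(x))
  z <- (x - mu) / sd
  z[!is.finite(z)] <- 0        # zero-variance genes
  z[z > cap] <- cap
  z[z < -cap] <- -cap
  z
}

#' Per-gene z-scoring with clipping
#'
#' Centers and scales every gene across cells (sample standard deviation,
#' n - 1), then clips to \code{[-cap, cap]}. Zero-variance genes become
#' all-zero rows.
#'
#' @param x genes x cells log-normalized matrix, or a
#'   \linkS4class{SingleCellExperiment} with a \code{logcounts} assay.
#' @param cap positive clipping bound (default 10).
#' @param ... unused.
#' @return Matrix input: the dense scaled matrix. SingleCellExperiment
#'   input: the object with a \code{scaled} assay added.
#' @rdname scaleGenes
#' @export
setMethod("scaleGenes", "ANY", function(x, cap = 10, ...) {
  .scaleGenesMatrix(x, cap)
})

#' @rdname scaleGenes
#' @export
setMethod("scaleGenes", "SingleCellExperiment", function(x, cap = 10, ...) {
  assay(x, "scaled") <- .scaleGenesMatrix(assay(x, "logcounts"), cap)
  x
})

## ---------------------------------------------------------------------------
## Highly variable genes
## ---------------------------------------------------------------------------

#' Select highly variable genes by trend-standardized variance
#'
#' Fits a degree-2 polynomial of log10(variance) on log10(mean) over
#' expressed genes as the mean-variance trend, standardizes each gene by
#' its trend standard deviation, clips the standardized values at
#' sqrt(number of cells), and ranks genes by the variance of the clipped
#' values. Deterministic; rank ties are broken by gene identifier.
#'
#' @param norm genes x cells expression matrix. The canonical pipeline
#'   passes raw counts, following the variance-stabilizing selection
#'   convention (the mean-variance trend is far more informative on counts
#'   than after the log transform).
#' @param n number of genes to select (default 2000).
#' @return Character vector of the \code{n} selected gene ids, ordered by
#'   decreasing standardized variance.
#' @importFrom stats lm predict
#' @export
selectHVG <- function(norm, n = 2000L) {
  n <- as.integer(n)
  if (n > nrow(norm))
    stop("n (", n, ") exceeds the number of genes (", nrow(norm), ")")
  x <- as.matrix(norm)
  mu <- rowMeans(x)
  v <- .rowVars(x)
  expressed <- mu > 0 & v > 0
  stdVar <- rep(0, nrow(x))
  if (any(expressed)) {
    lm10 <- log10(mu[expressed])
    lv10 <- log10(v[expressed])
    fit <- lm(lv10 ~ lm10 + I(lm10^2))
    trendSD <- sqrt(10^predict(fit))
    clipAt <- sqrt(ncol(x))
    z <- (x[expressed, , drop = FALSE] - mu[expressed]) / trendSD
    z[z > clipAt] <- clipAt
    z[z < -clipAt] <- -clipAt
    stdVar[expressed] <- .rowVars(z)
  }
  ord <- order(-stdVar, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

## ---------------------------------------------------------------------------
## Marker-based cell typing
## ---------------------------------------------------------------------------

#' Assign cell types by marker-signature argmax
#'
#' Scores each signature as the mean scaled expression of its genes present
#' in the matrix and labels every cell with the highest-scoring signature.
#' Ties go to the earlier signature in the list.
#'
#' @param scaled genes x cells scaled expression matrix.
#' @param markerSignatures list of [GeneSignature-class] marker sets.
#' @return data.frame with \code{cell_id}, \code{cell_type} and one score
#'   column per signature.
#' @export
assignCellTypes <- function(scaled, markerSignatures) {
  stopifnot(length(markerSignatures) >= 1L)
  scores <- vapply(markerSignatures, function(sig) {
    stopifnot(is(sig, "GeneSignature"))
    genes <- intersect(sig@genes, rownames(scaled))
    if (!length(genes))
      stop("signature '", sig@name, "' has no genes in the matrix")
    Matrix::colMeans(scaled[genes, , drop = FALSE])
  }, numeric(ncol(scaled)))
  sigNames <- vapply(markerSignatures, function(s) s@name, character(1))
  colnames(scores) <- sigNames
  label <- sigNames[apply(scores, 1L, which.max)]
  out <- data.frame(cell_id = colnames(scaled), cell_type = label,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores, row.names = NULL))
}
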