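#' @include AllClasses.R
NULL

#' Median-center every gene across samples
#'
#' Subtracts the per-gene median so every gene row has median 0 — the
#' standard preparation before nearest-centroid intrinsic subtyping.
#' Idempotent.
#'
#' @param x genes x samples numeric matrix.
#' @return Matrix of the same shape.
#' @examples
#' medianCenter(matrix(c(1, 2, 4), 1, 3))
#' @export
medianCenter <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1L)
  x - apply(x, 1L, stats::median)
}

#' Nearest-centroid molecular subtyping
#'
#' Each sample is correlated with every centroid over the genes shared
#' between the expression matrix and the model; the assigned subtype is the
#' centroid with the highest correlation. Ties go to the earlier subtype in
#' the model and are flagged. Spearman correlation is the default, so
#' calls are invariant to monotone transforms of a sample's values.
#'
#' @param x genes x samples expression matrix (typically median-centered,
#'   e.g. [bulkPrepare()] output).
#' @param model a [CentroidModel-class].
#' @param metric \code{"spearman"} (default) or \code{"pearson"}.
#' @param minOverlap minimum number of shared genes (default: half the
#'   model's genes, rounded up).
#' @return data.frame with \code{sample_id}, \code{subtype},
#'   \code{margin} (best minus second-best correlation), \code{tie},
#'   \code{n_genes_used}, and one \code{cor_<subtype>} column per subtype.
#' @examples
#' cm <- matrix(c(3, 2, 1, 0, 1, 0, 3, 2), 4, 2,
#'              dimnames = list(paste0("g", 1:4), c("A", "B")))
#' nearestCentroid(cm[, "A", drop = FALSE], centroidModel(cm),
#'                 minOverlap = 4)
#' @export
nearestCentroid <- function(x, model, metric = c("spearman", "pearson"),
                            minOverlap = NULL) {
  metric <- match.arg(metric)
  stopifnot(is(model, "CentroidModel"))
  cen <- centroidMatrix(model)
  if (is.null(minOverlap)) minOverlap <- ceiling(nrow(cen) / 2)
  x <- as.matrix(x)
  shared <- intersect(rownames(x), rownames(cen))
  if (length(shared) < minOverlap)
    stop("only ", length(shared), " genes shared with the centroid model ",
         "(minimum ", minOverlap, ")")
  xs <- x[shared, , drop = FALSE]
  cs <- cen[shared, , drop = FALSE]
  r <- stats::cor(xs, cs, method = metric)   # samples x subtypes
  subtypes <- colnames(cs)
  best <- apply(r, 1L, which.max)
  margin <- apply(r, 1L, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) > 1L) s[1L] - s[2L] else 0
  })
  tie <- apply(r, 1L, function(v) sum(v == max(v)) > 1L)
  out <- data.frame(
    sample_id = colnames(xs), subtype = subtypes[best],
    margin = as.numeric(margin), tie = tie,
    n_genes_used = length(shared), stringsAsFactors = FALSE,
    row.names = NULL)
  rcols <- as.data.frame(r, row.names = NULL)
  colnames(rcols) <- paste0("cor_", subtypes)
  cbind(out, rcols)
}
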