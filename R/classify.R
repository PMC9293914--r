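#' @include AllClasses.R AllGenerics.R cna.R
NULL

#' Per-cell CNA burden
#'
#' The burden of a cell is the mean of its squared smoothed CNA values —
#' the ranking statistic used to pick the most-aberrant candidates.
#'
#' @param x a [CNAProfile-class] or a genes x cells numeric matrix.
#' @return Named numeric vector, one non-negative burden per cell.
#' @examples
#' cnaBurden(matrix(c(1, -1, 0, 0), 2, dimnames = list(NULL, c("a", "b"))))
#' @rdname cnaBurden
#' @export
setMethod("cnaBurden", "ANY", function(x) {
  colMeans(as.matrix(x)^2)
})

#' @rdname cnaBurden
#' @export
setMethod("cnaBurden", "CNAProfile", function(x) {
  colMeans(cnaMatrix(x)^2)
})

#' Build the aberrant and normal reference profiles
#'
#' The aberrant (malignant) reference is the per-gene mean profile of the
#' \code{ceiling(topFraction * n)} highest-burden candidate cells (burden
#' ties broken by cell id, so the selection is deterministic); the normal
#' reference is the per-gene mean profile of the normal cells.
#'
#' @param profile a [CNAProfile-class].
#' @param candidateCells cell ids from which the aberrant pole is built.
#' @param normalCells cell ids averaged into the normal pole.
#' @param params a [ClassifierParams-class]; uses \code{topFraction}.
#' @return list with \code{malignantRef}, \code{normalRef} (gene-named
#'   numeric vectors) and \code{topCells} (the selected candidate ids).
#' @export
buildReferenceProfiles <- function(profile, candidateCells, normalCells,
                                   params = classifierParams()) {
  stopifnot(is(profile, "CNAProfile"), is(params, "ClassifierParams"))
  v <- cnaMatrix(profile)
  candidateCells <- intersect(candidateCells, colnames(v))
  normalCells <- intersect(normalCells, colnames(v))
  if (!length(candidateCells)) stop("candidate cell set is empty")
  if (!length(normalCells)) stop("normal cell set is empty")
  burden <- cnaBurden(profile)[candidateCells]
  nTop <- ceiling(params@topFraction * length(candidateCells))
  if (nTop < 1L) stop("top candidate set is empty")
  ord <- order(-burden, candidateCells)
  top <- candidateCells[ord][seq_len(nTop)]
  list(
    malignantRef = rowMeans(v[, top, drop = FALSE]),
    normalRef    = rowMeans(v[, normalCells, drop = FALSE]),
    topCells     = top)
}

#' Correlate every cell with the two reference profiles
#'
#' @param profile a [CNAProfile-class].
#' @param malignantRef,normalRef gene-length numeric reference vectors
#'   (e.g. from [buildReferenceProfiles()]); neither may be constant.
#' @param params a [ClassifierParams-class]; uses \code{correlation}.
#' @return data.frame with \code{cell_id}, \code{r_malignant},
#'   \code{r_normal}. Cells with a constant profile get correlation 0 with
#'   a warning: a flat profile is the definition of "no aberration" and can
#'   never be called malignant.
#' @importFrom stats cor sd median
#' @export
dualCorrelation <- function(profile, malignantRef, normalRef,
                            params = classifierParams()) {
  stopifnot(is(profile, "CNAProfile"), is(params, "ClassifierParams"))
  v <- cnaMatrix(profile)
  if (sd(malignantRef) == 0) stop("malignant reference profile is constant")
  if (sd(normalRef) == 0) stop("normal reference profile is constant")
  method <- params@correlation
  constant <- apply(v, 2L, sd) == 0
  rMal <- rep(0, ncol(v))
  rNorm <- rep(0, ncol(v))
  if (any(!constant)) {
    sub <- v[, !constant, drop = FALSE]
    rMal[!constant] <- as.vector(cor(sub, malignantRef, method = method))
    rNorm[!constant] <- as.vector(cor(sub, normalRef, method = method))
  }
  if (any(constant))
    warning(sum(constant),
            " cell(s) with constant profile assigned correlation 0")
  data.frame(cell_id = colnames(v), r_malignant = rMal, r_normal = rNorm,
             stringsAsFactors = FALSE)
}

#' Call malignant cells from the dual correlations
#'
#' Under the default \code{median} rule a cell is malignant iff its
#' correlation with the aberrant reference strictly exceeds the median of
#' that correlation over the classified set AND its correlation with the
#' normal reference is strictly below the corresponding median. Under the
#' \code{mean_sd} rule the cutoffs are mean(r_malignant) + k sd and
#' mean(r_normal) - k sd (a conservative variant selecting the extreme
#' corner). Cells failing exactly one condition are labelled
#' \code{ambiguous} when \code{flagAmbiguous} is on, otherwise
#' \code{normal}.
#'
#' @param correlations data.frame from [dualCorrelation()] (columns
#'   \code{cell_id}, \code{r_malignant}, \code{r_normal}), optionally with
#'   a \code{burden} column that is carried through.
#' @param params a [ClassifierParams-class].
#' @return data.frame with \code{cell_id}, \code{burden} (NA when not
#'   supplied), \code{r_malignant}, \code{r_normal}, \code{call}.
#' @export
classifyCells <- function(correlations, params = classifierParams()) {
  stopifnot(is(params, "ClassifierParams"),
            all(c("cell_id", "r_malignant", "r_normal") %in%
                colnames(correlations)))
  if (nrow(correlations) < 2L)
    stop("classification needs at least 2 cells")
  rMal <- correlations$r_malignant
  rNorm <- correlations$r_normal
  if (params@rule == "median") {
    cutMal <- median(rMal)
    cutNorm <- median(rNorm)
  } else {
    k <- params@sdMultiplier
    cutMal <- mean(rMal) + k * sd(rMal)
    cutNorm <- mean(rNorm) - k * sd(rNorm)
  }
  passMal <- rMal > cutMal
  passNorm <- rNorm < cutNorm
  call <- ifelse(passMal & passNorm, "malignant",
                 ifelse(xor(passMal, passNorm) & params@flagAmbiguous,
                        "ambiguous", "normal"))
  data.frame(
    cell_id = correlations$cell_id,
    burden = if ("burden" %in% colnames(correlations))
      correlations$burden else NA_real_,
    r_malignant = rMal, r_normal = rNorm, call = call,
    stringsAsFactors = FALSE)
}

#' Designate CNA-high malignant cells from smoothed profiles
#'
#' The full dual-correlation procedure: rank candidate cells by CNA burden,
#' average the top fraction into an aberrant reference profile, average the
#' normal cells into a normal reference profile, correlate every cell with
#' both, and apply the classification rule. When \code{sampleIds} is given,
#' references are built and cutoffs applied within each sample ("per
#' sample" mode); otherwise the whole profile is treated as one pooled
#' sample.
#'
#' @param profile a [CNAProfile-class].
#' @param candidateCells cell ids eligible to define the aberrant pole
#'   (typically all epithelial cells).
#' @param normalCells presumed-normal cell ids averaged into the normal
#'   pole (typically marker-identified normal epithelial cells).
#' @param params a [ClassifierParams-class].
#' @param sampleIds optional named character (names = cell ids) giving each
#'   cell's sample; triggers per-sample classification.
#' @param cells cell ids to classify (default: all candidate cells).
#' @return data.frame (one row per classified cell): \code{cell_id},
#'   \code{burden}, \code{r_malignant}, \code{r_normal}, \code{call}.
#' @examples
#' sce <- simulateExperiment(simConfig(seed = 7))
#' sce <- logNormalize(sce)
#' ref <- sce$cell_id[sce$cell_type != "epithelial"]
#' prof <- inferCNA(sce, params = cnaParams(referenceCells = ref))
#' epi <- sce$cell_id[sce$cell_type == "epithelial"]
#' nrm <- sce$cell_id[sce$cell_type == "epithelial" & !sce$is_malignant]
#' calls <- callMalignantCells(prof, epi, nrm)
#' table(calls$call)
#' @export
callMalignantCells <- function(profile, candidateCells, normalCells,
                               params = classifierParams(),
                               sampleIds = NULL, cells = candidateCells) {
  stopifnot(is(profile, "CNAProfile"))
  cells <- intersect(cells, colnames(profile))
  if (is.null(sampleIds)) {
    groups <- list(pooled = cells)
  } else {
    stopifnot(!is.null(names(sampleIds)))
    groups <- split(cells, sampleIds[cells])
  }
  burden <- cnaBurden(profile)
  out <- lapply(groups, function(grp) {
    cand <- intersect(candidateCells, grp)
    nrm <- intersect(normalCells,
                     if (is.null(sampleIds)) colnames(profile) else grp)
    refs <- buildReferenceProfiles(profile[, grp], cand, nrm, params)
    corr <- dualCorrelation(profile[, grp], refs$malignantRef,
                            refs$normalRef, params)
    corr$burden <- burden[corr$cell_id]
    classifyCells(corr, params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(cells, res$cell_id), , drop = FALSE]
}
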