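#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Signature scoring
## ---------------------------------------------------------------------------

#' Score a gene signature per cell or per sample
#'
#' The score of a unit (cell or bulk sample) is the mean scaled expression
#' of the signature genes present in the matrix; genes absent from the
#' matrix are dropped (and reported in the \code{missing_genes} attribute).
#'
#' @param scaled genes x units scaled expression matrix.
#' @param signature a [GeneSignature-class].
#' @return data.frame with \code{unit_id}, \code{signature}, \code{score},
#'   \code{n_genes_used}; attribute \code{missing_genes} lists signature
#'   genes absent from the matrix.
#' @examples
#' m <- matrix(c(1, -0.5), 2, 1, dimnames = list(c("a", "b"), "cell1"))
#' scoreSignature(m, geneSignature("s", c("a", "b")))
#' @export
scoreSignature <- function(scaled, signature) {
  stopifnot(is(signature, "GeneSignature"))
  genes <- intersect(signature@genes, rownames(scaled))
  if (!length(genes))
    stop("signature '", signature@name,
         "' shares no genes with the matrix")
  score <- Matrix::colMeans(scaled[genes, , drop = FALSE])
  out <- data.frame(unit_id = colnames(scaled), signature = signature@name,
                    score = as.numeric(score),
                    n_genes_used = length(genes),
                    stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- setdiff(signature@genes, genes)
  out
}

#' Score several signatures at once
#'
#' @param scaled genes x units scaled expression matrix.
#' @param signatures list of [GeneSignature-class] objects (e.g. from
#'   [readGMT()]).
#' @return Long data.frame, the row-bound [scoreSignature()] tables.
#' @export
scoreSignatures <- function(scaled, signatures) {
  do.call(rbind, c(lapply(signatures, function(s)
    scoreSignature(scaled, s)), make.row.names = FALSE))
}

## ---------------------------------------------------------------------------
## Wilcoxon rank-sum differential expression
## ---------------------------------------------------------------------------

## Two-sided Mann-Whitney p for one gene. Exact (distribution function)
## when both groups are small and tie-free; otherwise normal approximation
## with tie correction and continuity correction.
.rankSumP <- function(values, n1, exactMax = 25L) {
  n <- length(values)
  n2 <- n - n1
  r <- rank(values)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(values)
  hasTies <- any(ties > 1L)
  if (!hasTies && n1 <= exactMax && n2 <= exactMax) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Genes are pre-filtered: the absolute natural-log fold change of mean
#' expm1 normalized expression must reach \code{logfcThreshold} and the
#' expressed fraction must reach \code{minPct} in at least one group.
#' Surviving genes get a two-sided rank-sum p (exact for tie-free groups of
#' at most 25 cells, otherwise a normal approximation with tie and
#' continuity correction) and Benjamini-Hochberg adjustment over the tested
#' genes.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param group1,group2 disjoint cell id vectors, each of >= 3 cells.
#' @param logfcThreshold minimum |log fold change| (default 0.25, natural
#'   log).
#' @param minPct minimum expressed fraction in at least one group
#'   (default 0.1).
#' @return data.frame sorted by p-value: \code{gene}, \code{log_fc},
#'   \code{p_value}, \code{p_adjusted}, \code{pct_group1},
#'   \code{pct_group2}, \code{direction}.
#' @importFrom stats p.adjust
#' @export
wilcoxonDE <- function(norm, group1, group2, logfcThreshold = 0.25,
                       minPct = 0.1) {
  if (length(intersect(group1, group2)))
    stop("group1 and group2 overlap")
  missing <- setdiff(c(group1, group2), colnames(norm))
  if (length(missing))
    stop("cell(s) absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  if (length(group1) < 3L || length(group2) < 3L)
    stop("both groups need >= 3 cells")
  x1 <- as.matrix(norm[, group1, drop = FALSE])
  x2 <- as.matrix(norm[, group2, drop = FALSE])
  eps <- 1e-9
  logFc <- log((rowMeans(expm1(x1)) + eps) / (rowMeans(expm1(x2)) + eps))
  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  keep <- which(abs(logFc) >= logfcThreshold & pmax(pct1, pct2) >= minPct)
  if (!length(keep))
    return(data.frame(gene = character(), log_fc = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      pct_group1 = numeric(), pct_group2 = numeric(),
                      direction = numeric(), stringsAsFactors = FALSE))
  n1 <- length(group1)
  p <- vapply(keep, function(g)
    .rankSumP(c(x1[g, ], x2[g, ]), n1), numeric(1))
  out <- data.frame(
    gene = rownames(norm)[keep], log_fc = logFc[keep], p_value = p,
    p_adjusted = p.adjust(p, method = "BH"),
    pct_group1 = pct1[keep], pct_group2 = pct2[keep],
    direction = sign(logFc[keep]), stringsAsFactors = FALSE)
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Top upregulated marker genes of a differential-expression result
#'
#' @param results data.frame from [wilcoxonDE()].
#' @param n number of genes to return.
#' @return Character vector of at most \code{n} upregulated genes ordered
#'   by adjusted p, then |log fold change| (descending), ties by gene id.
#' @export
rankTopMarkers <- function(results, n = 100L) {
  up <- results[results$log_fc > 0, , drop = FALSE]
  ord <- order(up$p_adjusted, -abs(up$log_fc), up$gene)
  utils::head(up$gene[ord], n)
}

#' Markers conserved across disease states
#'
#' A gene qualifies when it is significantly upregulated in the target
#' group (positive log fold change, adjusted p below \code{alpha}) within
#' every condition separately; the reported p-values are the per-gene
#' maxima across conditions.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param groupCells cell ids of the group of interest (e.g. malignant
#'   cells).
#' @param conditionLabels named character (names = cell ids) assigning
#'   every cell of \code{norm} to a condition (e.g. disease state).
#' @param alpha adjusted-p significance level per condition (default 0.05).
#' @param logfcThreshold,minPct passed to [wilcoxonDE()].
#' @return data.frame with \code{gene}, \code{max_p_value},
#'   \code{max_p_adjusted}, \code{min_log_fc}, sorted by
#'   \code{max_p_value}.
#' @export
conservedMarkers <- function(norm, groupCells, conditionLabels,
                             alpha = 0.05, logfcThreshold = 0.25,
                             minPct = 0.1) {
  stopifnot(!is.null(names(conditionLabels)))
  cells <- intersect(colnames(norm), names(conditionLabels))
  byCond <- split(cells, conditionLabels[cells])
  perCond <- lapply(names(byCond), function(cond) {
    inGrp <- intersect(byCond[[cond]], groupCells)
    outGrp <- setdiff(byCond[[cond]], groupCells)
    if (length(inGrp) < 3L || length(outGrp) < 3L)
      stop("condition '", cond, "' is missing a group (needs >= 3 cells ",
           "in and out of the target group)")
    wilcoxonDE(norm, inGrp, outGrp, logfcThreshold = logfcThreshold,
               minPct = minPct)
  })
  names(perCond) <- names(byCond)
  qualifying <- lapply(perCond, function(de)
    de[de$log_fc > 0 & de$p_adjusted < alpha, , drop = FALSE])
  shared <- Reduce(intersect, lapply(qualifying, `[[`, "gene"))
  if (!length(shared))
    return(data.frame(gene = character(), max_p_value = numeric(),
                      max_p_adjusted = numeric(), min_log_fc = numeric(),
                      stringsAsFactors = FALSE))
  stat <- function(col, fun) {
    m <- do.call(cbind, lapply(qualifying, function(de)
      de[[col]][match(shared, de$gene)]))
    apply(m, 1L, fun)
  }
  out <- data.frame(
    gene = shared,
    max_p_value = stat("p_value", max),
    max_p_adjusted = stat("p_adjusted", max),
    min_log_fc = stat("log_fc", min), stringsAsFactors = FALSE)
  out[order(out$max_p_value, out$gene), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Ortholog translation
## ---------------------------------------------------------------------------

#' Translate a gene signature through an ortholog table
#'
#' Under the \code{one_to_one} policy only unambiguous pairs are kept: the
#' source symbol must map to exactly one target and that target must come
#' from exactly one source (table-wide). Under \code{any}, every target of
#' every signature gene is kept. The output is deduplicated; unmapped
#' genes are reported in the \code{unmapped} attribute.
#'
#' @param signature a [GeneSignature-class].
#' @param orthologs data.frame with \code{source_symbol},
#'   \code{target_symbol} (e.g. from [readOrthologTable()]).
#' @param policy \code{"one_to_one"} (default) or \code{"any"}.
#' @return A [GeneSignature-class] in the target gene space, with attribute
#'   \code{unmapped}.
#' @export
mapSignatureOrthologs <- function(signature, orthologs,
                                  policy = c("one_to_one", "any")) {
  policy <- match.arg(policy)
  stopifnot(is(signature, "GeneSignature"),
            all(c("source_symbol", "target_symbol") %in% colnames(orthologs)))
  tab <- orthologs
  if (policy == "one_to_one") {
    srcN <- table(tab$source_symbol)
    tgtN <- table(tab$target_symbol)
    tab <- tab[srcN[tab$source_symbol] == 1L &
               tgtN[tab$target_symbol] == 1L, , drop = FALSE]
  }
  hit <- tab[tab$source_symbol %in% signature@genes, , drop = FALSE]
  mapped <- unique(hit$target_symbol)
  unmapped <- setdiff(signature@genes, hit$source_symbol)
  if (!length(mapped))
    stop("no gene of signature '", signature@name,
         "' could be mapped under policy '", policy, "'")
  out <- geneSignature(signature@name, mapped,
                       description = signature@description)
  attr(out, "unmapped") <- unmapped
  out
}

## ---------------------------------------------------------------------------
## Bulk normalization and group comparison
## ---------------------------------------------------------------------------

#' Prepare bulk counts: upper-quartile normalize, log, median-center
#'
#' Each sample is scaled so the 75th percentile of its nonzero counts
#' equals a common target (the geometric mean of the per-sample upper
#' quartiles), then log2(x + 1) transformed, then every gene is centered on
#' its median across samples.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return Dense genes x samples matrix; every gene row has median 0.
#' @importFrom stats quantile
#' @export
bulkPrepare <- function(counts) {
  counts <- as.matrix(counts)
  uq <- apply(counts, 2L, function(col) {
    nz <- col[col > 0]
    if (!length(nz)) return(NA_real_)
    quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq) || any(uq == 0))
    stop("sample(s) with a degenerate (zero) upper quartile: ",
         paste(utils::head(colnames(counts)[is.na(uq) | uq == 0], 5L),
               collapse = ", "))
  target <- exp(mean(log(uq)))
  scaled <- sweep(counts, 2L, target / uq, "*")
  logged <- log2(scaled + 1)
  medianCenter(logged)
}

#' Pairwise Welch t-tests of signature scores between groups
#'
#' Every pair of groups is compared with a two-sided Welch t-test per
#' signature; Benjamini-Hochberg adjustment is applied across all reported
#' pairs.
#'
#' @param scores data.frame from [scoreSignature()] /
#'   [scoreSignatures()] (columns \code{unit_id}, \code{signature},
#'   \code{score}).
#' @param groups named character (names = unit ids) assigning each unit to
#'   a group; every group needs >= 2 units.
#' @return data.frame with \code{signature}, \code{group1}, \code{group2},
#'   \code{t}, \code{df}, \code{p_value}, \code{p_adjusted}.
#' @importFrom stats t.test
#' @export
compareGroups <- function(scores, groups) {
  stopifnot(all(c("unit_id", "signature", "score") %in% colnames(scores)),
            !is.null(names(groups)))
  g <- groups[scores$unit_id]
  if (anyNA(g)) stop("unit(s) without a group label")
  rows <- list()
  for (sig in unique(scores$signature)) {
    sub <- scores[scores$signature == sig, , drop = FALSE]
    gl <- unique(g[scores$signature == sig])
    sizes <- table(g[scores$signature == sig])
    if (any(sizes < 2L))
      stop("group(s) with fewer than 2 units: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "))
    if (length(gl) < 2L) stop("need >= 2 groups")
    for (i in seq_len(length(gl) - 1L)) for (j in seq.int(i + 1L,
                                                          length(gl))) {
      a <- sub$score[g[scores$signature == sig] == gl[i]]
      b <- sub$score[g[scores$signature == sig] == gl[j]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        # degenerate: no within-group variance
        eq <- isTRUE(all.equal(mean(a), mean(b)))
        tt <- list(statistic = c(t = if (eq) 0 else sign(mean(a) -
                                                           mean(b)) * Inf),
                   parameter = c(df = NA_real_),
                   p.value = if (eq) 1 else 0)
      } else {
        tt <- t.test(a, b)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig, group1 = gl[i], group2 = gl[j],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
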