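#' @include AllClasses.R
NULL

## Haldane-Anscombe 2x2 odds ratio with Wald CI, used both as the
## perfect-separation fallback and (without the 0.5 shift) nowhere else:
## the regular path is always the binomial GLM.
.haldane <- function(inK_ref, outK_ref, inK_alt, outK_alt) {
  a <- inK_alt + 0.5; b <- outK_alt + 0.5
  c <- inK_ref + 0.5; d <- outK_ref + 0.5
  logOr <- log(a) - log(b) - log(c) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- logOr / se
  list(or = exp(logOr), lo = exp(logOr - stats::qnorm(0.975) * se),
       hi = exp(logOr + stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(z)))
}

#' Per-cluster binomial regression of cell-type composition shifts
#'
#' For every cluster k a one-vs-rest binomial GLM
#' \code{logit P(cell in k) = b0 + b_state (+ b_batch)} is fitted by
#' maximum likelihood; the odds ratio of each non-reference state against
#' the reference is \code{exp(b_state)} with a Wald 95% confidence
#' interval and p-value, and Benjamini-Hochberg adjustment is applied
#' across clusters within each contrast. When a cluster is entirely absent
#' from one of the two states of a contrast (perfect separation) the
#' estimate falls back to the Haldane-Anscombe corrected 2x2 odds ratio
#' (0.5 added to each margin cell) and the row is flagged.
#'
#' @param input data.frame with one row per cell and columns
#'   \code{cluster}, \code{state}, and (optionally) \code{batch}.
#' @param referenceState the state the odds ratios are relative to.
#' @param includeBatch include batch as a fixed covariate (default TRUE
#'   when a \code{batch} column is present).
#' @return data.frame with \code{cluster}, \code{contrast},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{p_adjusted}, \code{separation_flag}.
#' @examples
#' cells <- data.frame(
#'   cluster = rep(c("c1", "c2"), c(60, 140)),
#'   state = rep(c("DCIS", "tumor"), times = 100))
#' fitComposition(cells, referenceState = "DCIS")
#' @importFrom stats glm binomial coef qnorm pnorm
#' @export
fitComposition <- function(input, referenceState,
                           includeBatch = "batch" %in% colnames(input)) {
  stopifnot(all(c("cluster", "state") %in% colnames(input)))
  states <- unique(as.character(input$state))
  if (length(states) < 2L) stop("need >= 2 states")
  if (!referenceState %in% states)
    stop("reference state '", referenceState, "' not present")
  if (includeBatch && !"batch" %in% colnames(input))
    stop("'includeBatch' requires a 'batch' column")
  stateF <- stats::relevel(factor(input$state), ref = referenceState)
  clusters <- sort(unique(as.character(input$cluster)))
  altStates <- setdiff(levels(stateF), referenceState)

  rows <- list()
  for (k in clusters) {
    y <- as.integer(input$cluster == k)
    dat <- data.frame(y = y, state = stateF)
    if (includeBatch) dat$batch <- factor(input$batch)
    form <- if (includeBatch) y ~ state + batch else y ~ state
    fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
    sm <- summary(fit)$coefficients
    for (s in altStates) {
      term <- paste0("state", s)
      inRef <- sum(y == 1L & stateF == referenceState)
      outRef <- sum(y == 0L & stateF == referenceState)
      inAlt <- sum(y == 1L & stateF == s)
      outAlt <- sum(y == 0L & stateF == s)
      separated <- inRef == 0L || outRef == 0L || inAlt == 0L ||
        outAlt == 0L
      if (separated) {
        h <- .haldane(inRef, outRef, inAlt, outAlt)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, contrast = paste(s, "vs", referenceState),
          odds_ratio = h$or, ci_low = h$lo, ci_high = h$hi,
          p_value = h$p, separation_flag = TRUE,
          stringsAsFactors = FALSE)
      } else {
        est <- sm[term, "Estimate"]
        se <- sm[term, "Std. Error"]
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, contrast = paste(s, "vs", referenceState),
          odds_ratio = exp(est),
          ci_low = exp(est - qnorm(0.975) * se),
          ci_high = exp(est + qnorm(0.975) * se),
          p_value = sm[term, "Pr(>|z|)"], separation_flag = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (ct in unique(out$contrast)) {
    i <- out$contrast == ct
    out$p_adjusted[i] <- stats::p.adjust(out$p_value[i], method = "BH")
  }
  out
}

#' Per-state cluster counts and proportions
#'
#' @param input data.frame with columns \code{cluster} and \code{state}.
#' @return data.frame over the complete state x cluster grid (empty
#'   combinations reported as count 0) with \code{state}, \code{cluster},
#'   \code{count}, \code{proportion}; proportions sum to 1 within each
#'   state.
#' @export
compositionTable <- function(input) {
  stopifnot(all(c("cluster", "state") %in% colnames(input)))
  tab <- table(state = input$state, cluster = input$cluster)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(df) <- c("state", "cluster", "count")
  totals <- rowSums(tab)
  df$proportion <- df$count / totals[df$state]
  df[order(df$state, df$cluster), , drop = FALSE]
}
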