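#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval without continuity correction: with `z` the normal
#' quantile at `(1+confidence)/2` and `phat = successes/n`,
#' center `(phat + z^2/(2n)) / (1 + z^2/n)` and half-width
#' `z * sqrt(phat(1-phat)/n + z^2/(4n^2)) / (1 + z^2/n)`. Unlike the Wald
#' interval, both bounds always lie in `[0, 1]`.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, `n >= 1`.
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return A list of class `"proportionCI"` with elements `point`, `lower`,
#'   `upper`, `confidence`, `n`.
#' @examples
#' wilsonCI(160692, 271164)
#' @export
wilsonCI <- function(successes, n, confidence = 0.95) {
  if (length(n) != 1 || !is.finite(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (successes < 0 || successes > n) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + confidence) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  structure(
    list(
      point = phat, lower = center - half, upper = center + half,
      confidence = confidence, n = n
    ),
    class = "proportionCI"
  )
}

#' @export
print.proportionCI <- function(x, ...) {
  cat(sprintf(
    "%.4f  %g%% CI (%.4f, %.4f)  n = %d\n",
    x$point, 100 * x$confidence, x$lower, x$upper, as.integer(x$n)
  ))
  invisible(x)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic with df = (R-1)(C-1) and upper-tail chi-squared
#' p-value; no Yates continuity correction.
#'
#' @param table an R x C matrix of counts with all row and column sums > 0.
#' @return List with `statistic`, `df`, `p.value`, `expected`.
#' @export
chisqContingency <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) <= 0) || any(colSums(table) <= 0)) {
    stop("contingency table has a zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(
    statistic = unname(res$statistic), df = unname(res$parameter),
    p.value = unname(res$p.value), expected = res$expected
  )
}

#' Phenotype proportions with Wilson confidence intervals
#'
#' Builds a survey-style report: one row per stratum, one cell per phenotype
#' class formatted `"percent (lower-upper)"` at 2 decimals. CIs are computed
#' from integer counts (percent tables are converted via
#' [percentagesToCounts()] first), not from the rounded percentages.
#'
#' @param x a [PhenotypeTable-class].
#' @param confidence confidence level; default 0.95.
#' @return A data.frame with columns `label`, `n`, and the 8 classes.
#' @export
ciReport <- function(x, confidence = 0.95) {
  counts <- if (phenoUnit(x) == "percent") percentagesToCounts(x) else x
  v <- phenoValues(counts)
  n <- sampleSizes(counts)
  out <- data.frame(
    label = populationLabels(counts), n = unname(n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (cls in PHENO_CLASSES) {
    cell <- character(nrow(v))
    for (i in seq_len(nrow(v))) {
      ci <- wilsonCI(v[i, cls], n[i], confidence)
      cell[i] <- sprintf(
        "%.2f (%.2f-%.2f)",
        100 * ci$point, 100 * ci$lower, 100 * ci$upper
      )
    }
    out[[cls]] <- cell
  }
  out
}
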