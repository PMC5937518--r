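#' Expected ABO phenotype counts under Hardy-Weinberg equilibrium
#'
#' With allele frequencies (p, q, r) for (A, B, O):
#' `E_A = (p^2 + 2pr) n`, `E_B = (q^2 + 2qr) n`, `E_AB = 2pq n`,
#' `E_O = r^2 n`.
#'
#' @param alleles an [AlleleFreqSet-class] at the ABO locus, or a named
#'   `c(A=, B=, O=)` frequency vector summing to 1.
#' @param n sample size, > 0.
#' @return Named numeric vector `c(A, B, AB, O)` of expected counts.
#' @examples
#' expectedABOPhenotypes(c(A = 0.2, B = 0.1, O = 0.7), n = 1000)
#' @export
expectedABOPhenotypes <- function(alleles, n) {
  if (is(alleles, "AlleleFreqSet")) alleles <- alleleFreqs(alleles)
  if (abs(sum(alleles) - 1) > 1e-6) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  if (length(n) != 1 || !is.finite(n) || n <= 0) {
    stop("n must be a single positive number", call. = FALSE)
  }
  p <- alleles[["A"]]; q <- alleles[["B"]]; r <- alleles[["O"]]
  n * c(
    A = p^2 + 2 * p * r, B = q^2 + 2 * q * r,
    AB = 2 * p * q, O = r^2
  )
}

#' Hardy-Weinberg goodness-of-fit test at the ABO locus
#'
#' Allele frequencies are estimated by EM (maximum likelihood) from the same
#' counts; the Pearson chi-squared statistic is computed over the four
#' phenotype classes against the HWE-expected counts. Degrees of freedom are
#' 4 classes - 1 - 2 estimated allele frequencies = 1.
#'
#' @param observed named ABO phenotype counts `c(A=, B=, AB=, O=)`.
#' @param ... passed to [emABO()].
#' @return A list of class `"hweTest"`: `locus`, `statistic`, `df`,
#'   `p.value`, `expected`, `alleles`, `note`. If an expected class count is
#'   0 while the observed count is positive, `statistic` is `Inf`.
#' @examples
#' hweTestABO(c(A = 8747, B = 2856, AB = 707, O = 16896))
#' @export
hweTestABO <- function(observed, ...) {
  observed <- .aboPheno(observed)
  fit <- emABO(observed, ...)
  expected <- expectedABOPhenotypes(fit, sum(observed))
  if (any(expected == 0 & observed > 0)) {
    stat <- Inf
  } else {
    nz <- expected > 0
    stat <- sum((observed[nz] - expected[nz])^2 / expected[nz])
  }
  structure(
    list(
      locus = "ABO", statistic = stat, df = 1L,
      p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      expected = expected, alleles = fit, note = NULL
    ),
    class = "hweTest"
  )
}

#' Hardy-Weinberg test at the D locus (structurally saturated)
#'
#' With only 2 phenotype classes and 1 estimated allele frequency, the
#' maximum-likelihood fit reproduces the observed counts exactly: the
#' expected Rh-negative count is `n * (sqrt(f_dd))^2 = n * f_dd`. The
#' goodness-of-fit statistic is therefore identically 0 with 0 degrees of
#' freedom, and no p-value is defined.
#'
#' @param observed named Rh phenotype counts `c("D+" = , "D-" = )`.
#' @return A list of class `"hweTest"` with `statistic = 0`, `df = 0`,
#'   `p.value = NA` (not testable), and a `note` explaining the saturation.
#' @export
hweTestRH <- function(observed) {
  if (is.null(names(observed)) && length(observed) == 2) {
    names(observed) <- c("D+", "D-")
  }
  observed <- observed[c("D+", "D-")]
  ntot <- sum(observed)
  fit <- rhAlleleFreq(if (ntot > 0) observed[["D-"]] / ntot else 0)
  structure(
    list(
      locus = "RH", statistic = 0, df = 0L, p.value = NA_real_,
      expected = observed, alleles = fit,
      note = paste(
        "saturated model: 2 phenotype classes and 1 estimated allele",
        "frequency leave 0 degrees of freedom, so the ML fit is exact",
        "and the test is not defined"
      )
    ),
    class = "hweTest"
  )
}

#' @export
print.hweTest <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg goodness-of-fit, %s locus\n", x$locus))
  if (x$df > 0) {
    cat(sprintf(
      "chi-squared = %.4f, df = %d, p = %.4g\n",
      x$statistic, x$df, x$p.value
    ))
  } else {
    cat("chi-squared = 0, df = 0, p not testable\n")
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
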