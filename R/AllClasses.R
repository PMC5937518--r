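#' @import methods
NULL

## Canonical serialization order of the 8 ABO x Rh(D) phenotype classes.
PHENO_CLASSES <- c("A+", "A-", "B+", "B-", "AB+", "AB-", "O+", "O-")
ABO_GROUPS <- c("A", "B", "AB", "O")
RH_GROUPS <- c("D+", "D-")

## Tolerance for a percent-mode row total: table values are printed at 2
## decimals, so 8 cells can drift from 100 by up to 0.25 under rounding.
PERCENT_SUM_TOL <- 0.25

#' PhenotypeTable: stratified ABO x Rh(D) phenotype data
#'
#' Holds one row per population stratum (state, region, age band, gender, ...)
#' with its sample size and the 8 ABO x Rh(D) phenotype class values, either
#' as raw counts or as percentages. The class order is fixed as
#' (A+, A-, B+, B-, AB+, AB-, O+, O-).
#'
#' @slot values numeric matrix, strata x 8 phenotype classes; row names are
#'   the stratum labels.
#' @slot region character vector of region/group metadata, one per stratum.
#' @slot n numeric vector of sample sizes.
#' @slot unit `"count"` or `"percent"`.
#' @slot strata character, names of the stratification keys (metadata only).
#' @exportClass PhenotypeTable
setClass("PhenotypeTable",
  representation(
    values = "matrix",
    region = "character",
    n = "numeric",
    unit = "character",
    strata = "character"
  )
)

setValidity("PhenotypeTable", function(object) {
  v <- object@values
  msg <- character(0)
  if (!identical(colnames(v), PHENO_CLASSES)) {
    return(sprintf("values must have columns %s", paste(PHENO_CLASSES, collapse = ", ")))
  }
  if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v)))) {
    msg <- c(msg, "stratum labels (row names) must be present and unique")
  }
  if (length(object@n) != nrow(v) || length(object@region) != nrow(v)) {
    msg <- c(msg, "region and n must have one entry per stratum")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    msg <- c(msg, "phenotype values must be finite and non-negative")
  }
  if (any(!is.finite(object@n)) || any(object@n < 0)) {
    msg <- c(msg, "sample sizes must be finite and non-negative")
  }
  if (!(object@unit %in% c("count", "percent"))) {
    msg <- c(msg, "unit must be 'count' or 'percent'")
  }
  if (length(msg) == 0 && object@unit == "percent") {
    tot <- rowSums(v)
    bad <- which(abs(tot - 100) > PERCENT_SUM_TOL)
    if (length(bad) > 0) {
      msg <- c(msg, sprintf(
        "percent row '%s' sums to %.2f, outside 100 +/- %.2f",
        rownames(v)[bad[1]], tot[bad[1]], PERCENT_SUM_TOL
      ))
    }
  }
  if (length(msg) == 0 && object@unit == "count") {
    bad <- which(abs(rowSums(v) - object@n) > 1e-6)
    if (length(bad) > 0) {
      msg <- c(msg, sprintf(
        "count row '%s' sums to %s but n = %s",
        rownames(v)[bad[1]], rowSums(v)[bad[1]], object@n[bad[1]]
      ))
    }
  }
  if (length(msg) == 0) TRUE else msg
})

#' AlleleFreqSet: allele frequencies at one blood-group locus
#'
#' Allele frequencies at the ABO locus (alleles A, B, O for I^A, I^B, I^O) or
#' the D locus (alleles D, d), together with estimation metadata.
#'
#' @slot locus `"ABO"` or `"RH"`.
#' @slot freqs named numeric vector of allele frequencies; names are
#'   `c("A","B","O")` or `c("D","d")`.
#' @slot method estimation method: `"bernstein_raw"`, `"bernstein_corrected"`,
#'   `"em"`, or `"ml"` (closed-form square root, D locus).
#' @slot deviation Bernstein deviation D = 1 - (p+q+r); `NA` for other methods.
#' @slot loglik multinomial log-likelihood at the estimate (EM only, else `NA`).
#' @slot iterations number of EM iterations (EM only, else `NA`).
#' @slot converged logical; `FALSE` when EM stopped at `max_iter`.
#' @exportClass AlleleFreqSet
setClass("AlleleFreqSet",
  representation(
    locus = "character",
    freqs = "numeric",
    method = "character",
    deviation = "numeric",
    loglik = "numeric",
    iterations = "integer",
    converged = "logical"
  ),
  prototype(
    deviation = NA_real_, loglik = NA_real_,
    iterations = NA_integer_, converged = TRUE
  )
)

setValidity("AlleleFreqSet", function(object) {
  f <- object@freqs
  expected <- switch(object@locus,
    ABO = c("A", "B", "O"),
    RH = c("D", "d"),
    return("locus must be 'ABO' or 'RH'")
  )
  if (!identical(names(f), expected)) {
    return(sprintf("freqs must be named %s", paste(expected, collapse = ", ")))
  }
  if (any(!is.finite(f)) || any(f < -1e-12)) {
    return("allele frequencies must be finite and non-negative")
  }
  ## raw Bernstein estimates record p-hat, q-hat, r-hat before redistribution
  ## of the deviation, so their sum is deliberately not constrained
  if (object@method != "bernstein_raw" && abs(sum(f) - 1) > 1e-9) {
    return(sprintf("allele frequencies sum to %.12f, not 1", sum(f)))
  }
  TRUE
})
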