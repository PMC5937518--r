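## internal constructor
.afs <- function(locus, freqs, method, deviation = NA_real_,
                 loglik = NA_real_, iterations = NA_integer_,
                 converged = TRUE) {
  new("AlleleFreqSet",
    locus = locus, freqs = freqs, method = method,
    deviation = deviation, loglik = loglik,
    iterations = as.integer(iterations), converged = converged
  )
}

#' Accessors for AlleleFreqSet
#'
#' `alleleFreqs` returns the named frequency vector, `estimationMethod` the
#' method tag, `bernsteinDeviation` the deviation `D = 1 - (p+q+r)` (raw
#' Bernstein ABO estimates only), `emLogLik` and `emIterations` the EM
#' metadata, and `emConverged` whether EM met its tolerance.
#'
#' @param x an [AlleleFreqSet-class].
#' @name AlleleFreqSet-accessors
NULL

#' @rdname AlleleFreqSet-accessors
#' @export
alleleFreqs <- function(x) x@freqs

#' @rdname AlleleFreqSet-accessors
#' @export
estimationMethod <- function(x) x@method

#' @rdname AlleleFreqSet-accessors
#' @export
bernsteinDeviation <- function(x) x@deviation

#' @rdname AlleleFreqSet-accessors
#' @export
emLogLik <- function(x) x@loglik

#' @rdname AlleleFreqSet-accessors
#' @export
emIterations <- function(x) x@iterations

#' @rdname AlleleFreqSet-accessors
#' @export
emConverged <- function(x) x@converged

setMethod("show", "AlleleFreqSet", function(object) {
  cat(sprintf(
    "AlleleFreqSet (%s locus, method = %s)\n",
    object@locus, object@method
  ))
  print(round(object@freqs, 4))
  if (!is.na(object@deviation)) {
    cat(sprintf("Bernstein deviation D = %.6f\n", object@deviation))
  }
  if (!is.na(object@loglik)) {
    cat(sprintf(
      "logLik = %.4f after %d iteration(s)%s\n",
      object@loglik, object@iterations,
      if (object@converged) "" else " (NOT converged)"
    ))
  }
  invisible(NULL)
})

## named ABO phenotype vector in (A, B, AB, O) order, from any named input
.aboPheno <- function(pheno) {
  if (is.null(names(pheno)) && length(pheno) == 4) {
    names(pheno) <- c("A", "B", "AB", "O")
  }
  if (!all(c("A", "B", "AB", "O") %in% names(pheno))) {
    stop("ABO phenotype vector must be named A, B, AB, O", call. = FALSE)
  }
  pheno[c("A", "B", "AB", "O")]
}

#' Bernstein's square-root estimator of ABO allele frequencies
#'
#' Raw estimates from phenotype proportions: `r = sqrt(f_O)`,
#' `p = 1 - sqrt(f_O + f_B)`, `q = 1 - sqrt(f_O + f_A)`. Because the three
#' square roots do not sum exactly to 1 on finite samples, the deviation
#' `D = 1 - (p + q + r)` is redistributed by Bernstein's correction:
#' `p' = p(1 + D/2)`, `q' = q(1 + D/2)`, `r' = (r + D/2)(1 + D/2)`,
#' then renormalized to sum to 1.
#'
#' @param pheno named ABO phenotype proportions `c(A=, B=, AB=, O=)`,
#'   non-negative, summing to 1 within 1e-6.
#' @param correct if `TRUE` (default) return the corrected estimate; if
#'   `FALSE` the raw square-root estimate, whose `bernsteinDeviation`
#'   records D.
#' @return An [AlleleFreqSet-class] at the ABO locus.
#' @examples
#' bernsteinABO(c(A = 0.3293, B = 0.0856, AB = 0.0205, O = 0.5646))
#' @export
bernsteinABO <- function(pheno, correct = TRUE) {
  f <- .aboPheno(pheno)
  if (any(f < 0)) stop("phenotype frequencies must be non-negative", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-6) {
    stop("ABO phenotype frequencies must sum to 1 (got ", sum(f), ")",
      call. = FALSE
    )
  }
  if (f[["O"]] == 0 && f[["A"]] + f[["B"]] < 1) {
    stop("degenerate input: f_O = 0 with f_A + f_B < 1", call. = FALSE)
  }
  r <- sqrt(f[["O"]])
  p <- 1 - sqrt(f[["O"]] + f[["B"]])
  q <- 1 - sqrt(f[["O"]] + f[["A"]])
  D <- 1 - (p + q + r)
  if (!correct) {
    return(.afs("ABO", c(A = p, B = q, O = r), "bernstein_raw", deviation = D))
  }
  pc <- p * (1 + D / 2)
  qc <- q * (1 + D / 2)
  rc <- (r + D / 2) * (1 + D / 2)
  fc <- c(A = pc, B = qc, O = rc)
  fc <- pmax(fc, 0)
  fc <- fc / sum(fc)
  .afs("ABO", fc, "bernstein_corrected", deviation = D)
}

## multinomial log-likelihood of ABO phenotype counts under HWE
.aboLogLik <- function(counts, p, q, r) {
  probs <- c(p^2 + 2 * p * r, q^2 + 2 * q * r, 2 * p * q, r^2)
  ll <- 0
  for (k in 1:4) {
    if (counts[k] > 0) {
      if (probs[k] <= 0) return(-Inf)
      ll <- ll + counts[k] * log(probs[k])
    }
  }
  ll
}

#' EM maximum-likelihood estimate of ABO allele frequencies
#'
#' Gene-counting EM under Hardy-Weinberg equilibrium: the E-step splits the
#' dominant phenotype counts into latent genotype counts (A into AA:AO with
#' weights p^2 : 2pr, B likewise; AB and O are unambiguous), and the M-step
#' re-counts alleles over the expected genotype counts. Iteration stops when
#' the multinomial log-likelihood improves by less than `tol` or at
#' `maxIter`; the log-likelihood is non-decreasing across iterations.
#'
#' @param counts named ABO phenotype counts `c(A=, B=, AB=, O=)`, total >= 1.
#' @param tol stopping tolerance on the log-likelihood change (default 1e-10).
#' @param maxIter maximum number of iterations (default 1000).
#' @param init optional initial `c(A=, B=, O=)` allele frequencies summing
#'   to 1; default is the corrected Bernstein estimate, falling back to
#'   (1/3, 1/3, 1/3) when Bernstein is degenerate or hits a boundary.
#' @return An [AlleleFreqSet-class] with `emLogLik`, `emIterations` and
#'   `emConverged` filled in. Non-convergence at `maxIter` is flagged, not
#'   an error.
#' @examples
#' emABO(c(A = 13320, B = 3463, AB = 830, O = 22836))
#' @export
emABO <- function(counts, tol = 1e-10, maxIter = 1000L, init = NULL) {
  counts <- .aboPheno(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  ntot <- sum(counts)
  if (ntot < 1) stop("total phenotype count must be >= 1", call. = FALSE)
  if (is.null(init)) {
    init <- tryCatch(
      alleleFreqs(bernsteinABO(counts / ntot)),
      error = function(e) NULL
    )
    if (is.null(init) || any(init <= 0) || any(init >= 1)) {
      init <- c(A = 1 / 3, B = 1 / 3, O = 1 / 3)
    }
  } else {
    if (abs(sum(init) - 1) > 1e-9) stop("init must sum to 1", call. = FALSE)
    init <- stats::setNames(as.numeric(init), c("A", "B", "O"))
  }
  p <- init[["A"]]; q <- init[["B"]]; r <- init[["O"]]
  nA <- counts[["A"]]; nB <- counts[["B"]]
  nAB <- counts[["AB"]]; nO <- counts[["O"]]
  ll <- .aboLogLik(c(nA, nB, nAB, nO), p, q, r)
  iter <- 0L
  converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    ## E-step: expected genotype counts within the dominant phenotypes
    dA <- p^2 + 2 * p * r
    dB <- q^2 + 2 * q * r
    nAA <- if (dA > 0) nA * p^2 / dA else 0
    nAO <- nA - nAA
    nBB <- if (dB > 0) nB * q^2 / dB else 0
    nBO <- nB - nBB
    ## M-step: allele counting over expected genotype counts
    p <- (2 * nAA + nAO + nAB) / (2 * ntot)
    q <- (2 * nBB + nBO + nAB) / (2 * ntot)
    r <- 1 - p - q
    llNew <- .aboLogLik(c(nA, nB, nAB, nO), p, q, r)
    if (llNew < ll - 1e-8) {
      stop("EM log-likelihood decreased; this should not happen", call. = FALSE)
    }
    if (llNew - ll < tol) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  .afs("ABO", c(A = p, B = q, O = r), "em",
    loglik = ll, iterations = iter, converged = converged
  )
}

#' D-locus allele frequencies from Rh phenotype frequencies
#'
#' With d recessive under Hardy-Weinberg equilibrium the Rh-negative
#' phenotype equals the dd genotype, so `I^d = sqrt(f_Dneg)` and
#' `I^D = 1 - I^d`; this square-root estimator is also the maximum-likelihood
#' estimate.
#'
#' @param pheno either a single Rh-negative proportion, or a named vector
#'   `c("D+" = , "D-" = )` summing to 1 within 1e-6.
#' @return An [AlleleFreqSet-class] at the D locus.
#' @examples
#' rhAlleleFreq(0.0688)
#' @export
rhAlleleFreq <- function(pheno) {
  if (length(pheno) == 2) {
    if (is.null(names(pheno))) names(pheno) <- c("D+", "D-")
    if (any(pheno < 0)) stop("phenotype frequencies must be non-negative", call. = FALSE)
    if (abs(sum(pheno) - 1) > 1e-6) {
      stop("Rh phenotype frequencies must sum to 1", call. = FALSE)
    }
    fneg <- pheno[["D-"]]
  } else if (length(pheno) == 1) {
    fneg <- as.numeric(pheno)
    if (fneg < 0 || fneg > 1) {
      stop("Rh-negative proportion must lie in [0, 1]", call. = FALSE)
    }
  } else {
    stop("pheno must be a proportion or a length-2 vector", call. = FALSE)
  }
  d <- sqrt(fneg)
  .afs("RH", c(D = 1 - d, d = d), "ml")
}

#' Per-population allele frequencies at both loci
#'
#' Estimates ABO (EM by default, or corrected Bernstein) and D-locus allele
#' frequencies for every stratum of a phenotype table. Percent tables are
#' converted to counts first; the EM runs on integer counts.
#'
#' @param x a [PhenotypeTable-class].
#' @param estimator `"em"` (default) or `"bernstein"` for the ABO locus.
#' @param tol,maxIter EM settings, see [emABO()].
#' @return A list per stratum, each with elements `ABO` and `RH`
#'   ([AlleleFreqSet-class] objects).
#' @export
alleleFrequencies <- function(x, estimator = c("em", "bernstein"),
                              tol = 1e-10, maxIter = 1000L) {
  estimator <- match.arg(estimator)
  counts <- if (phenoUnit(x) == "percent") percentagesToCounts(x) else x
  abo <- marginalize(counts, "ABO", proportions = FALSE)
  rh <- marginalize(counts, "RH", proportions = TRUE)
  out <- lapply(seq_len(nrow(abo)), function(i) {
    aboFit <- if (estimator == "em") {
      emABO(abo[i, ], tol = tol, maxIter = maxIter)
    } else {
      bernsteinABO(abo[i, ] / sum(abo[i, ]))
    }
    list(ABO = aboFit, RH = rhAlleleFreq(rh[i, "D-"]))
  })
  names(out) <- populationLabels(x)
  out
}

#' Population x allele frequency matrix
#'
#' Stacks the per-population estimates of [alleleFrequencies()] into the
#' matrix used by the distance and ordination stages, with columns
#' `A`, `B`, `O` (ABO locus) and `d`, `D` (D locus).
#'
#' @inheritParams alleleFrequencies
#' @return Numeric matrix, strata x 5.
#' @export
alleleFreqMatrix <- function(x, estimator = c("em", "bernstein")) {
  fits <- alleleFrequencies(x, estimator = match.arg(estimator))
  m <- t(vapply(fits, function(f) {
    c(alleleFreqs(f$ABO), alleleFreqs(f$RH)[c("d", "D")])
  }, numeric(5)))
  colnames(m) <- c("A", "B", "O", "d", "D")
  m
}
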