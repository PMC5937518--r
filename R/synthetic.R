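#' Simulation configuration for synthetic phenotype tables
#'
#' Defines the ground truth for the multinomial phenotype simulator: per
#' population a label, region, sample size, ABO allele frequencies
#' (p = I^A, q = I^B, r = I^O), the D-allele frequency `dD = I^D`, and an
#' inbreeding coefficient F in `[0, 1]` (the single Hardy-Weinberg-violation
#' knob), plus one master seed.
#'
#' @param populations data.frame with columns `label`, `n`, `p`, `q`, `r`,
#'   `dD`, and optionally `region` (default `""`) and `F` (default 0).
#' @param seed master integer seed.
#' @return A list of class `"simConfig"`.
#' @examples
#' cfg <- simConfig(data.frame(label = "Pop1", n = 1000,
#'                             p = 0.2, q = 0.1, r = 0.7, dD = 0.8), seed = 7)
#' simulateTable(cfg)
#' @export
simConfig <- function(populations, seed = 1L) {
  populations <- as.data.frame(populations)
  if (!"region" %in% names(populations)) populations$region <- ""
  if (!"F" %in% names(populations)) populations$F <- 0
  need <- c("label", "n", "p", "q", "r", "dD", "F")
  missing <- setdiff(need, names(populations))
  if (length(missing) > 0) {
    stop("simConfig missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- abs(populations$p + populations$q + populations$r - 1) > 1e-9
  if (any(bad)) {
    stop("p + q + r must sum to 1 (row ", which(bad)[1], ")", call. = FALSE)
  }
  if (any(populations$dD < 0 | populations$dD > 1)) {
    stop("dD must lie in [0, 1]", call. = FALSE)
  }
  if (any(populations$F < 0 | populations$F > 1)) {
    stop("F must lie in [0, 1]", call. = FALSE)
  }
  if (any(populations$n < 1)) stop("n must be >= 1", call. = FALSE)
  if (anyDuplicated(populations$label)) {
    stop("population labels must be unique", call. = FALSE)
  }
  cols <- c("label", "region", "n", "p", "q", "r", "dD", "F")
  structure(
    list(populations = populations[, cols], seed = as.integer(seed)),
    class = "simConfig"
  )
}

#' Phenotype class probabilities under HWE with inbreeding
#'
#' Genotype probabilities follow the inbreeding-adjusted Hardy-Weinberg
#' model: homozygote `p_i^2 + F p_i (1 - p_i)`, heterozygote
#' `2 p_i p_j (1 - F)`. ABO genotypes collapse to the 4 ABO phenotypes
#' (A = AA + AO, B = BB + BO, AB, O = OO); at the D locus the Rh-negative
#' phenotype is the dd genotype. The two loci combine independently into
#' the 8 joint classes, whose probabilities sum to 1 for all valid inputs.
#'
#' @param p,q,r ABO allele frequencies (I^A, I^B, I^O), summing to 1.
#' @param dD D-allele frequency I^D in `[0, 1]`.
#' @param F inbreeding coefficient in `[0, 1]`; default 0 (HWE).
#' @return Named numeric vector of 8 probabilities in the canonical class
#'   order.
#' @examples
#' genotypePhenotypeProbs(0.2, 0.1, 0.7, dD = 0.8)
#' @export
genotypePhenotypeProbs <- function(p, q, r, dD, F = 0) {
  if (abs(p + q + r - 1) > 1e-9) stop("p + q + r must equal 1", call. = FALSE)
  if (any(c(p, q, r) < 0) || dD < 0 || dD > 1 || F < 0 || F > 1) {
    stop("invalid frequency or inbreeding coefficient", call. = FALSE)
  }
  pA <- p^2 + F * p * (1 - p) + 2 * p * r * (1 - F)
  pB <- q^2 + F * q * (1 - q) + 2 * q * r * (1 - F)
  pAB <- 2 * p * q * (1 - F)
  pO <- r^2 + F * r * (1 - r)
  dd <- 1 - dD
  pNeg <- dd^2 + F * dd * (1 - dd)
  pPos <- 1 - pNeg
  probs <- c(
    "A+" = pA * pPos, "A-" = pA * pNeg,
    "B+" = pB * pPos, "B-" = pB * pNeg,
    "AB+" = pAB * pPos, "AB-" = pAB * pNeg,
    "O+" = pO * pPos, "O-" = pO * pNeg
  )
  probs
}

#' Simulate a phenotype table from known allele frequencies
#'
#' One multinomial draw of size n per population over the 8 phenotype class
#' probabilities of [genotypePhenotypeProbs()]. Each population uses a seed
#' substream derived from the master seed and the population label, so
#' adding a population does not perturb the draws of the others, and the
#' same configuration always yields the same table.
#'
#' @param config a [simConfig()] object.
#' @return A count-mode [PhenotypeTable-class] ready for the full pipeline.
#' @export
simulateTable <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  pops <- config$populations
  v <- matrix(0, nrow(pops), length(PHENO_CLASSES),
    dimnames = list(pops$label, PHENO_CLASSES)
  )
  for (i in seq_len(nrow(pops))) {
    probs <- genotypePhenotypeProbs(
      pops$p[i], pops$q[i], pops$r[i], pops$dD[i], pops$F[i]
    )
    set.seed(deriveSeed(config$seed, pops$label[i]))
    v[i, ] <- stats::rmultinom(1, pops$n[i], probs)
  }
  phenotypeTable(v, n = pops$n, unit = "count", region = pops$region)
}

#' Read / write a simulation configuration as JSON
#'
#' @param path JSON file path.
#' @return `readSimConfig` returns a [simConfig()] object; `writeSimConfig`
#'   returns `path` invisibly.
#' @export
readSimConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simConfig(as.data.frame(x$populations), seed = x$seed)
}

#' @rdname readSimConfig
#' @param config a [simConfig()] object.
#' @export
writeSimConfig <- function(config, path) {
  jsonlite::write_json(
    list(populations = config$populations, seed = config$seed),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Survey-like simulation configuration
#'
#' Builds a configuration that mirrors the packaged state survey: allele
#' frequencies re-estimated from the bundled per-state table and the
#' per-state sample sizes, with F = 0 (HWE) everywhere.
#'
#' @param seed master seed.
#' @return A [simConfig()] object with 17 populations.
#' @export
surveySimConfig <- function(seed = 1L) {
  tab <- readPhenotypeTable(
    system.file("extdata", "table2_states.csv", package = "seropop"),
    unit = "percent"
  )
  tab <- tab[populationLabels(tab) != "Total"]
  m <- alleleFreqMatrix(tab)
  simConfig(
    data.frame(
      label = populationLabels(tab), region = unname(regionLabels(tab)),
      n = unname(sampleSizes(tab)),
      p = m[, "A"], q = m[, "B"], r = m[, "O"], dD = m[, "D"], F = 0
    ),
    seed = seed
  )
}
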