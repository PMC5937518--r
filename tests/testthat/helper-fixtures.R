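# shared fixtures: the packaged state survey and small synthetic tables

stateTable <- function() {
  tab <- readPhenotypeTable(
    system.file("extdata", "table2_states.csv", package = "seropop"),
    unit = "percent"
  )
  tab[populationLabels(tab) != "Total"]
}

stateCounts <- function() percentagesToCounts(stateTable())

# ABO marginal counts for one state
aboCounts <- function(label) {
  m <- marginalize(stateCounts(), "ABO", proportions = FALSE)
  m[label, ]
}

# a small deterministic synthetic survey with known truth
toySim <- function(seed = 11, n = c(5000, 5000, 5000)) {
  simConfig(
    data.frame(
      label = c("PopA", "PopB", "PopC"),
      region = c("r1", "r1", "r2"),
      n = n,
      p = c(0.20, 0.18, 0.10),
      q = c(0.06, 0.07, 0.03),
      r = c(0.74, 0.75, 0.87),
      dD = c(0.75, 0.77, 0.87),
      F = 0
    ),
    seed = seed
  )
}

# multinomial ABO phenotype counts at exact HWE proportions
hweAboDraw <- function(p, q, r, n) {
  probs <- c(A = p^2 + 2 * p * r, B = q^2 + 2 * q * r, AB = 2 * p * q, O = r^2)
  x <- stats::rmultinom(1, n, probs)[, 1]
  stats::setNames(unname(x), c("A", "B", "AB", "O"))
}

# multinomial log-likelihood of ABO phenotype counts under HWE (test oracle)
aboLogLik <- function(counts, f) {
  p <- f[["A"]]; q <- f[["B"]]; r <- f[["O"]]
  probs <- c(p^2 + 2 * p * r, q^2 + 2 * q * r, 2 * p * q, r^2)
  counts <- counts[c("A", "B", "AB", "O")]
  sum(ifelse(counts > 0, counts * log(probs), 0))
}
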