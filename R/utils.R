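## Deterministic substream seeds: one master integer seed plus a string or
## integer key (population label, bootstrap replicate number). The key is
## hashed with a 31-multiplier polynomial rolling hash modulo 2^31 - 1, so
## substreams do not depend on the order in which they are drawn.
deriveSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

## Vectorized allele-frequency estimation over all rows of an 8-class count
## matrix at once, without building S4 objects; used in the bootstrap inner
## loop. Agrees with emABO()/bernsteinABO()/rhAlleleFreq() row by row.
.fastFreqMatrix <- function(v, estimator = "em", tol = 1e-10, maxIter = 1000L) {
  nA <- v[, "A+"] + v[, "A-"]
  nB <- v[, "B+"] + v[, "B-"]
  nAB <- v[, "AB+"] + v[, "AB-"]
  nO <- v[, "O+"] + v[, "O-"]
  ntot <- nA + nB + nAB + nO
  fA <- nA / ntot; fB <- nB / ntot; fO <- nO / ntot
  ## corrected Bernstein start (vectorized)
  r <- sqrt(fO)
  p <- 1 - sqrt(fO + fB)
  q <- 1 - sqrt(fO + fA)
  D <- 1 - (p + q + r)
  p <- p * (1 + D / 2)
  q <- q * (1 + D / 2)
  r <- (r + D / 2) * (1 + D / 2)
  p <- pmax(p, 0); q <- pmax(q, 0); r <- pmax(r, 0)
  s <- p + q + r
  p <- p / s; q <- q / s; r <- r / s
  bad <- !is.finite(p) | !is.finite(q) | !is.finite(r) |
    p <= 0 | q <= 0 | r <= 0
  p[bad] <- 1 / 3; q[bad] <- 1 / 3; r[bad] <- 1 / 3
  if (estimator == "em") {
    llOf <- function(p, q, r) {
      term <- function(cnt, prob) ifelse(cnt > 0, cnt * log(pmax(prob, 1e-300)), 0)
      term(nA, p^2 + 2 * p * r) + term(nB, q^2 + 2 * q * r) +
        term(nAB, 2 * p * q) + term(nO, r^2)
    }
    ll <- llOf(p, q, r)
    for (it in seq_len(maxIter)) {
      dA <- p^2 + 2 * p * r
      dB <- q^2 + 2 * q * r
      nAA <- ifelse(dA > 0, nA * p^2 / dA, 0)
      nBB <- ifelse(dB > 0, nB * q^2 / dB, 0)
      p <- (2 * nAA + (nA - nAA) + nAB) / (2 * ntot)
      q <- (2 * nBB + (nB - nBB) + nAB) / (2 * ntot)
      r <- 1 - p - q
      llNew <- llOf(p, q, r)
      if (max(llNew - ll) < tol) break
      ll <- llNew
    }
  }
  dpos <- v[, "A+"] + v[, "B+"] + v[, "AB+"] + v[, "O+"]
  d <- sqrt(1 - dpos / ntot)
  cbind(A = p, B = q, O = r, d = d, D = 1 - d)
}

## DA / Nei-standard distance matrix straight from a populations x 5
## frequency matrix (columns A, B, O, d, D); matches geneticDistances().
.fastDistanceMatrix <- function(m, method = "da") {
  abo <- m[, c("A", "B", "O"), drop = FALSE]
  rh <- m[, c("d", "D"), drop = FALSE]
  if (method == "da") {
    bc <- (tcrossprod(sqrt(abo)) + tcrossprod(sqrt(rh))) / 2
    dm <- 1 - bc
    dm[dm < 0] <- 0
    dm[dm > 1] <- 1
  } else {
    jxy <- (tcrossprod(abo) + tcrossprod(rh)) / 2
    j <- diag(jxy)
    I <- jxy / sqrt(outer(j, j))
    dm <- -log(I)
    dm[dm < 0] <- 0
  }
  diag(dm) <- 0
  dm <- (dm + t(dm)) / 2
  rownames(dm) <- colnames(dm) <- rownames(m)
  dm
}
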