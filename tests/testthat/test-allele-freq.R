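test_that("Bernstein estimator reproduces survey values and closed forms", {
  # Sinaloa ABO marginals as printed
  f <- c(A = 0.3293, B = 0.0856, AB = 0.0205, O = 0.5646)
  est <- bernsteinABO(f)
  expect_lt(abs(alleleFreqs(est)[["A"]] - 0.1937), 6e-5)
  expect_equal(sum(alleleFreqs(est)), 1)
  # raw estimate and deviation retrievable; the raw square root of the
  # O-phenotype frequency is the printed O-allele value
  raw <- bernsteinABO(f, correct = FALSE)
  expect_equal(unname(alleleFreqs(raw)[["O"]]), sqrt(0.5646))
  expect_lt(abs(alleleFreqs(raw)[["O"]] - 0.7514), 6e-5)
  expect_equal(
    bernsteinDeviation(raw),
    1 - sum(1 - sqrt(0.5646 + 0.0856), 1 - sqrt(0.5646 + 0.3293), sqrt(0.5646))
  )
  # Jalisco raw A-allele closed form
  rawJ <- bernsteinABO(
    c(A = 0.2995, B = 0.0978, AB = 0.0242, O = 0.5785),
    correct = FALSE
  )
  expect_equal(unname(alleleFreqs(rawJ)[["A"]]), 1 - sqrt(0.5785 + 0.0978),
    tolerance = 1e-12
  )
  expect_equal(round(alleleFreqs(rawJ)[["A"]], 4), 0.1776, ignore_attr = TRUE)
  # fixed point: all-O population
  fo <- bernsteinABO(c(A = 0, B = 0, AB = 0, O = 1))
  expect_equal(unname(alleleFreqs(fo)), c(0, 0, 1))
  expect_equal(bernsteinDeviation(bernsteinABO(c(A = 0, B = 0, AB = 0, O = 1),
    correct = FALSE
  )), 0)
  # errors
  expect_error(bernsteinABO(c(A = 0.5, B = 0.3, AB = 0.2, O = 0)), "degenerate")
  expect_error(bernsteinABO(c(A = -0.1, B = 0.4, AB = 0.2, O = 0.5)), "non-negative")
})

test_that("EM is a fixed point on exact HWE data and matches direct ML", {
  p <- 0.2; q <- 0.1; r <- 0.7
  counts <- 10000 * c(
    A = p^2 + 2 * p * r, B = q^2 + 2 * q * r, AB = 2 * p * q, O = r^2
  )
  est <- emABO(counts)
  expect_equal(unname(alleleFreqs(est)), c(p, q, r), tolerance = 1e-6)
  expect_true(emConverged(est))
  # direct 2-parameter ML via optim agrees on rough data
  set.seed(7)
  for (i in 1:5) {
    x <- hweAboDraw(0.25, 0.08, 0.67, 3000)
    em <- alleleFreqs(emABO(x))
    opt <- stats::optim(
      c(0.3, 0.1),
      function(th) -aboLogLik(x, c(A = th[1], B = th[2], O = 1 - sum(th))),
      method = "L-BFGS-B", lower = 1e-6, upper = 0.999
    )
    expect_equal(unname(em[c("A", "B")]), opt$par, tolerance = 1e-4)
  }
})

test_that("EM reproduces the printed Sinaloa allele frequencies from counts", {
  est <- emABO(aboCounts("Sinaloa"))
  expect_lt(abs(alleleFreqs(est)[["A"]] - 0.1937), 1e-3)
  expect_lt(abs(alleleFreqs(est)[["B"]] - 0.0549), 1e-3)
  expect_lt(abs(alleleFreqs(est)[["O"]] - 0.7514), 1e-3)
})

test_that("EM log-likelihood never decreases and improves on its start", {
  set.seed(21)
  for (i in 1:20) {
    f <- as.vector(stats::rmultinom(1, 2000, c(0.3, 0.1, 0.05, 0.55)))
    x <- stats::setNames(f, c("A", "B", "AB", "O"))
    init <- as.vector(prop.table(stats::runif(3) + 0.05))
    est <- emABO(x, init = init) # errors internally if loglik ever drops
    expect_gte(
      emLogLik(est),
      aboLogLik(x, stats::setNames(init, c("A", "B", "O"))) - 1e-9
    )
    expect_equal(sum(alleleFreqs(est)), 1, tolerance = 1e-12)
  }
})

test_that("EM estimates are invariant to count scaling", {
  x <- aboCounts("Jalisco")
  expect_equal(
    alleleFreqs(emABO(x)), alleleFreqs(emABO(x * 7)),
    tolerance = 1e-8
  )
})

test_that("corrected Bernstein and EM agree closely at survey sample sizes", {
  counts <- stateCounts()
  m <- marginalize(counts, "ABO", proportions = FALSE)
  for (lab in rownames(m)) {
    em <- alleleFreqs(emABO(m[lab, ]))
    bn <- alleleFreqs(bernsteinABO(m[lab, ] / sum(m[lab, ])))
    expect_true(all(abs(em - bn) <= 0.001), label = lab)
  }
})

test_that("EM recovers generating frequencies from multinomial sampling", {
  # mean absolute error over 200 simulations at n = 5000
  set.seed(31)
  p <- 0.16; q <- 0.06; r <- 0.78
  errs <- replicate(200, {
    est <- alleleFreqs(emABO(hweAboDraw(p, q, r, 5000)))
    abs(est - c(A = p, B = q, O = r))
  })
  expect_true(all(rowMeans(errs) < 0.01))
})

test_that("D-locus square-root estimator", {
  est <- rhAlleleFreq(0.0688)
  expect_lt(abs(alleleFreqs(est)[["d"]] - 0.2623), 6e-5)
  expect_equal(sum(alleleFreqs(est)), 1)
  expect_equal(unname(alleleFreqs(rhAlleleFreq(1))[["d"]]), 1)
  # national Rh(d) proportion
  expect_equal(unname(alleleFreqs(rhAlleleFreq(0.0442))[["d"]]), sqrt(0.0442))
  expect_equal(round(sqrt(0.0442), 4), 0.2102)
  # named two-vector form
  est2 <- rhAlleleFreq(c("D+" = 0.9312, "D-" = 0.0688))
  expect_equal(alleleFreqs(est2), alleleFreqs(est))
  expect_error(rhAlleleFreq(-0.1), "\\[0, 1\\]")
})

test_that("per-table estimation stacks both loci into a labeled matrix", {
  m <- alleleFreqMatrix(stateCounts())
  expect_equal(dim(m), c(17, 5))
  expect_equal(colnames(m), c("A", "B", "O", "d", "D"))
  expect_equal(unname(rowSums(m[, c("A", "B", "O")])), rep(1, 17))
  expect_equal(unname(rowSums(m[, c("d", "D")])), rep(1, 17))
})
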