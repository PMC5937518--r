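test_that("genetic distances: closed forms, identity, symmetry, bounds", {
  x <- list(L = c(1, 0))
  y <- list(L = c(0.5, 0.5))
  expect_equal(neiStandardDistance(x, y), -log(0.5 / sqrt(1 * 0.5)), tolerance = 1e-12)
  expect_equal(round(neiStandardDistance(x, y), 4), 0.3466)
  expect_equal(neiStandardDistance(x, x), 0)
  expect_equal(daDistance(x, x), 0)
  # disjoint support at every locus
  expect_equal(daDistance(
    list(L1 = c(1, 0), L2 = c(0, 1)),
    list(L1 = c(0, 1), L2 = c(1, 0))
  ), 1)
  # one disjoint locus, one identical locus
  expect_equal(daDistance(
    list(L1 = c(1, 0), L2 = c(1, 0)),
    list(L1 = c(0, 1), L2 = c(1, 0))
  ), 0.5)
  # error when a population is fixed-free (zero homozygosity impossible, so
  # exercise the guard with a degenerate zero vector)
  expect_error(
    neiStandardDistance(list(L = c(0, 0)), list(L = c(1, 0))),
    "zero mean homozygosity"
  )
  # fixture-level sanity: random pairs are symmetric with DA <= 1
  dm <- geneticDistances(stateCounts(), "da")
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  # neighboring northwest states are closer than cross-country pairs
  expect_lt(dm["Sinaloa", "Sonora"], dm["Sinaloa", "Puebla"])
  dmn <- geneticDistances(stateCounts(), "nei")
  expect_lt(dmn["Sinaloa", "Sonora"], dmn["Sinaloa", "Puebla"])
})

test_that("NJ recovers the generating tree from a 4-taxon additive matrix", {
  dm <- matrix(c(
    0, 3, 5, 6,
    3, 0, 6, 7,
    5, 6, 0, 7,
    6, 7, 7, 0
  ), 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(dm)
  expect_s3_class(tr, "phylo")
  expect_equal(tr$Nnode, 2L)
  # split AB|CD present
  splits <- lapply(ape::prop.part(tr), function(b) sort(tr$tip.label[b]))
  expect_true(any(vapply(splits, function(s) {
    identical(s, c("A", "B")) || identical(s, c("C", "D"))
  }, logical(1))))
  # path lengths reproduce the input exactly (additivity)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(dm), rownames(dm)],
    dm,
    tolerance = 1e-12
  )
  # leaf edges are 1,2,3,4 and the internal edge 1
  tipEdges <- tr$edge.length[match(seq_len(4), tr$edge[, 2])]
  expect_equal(sort(tipEdges), c(1, 2, 3, 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("NJ equals the path-length oracle on random additive matrices", {
  set.seed(17)
  for (i in 1:20) {
    nl <- sample(4:10, 1)
    ref <- ape::rtree(nl, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 2))
    dm <- as.matrix(ape::cophenetic.phylo(ref))
    tr <- neighborJoining(dm)
    # the reconstructed path-length matrix equals the input
    got <- as.matrix(ape::cophenetic.phylo(tr))[rownames(dm), rownames(dm)]
    expect_equal(got, dm, tolerance = 1e-8)
    # and the topology matches the generating tree (independent check)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), tr)), 0)
    # unrooted binary: n - 3 internal edges, n - 2 internal nodes
    expect_equal(tr$Nnode, nl - 2L)
    expect_equal(sum(tr$edge[, 2] > nl), nl - 3L)
  }
})

test_that("NJ edge cases: 3 taxa, invalid input, negative-branch clamping", {
  dm3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
    dimnames = list(c("x", "y", "z"), c("x", "y", "z"))
  )
  tr <- neighborJoining(dm3)
  expect_equal(tr$Nnode, 1L)
  # closed-form star edge lengths
  expect_equal(sort(tr$edge.length), sort(c(0, 2, 3)))
  expect_error(neighborJoining(dm3[1:2, 1:2]), "at least 3")
  bad <- dm3; bad[1, 2] <- 9
  expect_error(neighborJoining(bad), "symmetric")
  # a non-additive matrix that forces a negative NJ branch still yields
  # non-negative lengths with pairwise sums preserved
  dm4 <- matrix(c(
    0, 1, 6, 6,
    1, 0, 6, 6,
    6, 6, 0, 1,
    6, 6, 1, 0
  ), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm4[1, 2] <- dm4[2, 1] <- 7 # near-star, pushes a length negative
  tr4 <- neighborJoining(dm4)
  expect_true(all(tr4$edge.length >= 0))
})

test_that("bootstrap support is deterministic and structure-sensitive", {
  cfg <- simConfig(
    data.frame(
      label = c("A1", "A2", "B1", "B2", "C1", "C2"),
      n = 4000,
      p = c(0.35, 0.35, 0.10, 0.10, 0.200, 0.201),
      q = c(0.02, 0.02, 0.15, 0.15, 0.060, 0.060),
      r = c(0.63, 0.63, 0.75, 0.75, 0.740, 0.739),
      dD = c(0.60, 0.60, 0.95, 0.95, 0.800, 0.800),
      F = 0
    ),
    seed = 5
  )
  tab <- simulateTable(cfg)
  tr1 <- bootstrapSupport(tab, replicates = 200, seed = 99)
  tr2 <- bootstrapSupport(tab, replicates = 200, seed = 99)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- as.numeric(tr1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  # support for the well-separated {A1,A2} split exceeds the support of the
  # nearly-identical {C1,C2} split
  parts <- ape::prop.part(tr1)
  labelOf <- function(pair) {
    idx <- which(vapply(parts, function(b) {
      setequal(tr1$tip.label[b], pair) ||
        setequal(tr1$tip.label[-b], pair)
    }, logical(1)))
    if (length(idx) == 0) return(0)
    as.numeric(tr1$node.label[idx[1]])
  }
  expect_gt(labelOf(c("A1", "A2")), labelOf(c("C1", "C2")))
  # single replicate: support values are 0 or 100
  tr3 <- bootstrapSupport(tab, replicates = 1, seed = 3)
  expect_true(all(as.numeric(tr3$node.label) %in% c(0, 100)))
})

test_that("Newick output carries 6-decimal branch lengths and support labels", {
  dm <- geneticDistances(stateCounts()[c("Sinaloa", "Sonora", "Puebla", "Veracruz")])
  tr <- neighborJoining(dm)
  f <- tempfile(fileext = ".nwk")
  writeTreeNewick(tr, f)
  txt <- readLines(f)
  expect_match(txt, "^\\(.*\\);$")
  reread <- ape::read.tree(f)
  expect_setequal(reread$tip.label, gsub(" ", "_", rownames(dm)))
})
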