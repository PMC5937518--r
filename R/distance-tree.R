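## coerce one population's frequencies to list(ABO = numeric, RH = numeric)
.freqList <- function(x) {
  lapply(x, function(f) if (is(f, "AlleleFreqSet")) alleleFreqs(f) else f)
}

#' Nei's standard genetic distance
#'
#' `D = -ln(I)` with the normalized identity `I = J_xy / sqrt(J_x J_y)`,
#' where `J_xy` is the mean over loci of `sum_i x_i y_i` and `J_x`, `J_y`
#' are the corresponding mean homozygosities.
#'
#' @param x,y per-population allele frequencies: named lists with one
#'   numeric frequency vector per locus (or [AlleleFreqSet-class] objects),
#'   covering the same loci and alleles.
#' @return A non-negative number; 0 for identical populations.
#' @examples
#' neiStandardDistance(list(L = c(1, 0)), list(L = c(0.5, 0.5)))
#' @export
neiStandardDistance <- function(x, y) {
  x <- .freqList(x); y <- .freqList(y)
  stopifnot(length(x) == length(y))
  jxy <- mean(vapply(seq_along(x), function(l) sum(x[[l]] * y[[l]]), numeric(1)))
  jx <- mean(vapply(x, function(v) sum(v^2), numeric(1)))
  jy <- mean(vapply(y, function(v) sum(v^2), numeric(1)))
  if (jx <= 0 || jy <= 0) {
    stop("zero mean homozygosity; Nei standard distance undefined", call. = FALSE)
  }
  I <- jxy / sqrt(jx * jy)
  max(0, -log(I))
}

#' DA genetic distance
#'
#' `DA = 1 - (1/L) sum_loci sum_alleles sqrt(x_i y_i)`, bounded in `[0, 1]`:
#' 0 for identical populations, 1 when the two populations share no alleles
#' at any locus.
#'
#' @inheritParams neiStandardDistance
#' @return A number in `[0, 1]`.
#' @export
daDistance <- function(x, y) {
  x <- .freqList(x); y <- .freqList(y)
  stopifnot(length(x) == length(y))
  bc <- mean(vapply(seq_along(x), function(l) {
    sum(sqrt(x[[l]] * y[[l]]))
  }, numeric(1)))
  min(max(1 - bc, 0), 1)
}

#' Pairwise genetic distance matrix over the ABO and D loci
#'
#' @param x a [PhenotypeTable-class] (frequencies are estimated with
#'   [alleleFrequencies()]), or a named list of per-population frequency
#'   lists as accepted by [daDistance()].
#' @param method `"da"` (default) or `"nei"` (standard distance).
#' @param estimator ABO estimator when `x` is a table.
#' @return Symmetric numeric matrix with zero diagonal and population
#'   labels as dimnames.
#' @export
geneticDistances <- function(x, method = c("da", "nei"),
                             estimator = c("em", "bernstein")) {
  method <- match.arg(method)
  freqs <- if (is(x, "PhenotypeTable")) {
    alleleFrequencies(x, estimator = match.arg(estimator))
  } else {
    x
  }
  k <- length(freqs)
  dm <- matrix(0, k, k, dimnames = list(names(freqs), names(freqs)))
  fun <- if (method == "da") daDistance else neiStandardDistance
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      dm[i, j] <- dm[j, i] <- fun(freqs[[i]], freqs[[j]])
    }
  }
  dm
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion `Q_ij = (m-2) d_ij - R_i - R_j`, compute branch lengths by
#' the standard formulas, reduce the matrix, and finish with the 3-leaf
#' star. Ties on Q are broken by the smallest (i, j) index pair. A negative
#' branch length is clamped to 0 with the deficit moved to its sibling edge
#' (their sum is preserved). On an additive matrix the tree's path-length
#' matrix reproduces the input exactly.
#'
#' @param dm symmetric non-negative distance matrix with zero diagonal,
#'   labels as dimnames, at least 3 taxa.
#' @return An unrooted binary tree of class `"phylo"` (ape).
#' @examples
#' dm <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighborJoining(dm)
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12 || any(dm < 0)) {
    stop("distance matrix must be symmetric and non-negative", call. = FALSE)
  }
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  ids <- seq_len(n) # phylo node ids of the active clusters
  d <- dm
  ## internal nodes are numbered downward from 2n-2 so the final 3-way
  ## center ends up as n+1, ape's root id
  nextInternal <- 2L * n - 2L
  edge <- matrix(0L, 0, 2)
  elen <- numeric(0)
  while (length(ids) > 3) {
    m <- length(ids)
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
    u <- nextInternal
    nextInternal <- nextInternal - 1L
    edge <- rbind(edge, c(u, ids[i]), c(u, ids[j]))
    elen <- c(elen, bi, bj)
    keep <- setdiff(seq_len(m), c(i, j))
    dNew <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dNew), c(dNew, 0))
    ids <- c(ids[keep], u)
  }
  v <- nextInternal # == n + 1
  b <- c(
    (d[1, 2] + d[1, 3] - d[2, 3]) / 2,
    (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
    (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  )
  b <- pmax(b, 0)
  edge <- rbind(edge, c(v, ids[1]), c(v, ids[2]), c(v, ids[3]))
  elen <- c(elen, b)
  tr <- structure(
    list(
      edge = edge, edge.length = as.numeric(elen),
      tip.label = labels, Nnode = n - 2L
    ),
    class = "phylo"
  )
  stats::reorder(tr, "cladewise")
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Each replicate redraws every population's phenotype counts from a
#' multinomial with that population's own n and observed proportions,
#' re-estimates allele frequencies, and recomputes the distance matrix and
#' NJ tree. Support for an internal edge of the observed-data tree is the
#' percentage of replicate trees containing the same bipartition.
#' Replicate r uses a seed substream derived from the master seed, so
#' results are deterministic and independent of replicate ordering.
#'
#' @param x a [PhenotypeTable-class]; percent tables are converted to
#'   counts.
#' @param replicates number of bootstrap replicates (>= 1); default 1000.
#' @param seed master integer seed.
#' @param method distance, `"da"` (default) or `"nei"`.
#' @param estimator ABO estimator, `"em"` (default) or `"bernstein"`.
#' @return The observed-data NJ tree (`"phylo"`) with integer percentage
#'   support values as `node.label` on internal nodes.
#' @export
bootstrapSupport <- function(x, replicates = 1000L, seed = 1L,
                             method = c("da", "nei"),
                             estimator = c("em", "bernstein")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  counts <- if (phenoUnit(x) == "percent") percentagesToCounts(x) else x
  v <- phenoValues(counts)
  n <- sampleSizes(counts)
  baseTree <- neighborJoining(geneticDistances(counts, method, estimator))
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(deriveSeed(seed, r))
    vr <- v
    for (i in seq_len(nrow(v))) {
      vr[i, ] <- stats::rmultinom(1, n[i], v[i, ] / n[i])
    }
    m <- .fastFreqMatrix(vr, estimator)
    trees[[r]] <- neighborJoining(.fastDistanceMatrix(m, method))
  }
  class(trees) <- "multiPhylo"
  cnt <- ape::prop.clades(baseTree, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  baseTree$node.label <- as.character(as.integer(round(100 * cnt / replicates)))
  baseTree
}

#' Write a tree to a Newick file
#'
#' Branch lengths are rounded to 6 decimals; internal-node support values
#' (if present) are written as node labels.
#'
#' @param tree a `"phylo"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTreeNewick <- function(tree, path) {
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
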