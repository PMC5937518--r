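#' Principal components analysis of an allele-frequency matrix
#'
#' Columns are centered and, in the default correlation mode, scaled to
#' unit variance; the resulting cross-product matrix is eigendecomposed and
#' components are ordered by decreasing eigenvalue. Tiny negative
#' eigenvalues from floating-point round-off are clamped to 0. The sign of
#' each loading column is fixed so that its largest-magnitude entry is
#' positive, making score plots reproducible across runs.
#'
#' Note that with the 5 blood-group allele columns (A, B, O, d, D) the two
#' per-locus sum constraints leave at most 3 nonzero eigenvalues.
#'
#' @param m numeric matrix, populations x variables, at least 2 rows and 2
#'   columns, no missing values.
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return A list of class `"alleleFreqPCA"`: `scores` (populations x
#'   components), `loadings` (variables x components, orthonormal columns),
#'   `sdev`, `varianceFraction` (non-negative, non-increasing, summing
#'   to 1), `center`, `mode`.
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' m <- alleleFreqMatrix(tab[populationLabels(tab) != "Total"])
#' pcaAlleleFreq(m)
#' @export
pcaAlleleFreq <- function(m, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("PCA needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("PCA input has missing values", call. = FALSE)
  center <- colMeans(m)
  X <- sweep(m, 2, center)
  if (mode == "correlation") {
    sds <- apply(m, 2, stats::sd)
    zero <- which(sds == 0)
    if (length(zero) > 0) {
      stop("zero-variance column in correlation mode: ",
        paste(colnames(m)[zero], collapse = ", "),
        call. = FALSE
      )
    }
    X <- sweep(X, 2, sds, "/")
  }
  C <- crossprod(X) / (nrow(X) - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  V <- eig$vectors
  for (j in seq_len(ncol(V))) {
    top <- which.max(abs(V[, j]))
    if (V[top, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(m)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- X %*% V
  rownames(scores) <- rownames(m)
  structure(
    list(
      scores = scores, loadings = V, sdev = sqrt(vals),
      varianceFraction = vals / sum(vals), center = center, mode = mode
    ),
    class = "alleleFreqPCA"
  )
}

#' @export
print.alleleFreqPCA <- function(x, ...) {
  cat(sprintf(
    "PCA (%s mode): %d populations, %d variables\n",
    x$mode, nrow(x$scores), nrow(x$loadings)
  ))
  vf <- round(100 * x$varianceFraction, 1)
  cat("variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Quadrant grouping of PCA scores
#'
#' Assigns each population to a quadrant of the (PC1, PC2) plane, numbered
#' anticlockwise from the (+, +) quadrant: 1 = (+,+), 2 = (-,+), 3 = (-,-),
#' 4 = (+,-). A score exactly 0 on an axis is assigned to the positive side.
#'
#' @param x an `"alleleFreqPCA"` object or a score matrix with at least 2
#'   columns.
#' @return Named integer vector of quadrants in `1:4`.
#' @export
quadrantGroups <- function(x) {
  scores <- if (inherits(x, "alleleFreqPCA")) x$scores else as.matrix(x)
  if (ncol(scores) < 2) stop("need at least 2 components", call. = FALSE)
  s1 <- scores[, 1] >= 0
  s2 <- scores[, 2] >= 0
  q <- ifelse(s1 & s2, 1L, ifelse(!s1 & s2, 2L, ifelse(!s1 & !s2, 3L, 4L)))
  stats::setNames(q, rownames(scores))
}
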