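#' Nei gene diversity
#'
#' Expected heterozygosity `H = 1 - sum(p_i^2)` of an allele-frequency
#' vector.
#'
#' @param alleles an [AlleleFreqSet-class] or a numeric frequency vector
#'   summing to 1.
#' @return A number in `[0, 1 - 1/k]` for k alleles.
#' @examples
#' geneDiversity(c(A = 0.1937, B = 0.0549, O = 0.7514))
#' @export
geneDiversity <- function(alleles) {
  if (is(alleles, "AlleleFreqSet")) alleles <- alleleFreqs(alleles)
  if (abs(sum(alleles) - 1) > 1e-6) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  1 - sum(alleles^2)
}

#' Carrier diversity at the D locus
#'
#' The frequency of genotypes carrying at least one d allele,
#' `1 - (I^D)^2`. This is the convention behind the per-state D-locus
#' "heterozygosity" column of the survey report; it differs from the gene
#' diversity `2 I^D I^d` used in all partition arithmetic, and the two are
#' labeled separately in output.
#'
#' @param ID the I^D allele frequency in `[0, 1]`, or an
#'   [AlleleFreqSet-class] at the D locus.
#' @return `1 - ID^2`.
#' @examples
#' carrierDiversityRh(0.8700)
#' @export
carrierDiversityRh <- function(ID) {
  if (is(ID, "AlleleFreqSet")) ID <- alleleFreqs(ID)[["D"]]
  if (ID < 0 || ID > 1) stop("I^D must lie in [0, 1]", call. = FALSE)
  1 - ID^2
}

## per-stratum gene diversities at one locus, from a count-mode table
.memberDiversities <- function(counts, locus, estimator = "em") {
  fits <- alleleFrequencies(counts, estimator = estimator)
  vapply(fits, function(f) geneDiversity(f[[locus]]), numeric(1))
}

## total diversity from pooled phenotype counts re-estimated at one locus
.pooledDiversity <- function(counts, locus, estimator = "em") {
  pooled <- poolPopulations(counts, stats::setNames(
    rep("pool", nrow(phenoValues(counts))), populationLabels(counts)
  ))
  fits <- alleleFrequencies(pooled, estimator = estimator)
  geneDiversity(fits[[1]][[locus]])
}

#' Nei's hierarchical partition of gene diversity
#'
#' Partitions diversity over a set of populations into within-population
#' (`H_S`), total (`H_T`), among-population (`D_ST = H_T - H_S`) components
#' and the differentiation ratio `G_ST = D_ST / H_T`.
#'
#' `H_S` is the unweighted arithmetic mean of per-population gene
#' diversities (sample-size weighting available via `weighted = TRUE`).
#' By default `H_T` is the gene diversity of allele frequencies re-estimated
#' from the sample-size-weighted pool of the raw phenotype counts
#' (`htConvention = "pooled"`); with unequal sample sizes this can make
#' `H_T < H_S` and hence `G_ST` negative. Under the classical convention
#' (`htConvention = "meanfreq"`, `H_T` from the unweighted mean of the
#' per-population allele-frequency vectors) `G_ST` is always non-negative.
#'
#' For `locus = "POOLED"`, `H_S`, `H_T` and `D_ST` are the unweighted means
#' of the two per-locus components and `G_ST` is the unweighted mean of the
#' two per-locus `G_ST` values (so `G_ST != D_ST/H_T` for pooled rows).
#'
#' @param x a [PhenotypeTable-class] with at least 2 strata (percent tables
#'   are converted to counts first).
#' @param locus `"ABO"`, `"RH"`, or `"POOLED"`.
#' @param weighted if `TRUE`, weight `H_S` by sample size.
#' @param htConvention `"pooled"` (default) or `"meanfreq"`, see Details.
#' @param estimator ABO allele estimator, `"em"` (default) or `"bernstein"`.
#' @param group label for the output row.
#' @return A one-row data.frame with columns `group`, `locus`, `H_S`, `H_T`,
#'   `D_ST`, `G_ST`.
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' neiPartition(tab[c("Puebla", "Veracruz")], "RH")
#' @export
neiPartition <- function(x, locus = c("ABO", "RH", "POOLED"),
                         weighted = FALSE,
                         htConvention = c("pooled", "meanfreq"),
                         estimator = c("em", "bernstein"),
                         group = "group") {
  locus <- match.arg(locus)
  htConvention <- match.arg(htConvention)
  estimator <- match.arg(estimator)
  stopifnot(is(x, "PhenotypeTable"))
  if (nrow(phenoValues(x)) < 2) {
    stop("diversity partition needs at least 2 populations", call. = FALSE)
  }
  counts <- if (phenoUnit(x) == "percent") percentagesToCounts(x) else x
  oneLocus <- function(loc) {
    Hi <- .memberDiversities(counts, loc, estimator)
    HS <- if (weighted) {
      sum(Hi * sampleSizes(counts)) / sum(sampleSizes(counts))
    } else {
      mean(Hi)
    }
    HT <- if (htConvention == "pooled") {
      .pooledDiversity(counts, loc, estimator)
    } else {
      fits <- alleleFrequencies(counts, estimator = estimator)
      fbar <- rowMeans(vapply(fits, function(f) alleleFreqs(f[[loc]]),
        numeric(if (loc == "ABO") 3 else 2)
      ))
      geneDiversity(fbar)
    }
    c(HS = HS, HT = HT, DST = HT - HS, GST = (HT - HS) / HT)
  }
  if (locus == "POOLED") {
    a <- oneLocus("ABO")
    r <- oneLocus("RH")
    res <- c(
      (a[c("HS", "HT", "DST")] + r[c("HS", "HT", "DST")]) / 2,
      GST = unname((a[["GST"]] + r[["GST"]]) / 2)
    )
  } else {
    res <- oneLocus(locus)
  }
  data.frame(
    group = group, locus = locus,
    H_S = unname(res[["HS"]]), H_T = unname(res[["HT"]]),
    D_ST = unname(res[["DST"]]), G_ST = unname(res[["GST"]]),
    stringsAsFactors = FALSE
  )
}

#' Regional gene-diversity partition table
#'
#' Applies [neiPartition()] per locus and pooled to each group of a regional
#' grouping, plus an overall row computed over all member populations
#' directly (not over the regional aggregates). Groups with a single member
#' are skipped with a message, since a partition is undefined there.
#'
#' @param x a [PhenotypeTable-class] of member populations.
#' @param grouping named character vector mapping labels to groups, or a
#'   preset name for [regionPresets()].
#' @param ... passed to [neiPartition()].
#' @return A data.frame with one row per group x locus combination,
#'   including an `"All"` group.
#' @export
diversityPartitionTable <- function(x, grouping = "survey4", ...) {
  if (is.character(grouping) && length(grouping) == 1 && is.null(names(grouping))) {
    grouping <- regionPresets(grouping)
  }
  labels <- populationLabels(x)
  groups <- unique(unname(grouping[labels]))
  rows <- list()
  for (g in groups) {
    members <- labels[grouping[labels] == g]
    if (length(members) < 2) {
      message("skipping group '", g, "': single member")
      next
    }
    sub <- x[members]
    for (loc in c("ABO", "RH", "POOLED")) {
      rows[[length(rows) + 1]] <- neiPartition(sub, loc, group = g, ...)
    }
  }
  for (loc in c("ABO", "RH", "POOLED")) {
    rows[[length(rows) + 1]] <- neiPartition(x, loc, group = "All", ...)
  }
  do.call(rbind, rows)
}
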