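#' Run the full serological population-genetics pipeline
#'
#' Orchestrates the whole analysis on a stratified phenotype table:
#' Wilson confidence intervals per class, allele-frequency estimation and
#' Hardy-Weinberg tests per stratum, the regional Nei diversity partition,
#' pairwise genetic distances with a bootstrapped neighbor-joining tree,
#' and PCA of the allele-frequency matrix. All reports are written to
#' `outDir` and returned invisibly; two runs with the same inputs and seed
#' produce byte-identical outputs.
#'
#' Files written: `table1_ci.csv` (proportions with CIs, all strata),
#' `table3_alleles.csv` (allele frequencies, HWE tests, heterozygosities),
#' `table4_partition.csv` (H_S/H_T/D_ST/G_ST per group and locus),
#' `distances.csv`, `tree.nwk`, `pca_scores.csv`, `pca_loadings.csv`, and
#' `summary.json` (headline numbers at full precision).
#'
#' @param input a [PhenotypeTable-class] or a CSV/TSV path for
#'   [readPhenotypeTable()].
#' @param unit unit of the input when `input` is a path.
#' @param grouping regional grouping: preset name (default `"survey4"`) or a
#'   named label-to-group vector.
#' @param estimator ABO allele estimator, `"em"` (default) or `"bernstein"`.
#' @param emTol,emMaxIter EM settings.
#' @param distance `"da"` (default) or `"nei"`.
#' @param bootstrap number of bootstrap replicates for tree support
#'   (0 disables support values).
#' @param seed master seed for the bootstrap.
#' @param pcaMode `"correlation"` (default) or `"covariance"`.
#' @param outDir output directory, created if needed.
#' @param dropTotal drop strata labeled `"Total"` from the genetic analysis
#'   (they remain in the CI report); default `TRUE`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all computed objects (`ci`, `alleles`,
#'   `partition`, `distances`, `tree`, `pca`, `summary`).
#' @examples
#' \donttest{
#' out <- runPipeline(system.file("extdata", "table2_states.csv",
#'                                package = "seropop"),
#'                    bootstrap = 10, outDir = tempfile())
#' out$summary$pc12_variance_percent
#' }
#' @export
runPipeline <- function(input, unit = c("percent", "count"),
                        grouping = "survey4",
                        estimator = c("em", "bernstein"),
                        emTol = 1e-10, emMaxIter = 1000L,
                        distance = c("da", "nei"),
                        bootstrap = 1000L, seed = 1L,
                        pcaMode = c("correlation", "covariance"),
                        outDir = "seropop-results",
                        dropTotal = TRUE, quiet = FALSE) {
  estimator <- match.arg(estimator)
  distance <- match.arg(distance)
  pcaMode <- match.arg(pcaMode)
  say <- function(...) if (!quiet) message("seropop: ", ...)
  tab <- if (is(input, "PhenotypeTable")) {
    input
  } else {
    say("reading ", input)
    readPhenotypeTable(input, unit = match.arg(unit))
  }
  if (nrow(phenoValues(tab)) == 0) {
    stop("stage read: input table has no records", call. = FALSE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  say("Wilson confidence intervals (", nrow(phenoValues(tab)), " strata)")
  ci <- ciReport(tab)
  utils::write.csv(ci, file.path(outDir, "table1_ci.csv"), row.names = FALSE)

  gen <- if (dropTotal) tab[populationLabels(tab) != "Total"] else tab
  counts <- if (phenoUnit(gen) == "percent") percentagesToCounts(gen) else gen

  say("allele frequencies (", estimator, ") and HWE tests")
  fits <- alleleFrequencies(counts, estimator = estimator,
                            tol = emTol, maxIter = emMaxIter)
  abo <- marginalize(counts, "ABO", proportions = FALSE)
  rh <- marginalize(counts, "RH", proportions = FALSE)
  alleleRows <- lapply(populationLabels(counts), function(lab) {
    f <- fits[[lab]]
    hw <- hweTestABO(abo[lab, ], tol = emTol, maxIter = emMaxIter)
    af <- alleleFreqs(f$ABO)
    rf <- alleleFreqs(f$RH)
    data.frame(
      label = lab, region = unname(regionLabels(counts)[lab]),
      n = unname(sampleSizes(counts)[lab]),
      I_A = round(af[["A"]], 4), I_B = round(af[["B"]], 4),
      I_O = round(af[["O"]], 4),
      abo_chi2 = round(hw$statistic, 4), abo_df = hw$df,
      abo_p = hw$p.value,
      abo_hwe_deviation = !is.na(hw$p.value) && hw$p.value < 0.05,
      I_d = round(rf[["d"]], 4), I_D = round(rf[["D"]], 4),
      rh_chi2 = 0, rh_df = 0, rh_p = NA_real_,
      H_ABO = round(geneDiversity(f$ABO), 4),
      H_D_carrier = round(carrierDiversityRh(f$RH), 4),
      stringsAsFactors = FALSE
    )
  })
  alleleReport <- do.call(rbind, alleleRows)
  utils::write.csv(alleleReport, file.path(outDir, "table3_alleles.csv"),
    row.names = FALSE
  )

  say("Nei diversity partition")
  partition <- diversityPartitionTable(counts, grouping, estimator = estimator)
  partOut <- partition
  for (cn in c("H_S", "H_T", "D_ST", "G_ST")) partOut[[cn]] <- round(partOut[[cn]], 4)
  utils::write.csv(partOut, file.path(outDir, "table4_partition.csv"),
    row.names = FALSE
  )

  say("genetic distances (", distance, ") and NJ tree, ",
      bootstrap, " bootstrap replicate(s), seed ", seed)
  dm <- geneticDistances(counts, method = distance, estimator = estimator)
  utils::write.csv(round(dm, 6), file.path(outDir, "distances.csv"))
  tree <- if (bootstrap > 0) {
    bootstrapSupport(counts, replicates = bootstrap, seed = seed,
                     method = distance, estimator = estimator)
  } else {
    neighborJoining(dm)
  }
  writeTreeNewick(tree, file.path(outDir, "tree.nwk"))

  say("PCA (", pcaMode, " mode)")
  m <- alleleFreqMatrix(counts, estimator = estimator)
  pca <- pcaAlleleFreq(m, mode = pcaMode)
  utils::write.csv(round(pca$scores, 6), file.path(outDir, "pca_scores.csv"))
  utils::write.csv(round(pca$loadings, 6), file.path(outDir, "pca_loadings.csv"))

  allRow <- function(loc) partition[partition$group == "All" & partition$locus == loc, ]
  summary <- list(
    n_populations = nrow(phenoValues(counts)),
    total_n = sum(sampleSizes(counts)),
    estimator = estimator, distance = distance, pca_mode = pcaMode,
    seed = seed, bootstrap_replicates = bootstrap,
    H_S = list(ABO = allRow("ABO")$H_S, RH = allRow("RH")$H_S),
    H_T = list(ABO = allRow("ABO")$H_T, RH = allRow("RH")$H_T),
    G_ST = list(
      ABO = allRow("ABO")$G_ST, RH = allRow("RH")$G_ST,
      pooled = allRow("POOLED")$G_ST
    ),
    pc12_variance_percent = 100 * sum(pca$varianceFraction[1:2]),
    hwe_deviations = alleleReport$label[alleleReport$abo_hwe_deviation]
  )
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  say("done; reports in ", outDir)
  invisible(list(
    table = tab, ci = ci, alleles = alleleReport, partition = partition,
    distances = dm, tree = tree, pca = pca, summary = summary
  ))
}
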