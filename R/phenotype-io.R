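#' Construct a PhenotypeTable
#'
#' @param values numeric matrix (strata x 8) with columns in the canonical
#'   class order `c("A+","A-","B+","B-","AB+","AB-","O+","O-")` and stratum
#'   labels as row names, or a data.frame with a `label` column plus those
#'   class columns.
#' @param n numeric vector of sample sizes, one per stratum.
#' @param unit `"count"` or `"percent"`.
#' @param region optional character vector of region metadata (default `""`).
#' @param strata names of the stratification keys (metadata only).
#' @return A [PhenotypeTable-class] object.
#' @examples
#' m <- matrix(c(25, 1, 9, 0.5, 2, 0.1, 60, 2.4), nrow = 1,
#'             dimnames = list("Demo", phenotypeClasses()))
#' phenotypeTable(m, n = 1000, unit = "percent")
#' @export
phenotypeTable <- function(values, n, unit = c("count", "percent"),
                           region = NULL, strata = "label") {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(region)) region <- rep("", nrow(values))
  new("PhenotypeTable",
    values = values, region = as.character(region),
    n = as.numeric(n), unit = unit, strata = strata
  )
}

#' The canonical phenotype class order
#'
#' @return Character vector of the 8 ABO x Rh(D) classes in serialization
#'   order: A+, A-, B+, B-, AB+, AB-, O+, O-.
#' @export
phenotypeClasses <- function() PHENO_CLASSES

#' Read a stratified phenotype table from CSV/TSV
#'
#' The file must have a header with a `label` column, an `n` column, the 8
#' phenotype class columns (`A+`, `A-`, `B+`, `B-`, `AB+`, `AB-`, `O+`, `O-`)
#' and optionally a `region` column. The field separator (comma or tab) is
#' sniffed from the header line.
#'
#' Percent rows are kept exactly as printed (no renormalization); a percent
#' row whose classes do not sum to 100 within 0.25 is rejected, as is any
#' negative value.
#'
#' @param path file path.
#' @param unit unit of the class columns, `"percent"` or `"count"`.
#' @return A [PhenotypeTable-class].
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' tab
#' @export
readPhenotypeTable <- function(path, unit = c("percent", "count")) {
  unit <- match.arg(unit)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE, encoding = "UTF-8", quote = "\""
  )
  missing <- setdiff(c("label", "n", PHENO_CLASSES), names(df))
  if (length(missing) > 0) {
    stop("phenotype table format error: missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ## n may be printed with thousands separators
  nvec <- as.numeric(gsub("[ ,]", "", as.character(df$n)))
  vals <- as.matrix(df[, PHENO_CLASSES])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$label
  region <- if ("region" %in% names(df)) as.character(df$region) else NULL
  phenotypeTable(vals, n = nvec, unit = unit, region = region)
}

#' Write a PhenotypeTable to CSV
#'
#' @param x a [PhenotypeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTable <- function(x, path) {
  df <- data.frame(
    label = populationLabels(x), region = regionLabels(x),
    n = sampleSizes(x), check.names = FALSE
  )
  df <- cbind(df, as.data.frame(phenoValues(x), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

## ---- accessors ------------------------------------------------------------

#' Accessors for PhenotypeTable
#'
#' `populationLabels` returns the stratum labels, `regionLabels` the region
#' metadata, `sampleSizes` the per-stratum n, `phenoValues` the strata x 8
#' matrix, and `phenoUnit` the unit (`"count"` or `"percent"`).
#'
#' @param x a [PhenotypeTable-class].
#' @return See description.
#' @name PhenotypeTable-accessors
NULL

#' @rdname PhenotypeTable-accessors
#' @export
populationLabels <- function(x) rownames(x@values)

#' @rdname PhenotypeTable-accessors
#' @export
regionLabels <- function(x) stats::setNames(x@region, populationLabels(x))

#' @rdname PhenotypeTable-accessors
#' @export
sampleSizes <- function(x) stats::setNames(x@n, populationLabels(x))

#' @rdname PhenotypeTable-accessors
#' @export
phenoValues <- function(x) x@values

#' @rdname PhenotypeTable-accessors
#' @export
phenoUnit <- function(x) x@unit

#' Subset a PhenotypeTable by stratum
#'
#' @param x a [PhenotypeTable-class].
#' @param i integer, logical or character (label) index.
#' @param j unused.
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "PhenotypeTable", function(x, i, j, ..., drop = FALSE) {
  idx <- if (is.character(i)) match(i, populationLabels(x)) else i
  if (is.numeric(idx) && anyNA(idx)) {
    stop("unknown stratum label(s): ",
      paste(i[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  phenotypeTable(x@values[idx, , drop = FALSE],
    n = x@n[idx], unit = x@unit,
    region = x@region[idx], strata = x@strata
  )
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf(
    "PhenotypeTable: %d strata, unit = %s, total n = %s\n",
    nrow(object@values), object@unit,
    format(sum(object@n), big.mark = ",")
  ))
  k <- min(nrow(object@values), 5L)
  print(round(object@values[seq_len(k), , drop = FALSE], 2))
  if (nrow(object@values) > k) {
    cat(sprintf("... and %d more strata\n", nrow(object@values) - k))
  }
  invisible(NULL)
})

## ---- unit conversion ------------------------------------------------------

#' Convert a percent-mode table to exact integer counts
#'
#' Each class count is `round(percent/100 * n)`; the rounding residual
#' (sum of rounded counts minus n) is assigned to the record's largest class
#' so that every row sums to its sample size exactly.
#'
#' @param x a percent-mode [PhenotypeTable-class] with sample sizes.
#' @return A count-mode [PhenotypeTable-class].
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' counts <- percentagesToCounts(tab)
#' rowSums(phenoValues(counts)) - sampleSizes(counts)  # all zero
#' @export
percentagesToCounts <- function(x) {
  stopifnot(is(x, "PhenotypeTable"))
  if (x@unit != "percent") stop("table is not in percent mode", call. = FALSE)
  if (any(is.na(x@n)) || any(x@n <= 0)) {
    stop("sample size n is required to convert percentages to counts",
      call. = FALSE
    )
  }
  counts <- x@values
  for (i in seq_len(nrow(counts))) {
    ci <- round(x@values[i, ] / 100 * x@n[i])
    resid <- sum(ci) - x@n[i]
    if (resid != 0) {
      largest <- which.max(ci)
      ci[largest] <- ci[largest] - resid
    }
    counts[i, ] <- ci
  }
  phenotypeTable(counts,
    n = x@n, unit = "count",
    region = x@region, strata = x@strata
  )
}

#' Convert a count-mode table to percentages
#'
#' @param x a count-mode [PhenotypeTable-class].
#' @return A percent-mode [PhenotypeTable-class] (percent of each row's n).
#' @export
countsToPercentages <- function(x) {
  stopifnot(is(x, "PhenotypeTable"))
  if (x@unit != "count") stop("table is not in count mode", call. = FALSE)
  phenotypeTable(100 * x@values / x@n,
    n = x@n, unit = "percent",
    region = x@region, strata = x@strata
  )
}

## ---- marginalization and pooling -----------------------------------------

#' Marginal phenotype frequencies at one locus
#'
#' Collapses the 8 joint classes to the 4 ABO groups (summing Rh(D) and
#' Rh(d) cells) or the 2 Rh states (summing the four ABO groups), and
#' normalizes each record to proportions.
#'
#' @param x a [PhenotypeTable-class].
#' @param locus `"ABO"` or `"RH"`.
#' @param proportions if `TRUE` (default) rows are normalized to sum to 1;
#'   if `FALSE` the raw marginal values are returned (counts in count mode).
#' @return Numeric matrix, strata x 4 (`A`,`B`,`AB`,`O`) or strata x 2
#'   (`D+`,`D-`).
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' marginalize(tab, "ABO")["Sinaloa", ]
#' @export
marginalize <- function(x, locus = c("ABO", "RH"), proportions = TRUE) {
  stopifnot(is(x, "PhenotypeTable"))
  locus <- match.arg(locus)
  v <- x@values
  m <- if (locus == "ABO") {
    cbind(
      A = v[, "A+"] + v[, "A-"], B = v[, "B+"] + v[, "B-"],
      AB = v[, "AB+"] + v[, "AB-"], O = v[, "O+"] + v[, "O-"]
    )
  } else {
    cbind(
      `D+` = v[, "A+"] + v[, "B+"] + v[, "AB+"] + v[, "O+"],
      `D-` = v[, "A-"] + v[, "B-"] + v[, "AB-"] + v[, "O-"]
    )
  }
  rownames(m) <- populationLabels(x)
  if (proportions) m <- m / rowSums(m)
  m
}

#' Pool population strata into groups
#'
#' Sample-size-weighted pooling of raw phenotypes: group counts are the sums
#' of member counts and the group n is the sum of member n. Percent-mode
#' input is converted to counts first.
#'
#' @param x a [PhenotypeTable-class].
#' @param grouping named character vector mapping every stratum label to a
#'   group name (see [regionPresets()]), or a single preset name.
#' @return A count-mode [PhenotypeTable-class], one record per group, in
#'   order of first appearance of each group.
#' @examples
#' tab <- readPhenotypeTable(system.file("extdata", "table2_states.csv",
#'                                       package = "seropop"), unit = "percent")
#' states <- tab[populationLabels(tab) != "Total"]
#' poolPopulations(states, regionPresets("survey4"))
#' @export
poolPopulations <- function(x, grouping) {
  stopifnot(is(x, "PhenotypeTable"))
  if (is.character(grouping) && length(grouping) == 1 && is.null(names(grouping))) {
    grouping <- regionPresets(grouping)
  }
  labels <- populationLabels(x)
  unmapped <- setdiff(labels, names(grouping))
  if (length(unmapped) > 0) {
    stop("unmapped stratum label(s): ", paste(unmapped, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- if (x@unit == "percent") percentagesToCounts(x) else x
  groups <- unique(unname(grouping[labels]))
  v <- matrix(0, length(groups), length(PHENO_CLASSES),
    dimnames = list(groups, PHENO_CLASSES)
  )
  n <- numeric(length(groups))
  for (g in seq_along(groups)) {
    members <- labels[grouping[labels] == groups[g]]
    v[g, ] <- colSums(phenoValues(counts)[members, , drop = FALSE])
    n[g] <- sum(sampleSizes(counts)[members])
  }
  phenotypeTable(v,
    n = n, unit = "count", region = groups,
    strata = "group"
  )
}

#' Region groupings of the 17 surveyed Mexican states
#'
#' `"survey6"` is the six-region scheme used to present the per-state survey
#' (Northwest, Northeast, West, East, North-center, South-center);
#' `"survey4"` is the four-region scheme used for the gene-diversity
#' partition (north, west, east, center).
#'
#' @param name `"survey6"` or `"survey4"`.
#' @return Named character vector mapping state label to group name.
#' @export
regionPresets <- function(name = c("survey4", "survey6")) {
  name <- match.arg(name)
  if (name == "survey6") {
    c(
      "Baja California" = "Northwest", "Sonora" = "Northwest",
      "Sinaloa" = "Northwest", "Durango" = "Northwest",
      "Coahuila" = "Northeast", "Nuevo Leon" = "Northeast",
      "Nayarit" = "West", "Jalisco" = "West", "Michoacan" = "West",
      "Puebla" = "East", "Veracruz" = "East",
      "San Luis Potosi" = "North-center", "Aguascalientes" = "North-center",
      "Guanajuato" = "North-center", "Queretaro" = "North-center",
      "Estado de Mexico" = "South-center", "Ciudad de Mexico" = "South-center"
    )
  } else {
    c(
      "Baja California" = "North", "Sonora" = "North", "Sinaloa" = "North",
      "Nuevo Leon" = "North", "Durango" = "North", "Coahuila" = "North",
      "Nayarit" = "West", "Jalisco" = "West", "Michoacan" = "West",
      "Puebla" = "East", "Veracruz" = "East",
      "San Luis Potosi" = "Center", "Aguascalientes" = "Center",
      "Guanajuato" = "Center", "Queretaro" = "Center",
      "Estado de Mexico" = "Center", "Ciudad de Mexico" = "Center"
    )
  }
}
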