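test_that("the packaged state survey reads and validates", {
  tab <- readPhenotypeTable(
    system.file("extdata", "table2_states.csv", package = "seropop"),
    unit = "percent"
  )
  expect_s4_class(tab, "PhenotypeTable")
  expect_equal(nrow(phenoValues(tab)), 18) # 17 states + Total
  expect_equal(unname(sampleSizes(tab)["Sinaloa"]), 40449)
  expect_equal(unname(sampleSizes(tab)["Total"]), 271164)
  expect_equal(phenoUnit(tab), "percent")
  expect_setequal(unique(regionLabels(stateTable())), c(
    "Northwest", "Northeast", "West", "East", "North-center", "South-center"
  ))
})

test_that("malformed tables are rejected with informative errors", {
  f <- tempfile(fileext = ".csv")
  # 7 of 8 class columns
  writeLines(c(
    "label,n,A+,A-,B+,B-,AB+,AB-,O+",
    "X,100,25,1,9,0.5,2,0.1,62.4"
  ), f)
  expect_error(readPhenotypeTable(f, "percent"), "missing column.*O-")
  # percent row summing to 98
  writeLines(c(
    "label,n,A+,A-,B+,B-,AB+,AB-,O+,O-",
    "X,100,25,1,9,0.5,2,0.1,58,2.4"
  ), f)
  expect_error(readPhenotypeTable(f, "percent"), "'X' sums to 98")
  # negative value
  writeLines(c(
    "label,n,A+,A-,B+,B-,AB+,AB-,O+,O-",
    "X,100,25,1,9,-0.5,2,0.1,62,2.4"
  ), f)
  expect_error(readPhenotypeTable(f, "percent"), "non-negative")
})

test_that("percent-to-count conversion rounds per class and repairs the residual", {
  counts <- percentagesToCounts(stateTable())
  v <- phenoValues(counts)
  n <- sampleSizes(counts)
  # every row sums to its n exactly
  expect_equal(unname(rowSums(v)), unname(n))
  # each class is the rounded value up to the (single-cell) residual repair
  pv <- phenoValues(stateTable())
  for (lab in rownames(v)) {
    raw <- round(pv[lab, ] / 100 * n[lab])
    resid <- sum(raw) - n[lab]
    expect_true(all(abs(v[lab, ] - raw) <= abs(resid)))
    expect_lte(sum(v[lab, ] != raw), 1) # only the largest class is touched
  }
  # Sinaloa O+ is round(0.5273 * 40449) up to the row residual
  expect_lte(abs(v["Sinaloa", "O+"] - round(0.5273 * 40449)), 2)
  # national AB- count: round(0.0010 * 271164) = 271 (residual lands on O+)
  tot <- percentagesToCounts(readPhenotypeTable(
    system.file("extdata", "table2_states.csv", package = "seropop"), "percent"
  ))
  expect_equal(unname(phenoValues(tot)["Total", "AB-"]), 271)
  # all mass in one class
  one <- phenotypeTable(
    matrix(c(0, 0, 0, 0, 0, 0, 100, 0), 1,
      dimnames = list("Z", phenotypeClasses())
    ),
    n = 57, unit = "percent"
  )
  expect_equal(unname(phenoValues(percentagesToCounts(one))["Z", "O+"]), 57)
})

test_that("count -> percent -> count round-trips within table precision", {
  counts <- stateCounts()
  back <- percentagesToCounts(countsToPercentages(counts))
  expect_equal(phenoValues(back), phenoValues(counts))
  # percent -> count -> percent within 100/(2n) per class, except the
  # single largest class, which absorbs the row residual: up to 8 half-count
  # roundings plus the printed row-sum bias (rows sum to 100 +/- 0.25)
  tab <- stateTable()
  pct <- countsToPercentages(percentagesToCounts(tab))
  tol <- 100 / (2 * sampleSizes(tab))
  diffs <- abs(phenoValues(pct) - phenoValues(tab))
  for (i in seq_len(nrow(diffs))) {
    largest <- which.max(phenoValues(tab)[i, ])
    expect_true(all(diffs[i, -largest] <= tol[i] + 1e-9))
    rowBias <- abs(sum(phenoValues(tab)[i, ]) - 100)
    expect_lte(diffs[i, largest], 100 * 4.5 / sampleSizes(tab)[i] + rowBias)
  }
})

test_that("marginalization sums the right cells and normalizes", {
  tab <- stateTable()
  abo <- marginalize(tab, "ABO")
  rh <- marginalize(tab, "RH")
  expect_lt(abs(abo["Sinaloa", "O"] - 0.5646), 1e-4)
  expect_lt(abs(rh["Sinaloa", "D-"] - 0.0688), 1e-4)
  expect_equal(unname(rowSums(abo)), rep(1, 17))
  expect_equal(unname(rowSums(rh)), rep(1, 17))
  # national Rh(d) marginal
  tot <- readPhenotypeTable(
    system.file("extdata", "table2_states.csv", package = "seropop"), "percent"
  )
  expect_lt(abs(marginalize(tot, "RH")["Total", "D-"] - 0.0442), 1e-4)
  # count mode: proportions are exact ratios of integers
  cm <- marginalize(stateCounts(), "ABO", proportions = FALSE)
  expect_true(all(cm == round(cm)))
  expect_equal(unname(rowSums(cm)), unname(sampleSizes(stateCounts())))
})

test_that("pooling is sample-size-weighted, associative, and commutes with marginalization", {
  counts <- stateCounts()
  east <- poolPopulations(counts[c("Puebla", "Veracruz")], c(
    "Puebla" = "east", "Veracruz" = "east"
  ))
  expect_equal(unname(sampleSizes(east)), 6212 + 1790)
  o <- marginalize(east, "ABO")[1, "O"]
  expect_lt(abs(o - 0.7290), 3e-4)
  # single-member grouping is the identity
  solo <- poolPopulations(counts["Sinaloa"], c("Sinaloa" = "nw"))
  expect_equal(unname(phenoValues(solo)[1, ]), unname(phenoValues(counts)["Sinaloa", ]))
  # north preset n
  north <- poolPopulations(counts, regionPresets("survey4"))
  expect_equal(unname(sampleSizes(north)["North"]), 126313)
  # associativity: pool(A|B then with C) == pool(A|B|C)
  g1 <- c("Puebla" = "g", "Veracruz" = "g")
  step1 <- poolPopulations(counts[c("Puebla", "Veracruz")], g1)
  withC <- phenotypeTable(
    rbind(phenoValues(step1), phenoValues(counts)["Queretaro", , drop = FALSE]),
    n = c(sampleSizes(step1), sampleSizes(counts)["Queretaro"]),
    unit = "count"
  )
  twoStep <- poolPopulations(withC, c("g" = "all", "Queretaro" = "all"))
  oneStep <- poolPopulations(
    counts[c("Puebla", "Veracruz", "Queretaro")],
    c("Puebla" = "all", "Veracruz" = "all", "Queretaro" = "all")
  )
  expect_equal(phenoValues(twoStep), phenoValues(oneStep))
  # marginalize(pool) == pool(marginalize) in count mode, exactly
  pooled <- poolPopulations(counts, regionPresets("survey4"))
  mp <- marginalize(pooled, "ABO", proportions = FALSE)
  pm <- rowsum(
    marginalize(counts, "ABO", proportions = FALSE),
    regionPresets("survey4")[populationLabels(counts)]
  )
  expect_equal(mp[rownames(mp), ], pm[rownames(mp), ])
  # unmapped label errors by name
  expect_error(
    poolPopulations(counts, c("Puebla" = "east")),
    "unmapped.*Veracruz"
  )
})
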