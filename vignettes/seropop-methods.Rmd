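---
title: "Serological population genetics with seropop: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serological population genetics with seropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seropop)
```

## The problem

ABO and Rh(D) blood groups are among the cheapest genetic markers available
at population scale: a national blood-typing campaign yields, for each
stratum (state, age band, gender), the counts of the 8 joint phenotype
classes A+, A-, B+, B-, AB+, AB-, O+, O-. Because both systems have
dominance (I^O recessive to I^A and I^B; d recessive to D), genotypes are
only partially observed, and every population-genetic quantity — allele
frequencies, heterozygosities, differentiation, genetic distances — must be
inferred through a genetic model rather than counted directly.

`seropop` implements that inference chain end to end for stratified
phenotype tables, with the conventions needed to reproduce a large Mexican
blood-donor survey (17 states, n = 271,164) from its published per-state
percentage table alone. A multinomial simulator with known ground truth
makes every stage testable without external data.

## Data model and unit conventions

A `PhenotypeTable` holds one row per stratum: label, region, sample size n,
and the 8 class values, in `count` or `percent` mode. Percent tables are
kept exactly as printed; a row whose classes do not sum to 100 within 0.25
(the worst case for 8 cells rounded to 2 decimals) is rejected rather than
renormalized. Analysis runs on counts: `percentagesToCounts()` rounds each
class to `round(pct/100 * n)` and assigns the residual to the row's largest
class, so totals are exact. The residual combines up to 8 half-count
roundings with the row-sum bias, so the largest class may move by a few
counts; all other classes are exact to half a count. This matters for small
cells: a chi-squared statistic on a class with ~200 expected counts can
shift by several percent depending on where within the printed rounding
band the true counts fell, which bounds how precisely published test
statistics can be reproduced from a percentage table (see *Known limits*).

One cell of the bundled age/gender fixture deviates from the source table:
the 50–59 O Rh(D) entry is stored as 55.54 rather than the printed 57.54,
which contradicts both its own confidence interval (54.57–56.51 is exactly
the Wilson interval for 55.54 at n = 10,085) and the row sum (102.01).

## Allele-frequency estimation

**ABO, Bernstein's method.** With phenotype proportions `f_O, f_A, f_B`,
the square-root estimators are `r = sqrt(f_O)`, `p = 1 - sqrt(f_O + f_B)`,
`q = 1 - sqrt(f_O + f_A)`. Their sum misses 1 by a deviation `D`; the
corrected estimate multiplies `p` and `q` by `(1 + D/2)` and replaces `r`
by `(r + D/2)(1 + D/2)`, then renormalizes. Both raw and corrected forms
are exposed (`bernsteinABO(correct = FALSE)` keeps `D` retrievable);
the survey's printed I^O values match the *raw* square root while I^A
matches either form at 4 decimals.

**ABO, EM (default).** `emABO()` is gene counting: the E-step splits the A
phenotype count into AA and AO with weights `p^2 : 2pr` (likewise B), AB
and O being unambiguous; the M-step counts alleles in the expected genotype
table. The multinomial log-likelihood is non-decreasing by construction and
the implementation aborts if it ever drops. Defaults: tolerance 1e-10 on
the log-likelihood change, at most 1000 iterations, initialization at the
corrected Bernstein estimate (uniform 1/3 fallback when Bernstein is
degenerate). Non-convergence is flagged on the result, not thrown. Zero
count classes need no pseudocounts — the EM weights handle them.

**D locus.** Rh-negative is the dd genotype, so `I^d = sqrt(f_Dneg)` is
both the method-of-moments and the maximum-likelihood estimate; no
iteration is needed.

At survey sample sizes the corrected Bernstein and EM estimates agree to
within 0.001 per allele; EM is the default for all reported tables because
it is exactly ML, which also makes the downstream goodness-of-fit test the
textbook construction.

## Hardy–Weinberg testing

`hweTestABO()` compares observed ABO phenotype counts with HWE expectations
at the EM (ML) frequencies: `E_O = r^2 n`, `E_A = (p^2+2pr) n`,
`E_B = (q^2+2qr) n`, `E_AB = 2pq n`; Pearson chi-squared with
df = 4 - 1 - 2 = 1. The D locus admits no test: 2 phenotype classes minus 1
estimated frequency saturate the model, so `hweTestRH()` reports statistic
0 with df 0 and a not-testable marker rather than imitating published
nonzero values, which cannot arise from a 2-phenotype system.

A property worth knowing before trusting this test as an inbreeding
screen: with dominance-masked phenotypes the best-fitting HWE model
absorbs an inbreeding perturbation F to first order, leaving Pearson
noncentrality of order n·F^4 (measured: 4e-4 at F = 0.05, n ≈ 29,000 — no
power at all; detection needs F around 0.5 at that n). The test does
detect general lack of fit, but tiny F is invisible in phenotype data.
The property tests therefore exercise power at F ∈ {0.4, 0.8}.

## Gene diversity and its partition

Per-population gene diversity is Nei's `H = 1 - sum(p_i^2)`. Two
conventions coexist for the D locus and are labeled separately in output:
partition arithmetic always uses `2 p q`, while the per-state report column
uses the carrier convention `1 - (I^D)^2` (the frequency of genotypes
carrying at least one d allele), because that is the convention behind the
published per-state D column.

`neiPartition()` computes, over member populations:

* `H_S`: the unweighted arithmetic mean of member diversities (sample-size
  weighting available but not default — the unweighted mean is what
  reproduces the published within-population values);
* `H_T`: the diversity of allele frequencies re-estimated from the pooled
  raw phenotype counts (sample-size weighted by construction);
* `D_ST = H_T - H_S` and `G_ST = D_ST / H_T`.

Mixing an unweighted `H_S` with a count-pooled `H_T` means `G_ST` can be
negative when a large, low-diversity population dominates the pool — the
east region (Puebla n = 6,212 vs Veracruz n = 1,790) is exactly this case
and the published negative value reproduces to 4 decimals. Under the
classical convention (`htConvention = "meanfreq"`, `H_T` from unweighted
mean frequencies) `G_ST = sum of column variances / H_T` is provably
non-negative, which the property suite checks.

Pooled-locus rows average `H_S`, `H_T`, `D_ST` component-wise across the
two loci, and average the two per-locus `G_ST` values — not `D_ST/H_T`
recomputed from the averaged components. The published pooled rows follow
the averaged-ratio convention in every group (e.g. the national pooled
G_ST of 0.0520 is the mean of 0.0353 and 0.0686, while the recomputed
ratio would give 0.0513), so that is the convention implemented; the price
is that the identity `G_ST = D_ST/H_T` holds per locus but not for pooled
rows. The overall ("All") partition is computed across the 17 member
populations directly, never across the 4 regional aggregates.

## Distances, neighbor joining, bootstrap

Two distances over the (ABO, D) loci are provided, both operating on
per-locus allele-frequency vectors: Nei's standard distance
`D = -ln( J_xy / sqrt(J_x J_y) )` with J terms averaged over loci, and the
DA distance `1 - (1/L) sum_loci sum_alleles sqrt(x_i y_i)`, bounded in
[0, 1]. DA is the default (it is the distance named in the survey's
clustering analysis); the standard distance is a flag away.

`neighborJoining()` is a from-scratch Saitou–Nei implementation: join the
pair minimizing `Q_ij = (m-2) d_ij - R_i - R_j`, with ties broken by the
smallest (i, j) index pair; standard branch-length formulas; a negative
branch is clamped to zero with the deficit moved to its sibling so the
pair's total is preserved; the 3-cluster star closes the tree. On additive
matrices the result reproduces the input path lengths exactly, which the
suite verifies against random trees with an independent path-length oracle.
Trees are returned as `ape` `phylo` objects and written as Newick with
6-decimal branch lengths.

`bootstrapSupport()` resamples each population's phenotype counts from a
multinomial with its own n and observed proportions, re-estimates, and
rebuilds the tree; support for an edge is the percentage of replicate
trees containing the same bipartition. Counts are resampled rather than
loci because with 2 loci a locus bootstrap would be degenerate — a
deliberate divergence from locus-resampling phylogenetic software. One
master seed drives everything; replicate r and population labels derive
independent substreams via a stable hash, so results do not depend on
evaluation order and adding a population leaves other draws unchanged.

## Ordination

`pcaAlleleFreq()` is a plain centering + eigendecomposition PCA of the
populations × 5 allele matrix (A, B, O, d, D), with a deterministic sign
convention (each loading column's largest-magnitude entry positive) and
eigenvalues clamped at zero. Correlation mode (unit-variance scaling) is
the default: on this data it is the mode that reproduces the published
"PC1+PC2 explain 97.2%" figure and the four published quadrant groups,
whereas covariance mode concentrates ~99% in two components because the
O and D columns have much larger spread than A and B. All five columns are
retained although the two per-locus sum constraints add only zero
eigenvalues. `quadrantGroups()` assigns populations to (PC1, PC2)
quadrants numbered anticlockwise from (+, +), with exact zeros going to
the positive side.

## The synthetic generator

`simulateTable()` draws, per population, one multinomial of size n over the
8 joint class probabilities implied by allele frequencies (p, q, r; I^D)
under the inbreeding-adjusted model: homozygotes `p_i^2 + F p_i (1-p_i)`,
heterozygotes `2 p_i p_j (1-F)`, loci independent. F is the single
HWE-violation knob. The generator emulates exactly the sampling model the
estimators assume — multinomial phenotype sampling at fixed allele
frequencies. It does not emulate admixture, migration, drift over time,
genotyping error, or the non-random recruitment of a clinic-based sample,
so passing recovery tests demonstrates correctness of the inference chain
under its own model, not robustness to those real-data features.
`surveySimConfig()` builds a survey-like configuration (17 populations at
the re-estimated state frequencies and printed sample sizes, F = 0).

## Problem sizes in the test suite

The suite runs the full survey pipeline (17 populations) with bootstrap
trees at 1000 replicates in a few seconds; calibration properties use
1000 null simulations at n = 5,000 (type-I error), 50 simulations at
n = 50,000 (parameter recovery), and 20 random additive trees of 4–10
leaves (NJ exactness). These sizes keep the default run comfortably inside
a couple of minutes while leaving Monte-Carlo margins wide relative to the
asserted bands.

## Known limits

* Published values are printed at 2 decimals (percentages) and 4 decimals
  (frequencies). Reconstructed integer counts are therefore only defined up
  to the printing band, which propagates most visibly into chi-squared
  statistics (a few percent) and into PCA scores of populations sitting
  near a quadrant boundary; one state (Jalisco) flips PC2 sign relative to
  a computation from the published 4-decimal frequency table.
* The Rh goodness-of-fit column cannot be reproduced from 2-phenotype data
  (see above); it is reported as structurally saturated.
* No ABO subgroups (A1/A2), no Rh C/c/E/e haplotypes, no F-statistics
  beyond G_ST, no exact HWE tests, and no tree/biplot graphics: the
  package targets the serological analysis chain, and its outputs (Newick,
  CSV, JSON) feed standard tools for anything further.
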