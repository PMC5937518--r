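Package: seropop
Title: Population Genetics of ABO and Rh(D) Blood-Group Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for serological population genetics from stratified
    ABO x Rh(D) phenotype tables: allele-frequency estimation at the ABO
    locus (Bernstein's corrected square-root estimator and an EM
    maximum-likelihood estimator under Hardy-Weinberg equilibrium) and at
    the D locus (square-root estimator), Hardy-Weinberg goodness-of-fit
    tests, Nei gene-diversity partitioning (H_S, H_T, D_ST, G_ST) across
    regions, Nei standard and DA genetic distances with neighbor-joining
    trees and multinomial bootstrap support, principal components analysis
    of allele-frequency matrices, and Wilson score confidence intervals for
    phenotype proportions. Includes a multinomial phenotype simulator under
    Hardy-Weinberg equilibrium with optional inbreeding so every stage can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
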