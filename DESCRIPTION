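Package: bromeval
Title: Multi-Year Forage Genotype Evaluation: Entropy-TOPSIS Ranking,
    Piecewise SEM and Random-Forest Importance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-year statistical evaluation of forage
    grass genotypes from balanced field trials. Implements forage-quality
    indices (digestible dry matter, dry-matter intake, relative feed
    value, crude protein), assumption screening (Lilliefors
    Kolmogorov-Smirnov with Monte-Carlo p-values, median-based Levene
    test), one- and two-way fixed-effects ANOVA with partial eta-squared
    and protected LSD comparisons with compact letter displays, k-means++
    clustering with silhouette-based k selection, Mantel permutation
    tests, entropy-weighted TOPSIS multi-criteria genotype ranking,
    permutation-based random-forest variable importance, and piecewise
    structural equation modelling with d-separation basis sets and
    Fisher's C. A synthetic trial generator with known ground truth
    (additive genotype, year and block effects, genotype-by-year
    interaction, linear-Gaussian path models) makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    nortest,
    car,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
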