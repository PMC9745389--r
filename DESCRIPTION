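Package: climrich
Title: Colonization Time, Diversification Rate, and Climate-Richness
    Relationships on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether climate-richness relationships arise from
    earlier colonization of climatic zones (the time-for-speciation effect) or
    from faster net diversification in those zones. Provides climatic binning
    of gridded species occurrences with local and regional richness,
    method-of-moments stem-age diversification estimators and the equal-splits
    (DR) tip rate, maximum-likelihood fitting of Brownian motion, lambda,
    Ornstein-Uhlenbeck and white-noise trait models with AIC comparison,
    Pagel's lambda phylogenetic signal with a likelihood-ratio test,
    ancestral climate-niche reconstruction (including a two-stage
    genus-level workflow), per-bin first-colonization times, ordinary and
    phylogenetic generalized least squares regressions, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    nlme
Config/testthat/edition: 3
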