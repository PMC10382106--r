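Package: neonorm
Title: Gaussian-Process Normative Models of Perioperative Neonatal Brain Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Gaussian-process normative growth curves for regional
    neonatal brain volumes as a function of postmenstrual age, postnatal
    days and sex, and scores individual scans as deviation Z-scores against
    the normative reference. Paired pre- and post-operative scores are
    turned into per-infant growth trajectories (Z-score slope changes),
    flagged against extreme-deviation thresholds, and analysed with a
    nonparametric clinical-association battery (paired Wilcoxon,
    Kruskal-Wallis, Mann-Whitney, Fisher exact, Spearman and partial
    Spearman correlations) with Benjamini-Hochberg false-discovery-rate
    correction. Includes a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
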