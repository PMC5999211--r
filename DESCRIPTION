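Package: matesel
Title: Mating Patterns and Sexual Selection from Microsatellite Parentage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mating patterns and sexual selection in
    harvested crustacean populations from microsatellite parentage data.
    Provides a synthetic-population generator (size distributions, size-biased
    mating with occasional skewed multiple paternity, Mendelian broods with an
    allelic-dropout/false-allele observation layer, and mark-recapture growth
    series), genotype input/output with quality-control filters, descriptive
    and inferential population genetics (exact Hardy-Weinberg tests,
    Weir-Cockerham F-statistics, linkage disequilibrium, null alleles,
    second-parent exclusion probabilities), genotyping-error-aware paternity
    assignment with simulation-calibrated confidence, Monte-Carlo power to
    detect multiple paternity, growth back-adjustment of male size to the
    mating year, and estimation of size-assortative mating models, selection
    differentials and logistic-regression selection gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
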