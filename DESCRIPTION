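Package: hacoef
Title: Hierarchical Association Coefficient for Marker-Trait Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the hierarchical association coefficient (HA-coefficient),
    a bounded [0,1] measure of association between a quantitative trait and a
    categorical marker, from a closed-form area ratio under the hierarchical
    association distance curve. Includes a one-way ANOVA F-test baseline, a
    simulation harness that regenerates triangle-patterned genotype matrices
    for validating the statistic, and a per-marker scan driver with TSV and
    minimal VCF input for GWAS-style use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
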