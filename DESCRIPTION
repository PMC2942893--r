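Package: fstpower
Title: Power of F(ST)-Outlier Scans for Loci Under Domestication Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of a single bi-allelic
    locus in parallel finite populations, with additive viability selection,
    and Monte Carlo estimation of the statistical power of two F(ST)-outlier
    designs for detecting loci under artificial (domestication) selection:
    a low-F(ST) scan among independently selected farmed strains, and a
    high-F(ST) scan between a pooled farmed and a pooled wild metapopulation.
    F(ST) is estimated with the Weir-Cockerham (1984) theta variance-component
    estimator; power is read off empirical percentiles of a simulated
    no-selection null distribution.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
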