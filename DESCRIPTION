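Package: acprofiler
Title: Activity Correlation Profiling for Co-Fractionation Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identify which protein in a crude membrane-protein mixture
    carries a biochemical activity by correlating per-fraction protein
    abundance profiles from velocity-gradient co-fractionation mass
    spectrometry with a per-fraction activity profile. Includes a synthetic
    gradient and TMT-quantification simulator, a Poisson occupancy model of
    end-point lectin-capture reconstitution assays, Pearson profile
    correlation with technical-replicate aggregation, annotation-driven
    candidate curation with Venn accounting, scenario experiments probing
    quaternary-structure failure modes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
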