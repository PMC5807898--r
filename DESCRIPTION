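Package: viromass
Title: Quantitative Mass Apportioning and Profiling of ssDNA and dsDNA Viral Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts measured single-stranded and double-stranded viral DNA mass
    concentrations in marine sediment into genome-copy abundance intervals under
    assumed genome-size ranges, and compares the result against fluorescence-based
    direct virus counts. Also classifies virome reads into ssDNA/dsDNA viral family
    profiles by lowest-common-ancestor assignment of BLAST tabular hits, applies
    rRNA-contamination quality criteria to virome libraries, ordinates community
    composition profiles by principal component analysis, and ships a seeded
    synthetic benthic viral community simulator (DNA masses, read profiles, hit
    tables, direct counts) so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
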