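Package: sibmap
Title: Bin-Marker Linkage Maps and QTL Scans for Outcrossed F1 Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic mapping in a full-sib (CP, pseudo-testcross)
    family of an outbreeding species genotyped by whole-genome resequencing.
    Provides quality masking and segregation typing of bi-allelic SNPs with
    chi-square distortion filtering, a five-step sliding-window bin-marker
    construction, two-point recombination-fraction estimation by EM with
    phase inference, linkage grouping and marker ordering with Kosambi map
    distances, consensus-map merging through hkxhk bridge markers, interval
    mapping and Kruskal-Wallis QTL scans with LOD-drop support intervals,
    GRM-based narrow-sense heritability, SNP-bin collinearity analysis, and
    genetic-map-guided scaffold re-anchoring with AGP output. A synthetic
    F1 population generator with recorded ground truth makes the whole
    chain testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    vcfR
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
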