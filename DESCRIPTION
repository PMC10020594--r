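Package: terpseg
Title: Segregation Genetics and Trichome Terpene Phenotyping for Interspecific Tomato Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting qualitative metabolite phenotypes in F2
    populations from interspecific tomato crosses. Enumerates multi-locus
    Mendelian models (recessive and dominant locus requirements) for a
    selfed-F1 population, ranks them against observed high/low segregation
    counts by Pearson chi-square goodness-of-fit, normalizes integrated GC-MS
    peak tables to internal-standard-corrected quantities per mg fresh weight
    or per glandular trichome, classifies plants against a parental reference
    interval, computes trichome densities and prolate-spheroid storage-cavity
    volumes, and forward-simulates F2 populations with the statistical
    structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
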