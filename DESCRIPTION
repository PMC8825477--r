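Package: macploidy
Title: Molecular Karyotyping of Interploidy-Cross Progeny from SSR Allele Dosage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers chromosome compositions of progeny from interploidy crosses
    (e.g. a diploid x triploid Populus cross) using capillary-electrophoresis
    microsatellite (SSR) peak tables. Implements microsatellite allele
    counting-peak ratio (MAC-PR) dosage estimation to assign allelic
    configurations per locus, aggregates locus copy numbers into per-chromosome
    calls, detects segmental duplication/deletion events from within-chromosome
    marker discordance, classifies ploidy (hypo-/hyper-/eu- tri- and
    tetraploid), quantifies observed heterozygosity and paternal heterozygosity
    transmission, and provides a truth-labelled forward simulator of triploid
    meiosis (unequal 1:2 segregation, first/second division restitution,
    chromosome elimination, crossovers) for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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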