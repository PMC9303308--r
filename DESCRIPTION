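Package: twistspacer
Title: Supercoiling Sensitivity of Bacterial Promoters from Spacer Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Thermodynamic model of how the length of the spacer between the
    -35 and -10 hexamers couples sigma70 promoter activity to the DNA
    supercoiling level during closed-complex formation. The spacer is treated
    as a torsional spring that RNA polymerase must (un)twist to an optimal
    -35/-10 angle; the resulting orientational free energy yields
    parameter-free predictions of relative expression slopes and shock
    fold-changes. The package provides the model (including a
    sequence-dependent dinucleotide-twist extension), analysis pipelines for
    in vitro supercoiling titrations, plate-reader reporter shock assays and
    genome-wide promoter-map statistics, and seeded synthetic-data generators
    emulating each input, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
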