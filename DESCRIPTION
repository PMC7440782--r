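Package: mycodamp
Title: Fungal Signatures of Building Moisture Damage from Mycobiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted and untargeted analysis of indoor fungal (ITS amplicon)
    count data for signals of building moisture damage. Classifies fungi into
    moisture guilds (hydrophilic, mesophilic, xerophilic) from curated minimum
    water-activity requirements, aggregates guild and ERMI group-1 counts, and
    relates them to researcher-assessed damage indicators with negative
    binomial regressions offset by log total reads (relative abundance) or
    unoffset on qPCR-scaled loads (absolute abundance). Also compares indoor
    communities to composite outdoor profiles with Bray-Curtis distances,
    screens for indicator taxa with an ANCOM-style W statistic, derives the
    standard home- and room-level damage indicators including a 0-6 composite
    index, and generates fully synthetic studies with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
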