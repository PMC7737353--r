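Package: karyotracer
Title: Reconstruction of Complex Cancer Karyotypes from SNP-Array and FISH Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing complex, mosaic cancer karyotypes from
    SNP-array log R ratio (LRR) and B-allele frequency (BAF) tracks combined
    with targeted metaphase and interphase FISH evidence. Provides a
    homologue-aware genome and karyotype data model with rearrangement events
    and chromosome-viability checking; simulators for SNP-probe panels, array
    tracks and FISH signal tables; an inference core that segments tracks,
    extracts BAF bands, enumerates allele configurations, estimates mosaic
    cell fractions and calls per-segment homologue dosage; and assembly
    routines that integrate segment calls with FISH membership evidence to
    compose derivative chromosomes and detect centromere and telomere capture.
    Ships an encoded U937 cell-line fixture and a random-scenario generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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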