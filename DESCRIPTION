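Package: synaptodev
Title: Quantification Pipelines for NMDA-Receptor Maturation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable, tested implementations of the quantification
    procedures used in studies of NMDA-receptor subunit maturation in
    cultured and in vivo cortical neurons: biexponential fitting of evoked
    NMDAR-EPSC decays with the amplitude-weighted time constant, kymograph
    extraction of dendritic GCaMP signals along wide line ROIs with
    delta-F/F0, per-site transient AUC, diffusion distance, frequency and
    synchrony read-outs, threshold-and-particle quantification of
    autofluorescent lipopigment and lysosome puncta with circularity
    filters, plate-reader viability normalization, densitometry ratios for
    the acyl-PEGyl exchange gel-shift (APEGS) palmitoylation assay, and the
    accompanying group statistics. Seeded synthetic-data generators with
    ground-truth records make every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
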