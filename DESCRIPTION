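Package: hcscreen
Title: Image-Based Co-Culture Phenotypic Screening for Cancer-Selective
    Cytotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-content phenotypic screens run on
    co-cultures of hepatocellular carcinoma (HCC) cells with hepatocytes.
    Provides a seeded synthetic-screen generator (multi-channel well images
    plus plate and viability tables with per-cell ground truth), nuclei
    segmentation and two-marker (CHALV1/AFP) cell classification,
    dual-population inhibition with Z'-factor plate quality control and
    selective-hit calling, constrained four-parameter logistic dose-response
    fitting with IC50 enhancement-ratio selectivity, per-cell organelle
    readouts (lysosomal puncta, cathepsin-B translocation, nuclear intensity
    channels, caspase activation), spheroid mid-plane apoptosis scoring, and
    co-culture seeding-design arithmetic from population doubling times.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
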