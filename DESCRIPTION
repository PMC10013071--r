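Package: tissueIIF
Title: Computer-Aided Reading of Indirect Immunofluorescence on Tissue Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation-guided classification of indirect immunofluorescence
    (IIF) patterns on primate salt-split skin and monkey esophagus biochips
    for the serological work-up of autoimmune bullous dermatoses. Provides an
    encoder-decoder tissue segmenter, attention-line extraction by binary
    morphology, Poisson-disc patch sampling with a two-head patch classifier
    and the associated aggregation and brightness statistics, a dual-input
    esophagus pattern classifier with quantile intensity extraction, dilution
    series titer estimation, agreement statistics (accuracy, positive and
    negative percent agreement), and a seeded synthetic image generator with
    exact ground truth for desk-scale training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
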