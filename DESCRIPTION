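Package: protosal
Title: Proto-Object Saliency Maps with Second-Order Texture Channels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Bottom-up visual saliency prediction built on perceptual grouping
    of proto-objects. Images are decomposed into intensity and color-opponency
    feature pyramids, filtered with even-symmetric Gabor banks, and passed
    through filter-rectify-filter texture channels (spatial pooling,
    cross-scale and cross-orientation products with circular max-pooling).
    A border-ownership and grouping stage assigns figure-ground structure and
    assembles channel conspicuity into a saliency map. Includes the standard
    fixation-prediction evaluation metrics (CC, SIM, NSS, KLD, shuffled AUC),
    blur-sigma sweeps, distance-to-center re-weighting, an inter-observer
    baseline, and generators for synthetic texture-defined and pop-out
    stimuli with simulated observers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
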