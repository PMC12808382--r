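Package: petperf
Title: Muscle Perfusion Quantification from Dynamic [15O]H2O PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies skeletal-muscle perfusion from dynamic [15O]H2O
    PET-CT of the lower leg. Provides image-derived input function (IDIF)
    extraction from the superficial femoral artery, contour- and sphere-based
    muscle volume-of-interest construction, one-tissue compartment model
    fitting with blood-delay estimation (basis-function method), and
    intra-/interrater agreement statistics (ICC(2,1), Bland-Altman limits of
    agreement). A parametric digital lower-leg phantom with known
    ground-truth kinetics, realistic frame timing, radioactive decay and
    Poisson count noise makes every stage of the pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
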