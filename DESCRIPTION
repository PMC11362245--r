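Package: sononav
Title: Tracked Freehand Ultrasound Navigation for Needle Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for image-guided needle biopsy under tracked freehand
    ultrasound. Registers a lesion segmented in a 2-D B-mode frame into the
    3-D world frame of an optical tracking camera through a rigid transform
    chain, calibrates the probe (image-to-tool transform plus pixel spacing)
    and the needle tip (pivot calibration), classifies needle alignment
    against the registered spherical target with a three-tier acoustic
    feedback mapping (200/350/440 Hz), and evaluates surgical accuracy on a
    simulated evaluation phantom: per-trial euclidean deviations, mean
    position, maximum surgical deviation and hit count. A phantom simulator
    provides noisy tracked pose streams and speckled B-mode-like frames with
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
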