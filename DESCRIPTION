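Package: gocao
Title: Visible and Infrared Image Registration via Gabor-Ordinal Contour
    Angle Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registration of visible and thermal-infrared image pairs of
    animal bodies acquired by co-mounted cameras with very different
    resolutions and spectral responses. Contour feature maps are built with
    an even-symmetric Gabor filter bank followed by a zero-sum ordinal
    (centre-surround) filter; corner keypoints are detected on the extracted
    contour chains by curvature-scale-space analysis and each receives a
    main orientation from the angular bisector of its two contour arms.
    Modified SIFT descriptors with folded gradient orientations provide
    contrast-reversal invariance across modalities; bilateral (mutual
    nearest-neighbour) matching, RANSAC similarity estimation and windowed
    normalized cross-correlation refinement produce a rough-to-fine
    registration. Includes the standard evaluation metrics (RMSE, precision,
    recall, accuracy, orientation agreement) and a synthetic ground-truthed
    multi-modal pair generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
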