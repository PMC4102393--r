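Package: nemaswim
Title: Quantitative Analysis of C. elegans Swim Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the swimming gait of Caenorhabditis elegans
    from video or from externally tracked centerlines. Implements multi-animal
    centerline tracking (standard-deviation filtering, greedy gradient-flow
    contouring, inner distance transform), a curvature kymograph, a
    multi-window short-time two-dimensional Fourier analysis of the body wave,
    and ten behavioral measures (wave initiation rate, body wave number,
    asymmetry, stretch, attenuation, reverse swimming, curling, travel speed,
    brush stroke, activity index) with robust per-trial summaries. Includes a
    synthetic swimmer generator for validation, a flat-file trial registry, and
    grouped statistical comparison with plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
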