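Package: thermoloc
Title: Heat-Source Localization from Surface Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady-state bioheat forward modelling and analytic inversion for
    locating an embedded spherical heat source (such as a superficial tumor)
    from skin-surface temperature data. Implements the point-source solution of
    the steady-state Pennes bioheat equation, closed-form inversion of surface
    temperatures to source depth, intensity and radius, a small feed-forward
    neural surrogate for parameter refinement, parameter and temperature-error
    sensitivity studies, synthetic thermogram generation with seeded noise
    models, CSV/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
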