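Package: eritwin
Title: Digital-Twin Apposition Analysis and Endoleak Risk Index for EVAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stent-graft apposition in the proximal sealing zone of
    an endovascular aneurysm repair (EVAR) from triangulated surface meshes of
    the aortic lumen and the deployed stent-graft. Cross-sectional slices taken
    every 0.5 mm along the centerline are discretized into around 200 radial
    measurements per circumference for both structures, yielding a dense
    radius/gap field from which three physics-informed features are derived:
    aortic conicity, stent-graft shape (ovalization), and the longitudinal
    extent of stent-graft malapposition. The features combine into a normalized
    Endoleak Risk Index (ERI) with a 0.80 decision cutoff for type IA endoleak
    prediction. Also provides parametric synthetic aorta/graft generators that
    emulate deployed configurations, geometric-fidelity validation (volumetric
    Dice coefficient, symmetric Hausdorff distance), an orthotropic
    aortic-wall stiffness utility, a logistic risk model, and a
    diagnostic-accuracy and propensity-score-matching evaluation layer with
    exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
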