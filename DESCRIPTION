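Package: ablatr
Title: Coupled Electro-Thermal-Fluid Simulation of Cardiac Catheter Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of endocardial catheter ablation in a
    three-layer slab model of the cardiac chamber (blood, myocardium, skeletal
    muscle). Implements temperature-controlled radiofrequency ablation (PI
    voltage control, 500 kHz quasi-static conduction) and pulsed field ablation
    (irreversible electroporation with a field-dependent Gompertz conductivity,
    150 kHz burst protocol), coupled to the Pennes bioheat equation with an
    enthalpy-method phase change and to a stationary laminar blood-flow field.
    Provides parametric geometry and graded tetrahedral mesh generation for
    monopolar and bipolar catheter configurations, analytic verification
    fixtures, Arrhenius thermal-damage integration, and lesion morphometry
    (volume, depth, width, symmetry ratio) together with declarative study
    runners for blood-velocity and catheter-orientation sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
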