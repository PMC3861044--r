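Package: baroafferent
Title: Mechanistic Modelling of Afferent Baroreceptor Firing
Version: 0.1.0
Authors@R:
    person("Ryle", "Govind", email = "rgovind@posteo.net", role = c("aut", "cre"))
Description: A modular simulator and estimation toolkit for afferent
    baroreceptor dynamics. Blood pressure is mapped to circumferential
    arterial wall strain (linear elastic, sigmoidal nonlinear elastic, or
    standard-linear-solid viscoelastic wall, unified under quasi-linear
    viscoelasticity), wall strain to mechanoreceptor nerve-ending strain
    (chains of one to three Voigt bodies in series with a spring), and
    nerve-ending strain to firing rate (linear amplifier or leaky
    integrate-and-fire neuron). Composite models are simulated from
    relaxed steady states with an exact modal integrator, and fitted to
    firing-rate recordings with sensitivity-based subset selection,
    Levenberg-Marquardt and Nelder-Mead optimisation. Includes detectors
    for the classical qualitative firing phenomena (threshold, saturation,
    adaptation, post-excitatory depression, hysteresis, rectification) and
    a synthetic-data generator emulating the classical rat protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
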