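Package: allostat
Title: Active-Inference Simulation of Homeostatic Reflex Arcs Under
    Allostatic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a minimal active-inference model of a homeostatic
    reflex arc: a physiological state is sensed through a noisy
    viscerosensory channel, compared against a Gaussian setpoint belief,
    and corrected by actions proportional to the precision-weighted
    prediction error (gradient descent on interoceptive surprise).
    Allostatic control is modelled as scheduled, time-varying changes of
    the setpoint belief's mean and precision. A metacognitive layer
    monitors the surprise stream, maintains an allostatic self-efficacy
    belief, and classifies a two-stage progression from normal regulation
    through fatigue to a generalized low-self-efficacy state. Five lesion
    loci (sensor, allostatic predictor, effector, body, metacognition)
    can be injected to produce distinguishable dysfunction signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
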