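Package: bgspike
Title: Spiking Basal Ganglia Network Model of Learning, Medication, and
    Deep Brain Stimulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-dimensional spiking network model of the basal
    ganglia built from Izhikevich neurons arranged in lattices for the
    subthalamic nucleus (STN) and the external and internal globus pallidus
    (GPe, GPi), driven by Poisson medium-spiny-neuron input whose rate
    encodes learned cortico-striatal weights.  A temporal-difference
    dopamine signal trains D1 and D2 weight channels under healthy,
    Parkinsonian (OFF and medicated ON) and subthalamic
    deep-brain-stimulation conditions, including Gaussian electrode current
    spread and antidromic activation of GPe.  Action selection and reaction
    times come from a mutual-inhibition race over normalized, reversed GPi
    firing.  An experiment harness runs the probabilistic learning task
    (train on AB/CD/EF with 80/20, 70/30, 60/40 reward schedules; test on
    all novel pairs) and computes training-accuracy curves,
    difference-in-reward-expectation, choose-A/avoid-B accuracy,
    conflict-resolved reaction times, and accuracy-versus-DRE regression
    fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
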