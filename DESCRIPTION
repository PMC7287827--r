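Package: protoacoustics
Title: Ionoacoustic Bragg Peak Monitoring for Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator of the full ionoacoustic monitoring chain
    for proton therapy of the brain: analytic Bragg-curve dose deposition of
    a pulsed proton beam, thermoacoustic pressure generation by retarded-time
    discretization of the thermoacoustic integral, ray-acoustic amplitude
    propagation with attenuation, a small 2-D finite-difference acoustic
    solver for time-of-arrival validation, cerebrospinal-fluid/skull
    interface physics (Snell refraction, power transmission, arrival-time
    correction), piezoelectric disc resonance design for the signal band,
    and time-difference-of-arrival reconstruction of the Bragg peak position
    by damped Gauss-Newton multilateration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
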