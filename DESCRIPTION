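Package: anomdiff
Title: Anomalous-Diffusion Modelling of Disease-Symptom Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the time evolution of a binned clinical parameter
    (thoracic fluid content, TFC, measured by impedance cardiography) as
    subdiffusion governed by a fractional Fokker-Planck equation.  Provides
    a numerically careful evaluator for the subdiffusive propagator (power
    series in the similarity variable with a fixed-Talbot inverse-Laplace
    fallback), closed-form fractional moments, evolution of 15-slot binned
    distributions by kernel convolution, RMSE-based estimation of the
    anomalous exponent alpha and generalized diffusion coefficient, the
    Hurst exponent H = alpha/2, and a continuous-time random walk (CTRW)
    generator of synthetic longitudinal cohorts with irregular visit times
    for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
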