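Package: psonet
Title: Swarm-Optimized Neural Forecasting of Chaotic Time Series with
    Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Short-term forecasting of chaotic time series with a
    feed-forward neural network trained by inertia-weight particle swarm
    optimization (PSO), applied to the Mackey-Glass delay-differential
    benchmark.  Includes a fourth-order Runge-Kutta integrator for the
    Mackey-Glass equation, Gaussian white-noise corruption, delay-coordinate
    embedding, a Monte-Carlo stochastic predictor that propagates input
    noise into per-point prediction uncertainties, hidden-layer-size sweeps
    with linear noise laws, and chaos diagnostics (Lyapunov spectra from the
    linearized delay system and from data, Kaplan-Yorke dimension).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, graphics, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
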