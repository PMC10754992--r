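Package: spikesharp
Title: Threshold-Sharpened Spiking Networks for Parkinsonian Spike-Timing
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for time-domain detection of parkinsonian activity from
    subthalamic-nucleus (STN) spike timing. Generates labeled healthy and
    parkinsonian spike-timing datasets with a phenomenological point-process
    generator and a reduced cortico-basal-ganglia-thalamus spiking-circuit
    simulator; trains spiking LSTM and feedforward detectors whose
    bounded-ReLU activations are progressively sharpened into binary
    threshold units during training; evaluates classifiers with confusion
    based metrics, rank-based AUC, beta-band (13-30 Hz) spectral analysis,
    and a Gaussian spike-timing jitter robustness protocol; and maps trained
    weights onto simulated memristive crossbar arrays (differential
    conductance pairs, quantized levels, subarray tiling) for in-memory
    vector-matrix-multiply inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
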