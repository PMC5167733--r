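Package: dcmerp
Title: Dynamic Causal Modeling of Evoked Somatosensory Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to ask whether somatosensory input reaches the secondary
    somatosensory cortex (SII) directly from the thalamus (parallel routing)
    or only via the primary somatosensory cortex (SI) (serial routing), and
    whether the dominant route changes over peri-stimulus time.  Implements
    a three-node evoked-response neural mass network (contralateral SI,
    contralateral SII, ipsilateral SII) with Gaussian phasic and sustained
    thalamic drives, a linear sensor observation model with spatial-mode
    reduction, MEG-style preprocessing (band-pass filtering, epoching,
    baseline correction, signal-space artifact projection), variational
    Laplace model inversion with a free-energy approximation to the log
    model evidence, random-effects Bayesian model selection with exceedance
    probabilities over sliding and incremental peri-stimulus windows,
    Bayesian model averaging of thalamic input strengths, and a synthetic
    multi-subject MEG-like data generator with known ground truth for
    end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
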