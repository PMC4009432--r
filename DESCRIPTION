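Package: sdmemory
Title: Sparse Distributed Memory and the Critical Distance of Recall
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An implementation of Kanerva-style Sparse Distributed Memory:
    an associative memory over the binary hypercube with Hamming-ball
    activation, counter-based distributed writes and majority-vote reads.
    Includes the analytic critical-distance machinery (shared-circle
    overlap counts, cell-assembly load, per-bit wrong-read probabilities
    and the squared-residual objective whose integer minimizer locates the
    convergence/divergence boundary of iterated reading), plus scaled
    simulation experiments that estimate the empirical critical band under
    varying memory saturation, rehearsal count and iteration budget.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
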