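Package: nisland
Title: Piecewise-Stationary n-Island Coalescent Models and IICR-Based
    Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting PSMC-style effective-size curves under
    population structure. Computes the exact IICR (inverse instantaneous
    coalescence rate) of symmetric n-island models whose migration rate
    changes between time components, simulates pairwise coalescence times
    (T2) and the corresponding empirical IICR, reads and writes PSMC text
    output with theta-based rescaling to years and diploid Ne, fits
    connectivity-change scenarios to target curves by seeded stochastic
    distance minimization with re-inference validation, and reports the
    competing panmictic (size-change) and structured (connectivity-change)
    readings of the same curve side by side.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
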