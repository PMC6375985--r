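Package: ptxshim
Title: Optimized Parallel-Transmit RF Shimming for Implant Heating Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying radiofrequency (RF) heating of deep-brain-stimulation
    (DBS) lead tips during MRI and its suppression by parallel-transmit (pTx) RF
    shimming. Combines per-coil electromagnetic field maps under complex channel
    weights, minimizes a two-term cost (local E-field power near the exposed lead
    tip plus transmit-field inhomogeneity) with a safety-limited lambda-selection
    procedure, and evaluates outcomes via 1 g averaged SAR, whole-head SAR, the
    coefficient of variation of B1+, and a finite-difference Pennes bioheat
    temperature solver. Includes a quasi-static electromagnetic surrogate (coil
    arrays, head phantoms, seeded lead trajectories, implant-tip coupling) so the
    full workflow runs at desk scale without an external field solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
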