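Package: ddrsim
Title: Hybrid Stochastic-Deterministic Simulation of the ATM/p53/NF-kB/Wip1
    DNA Damage Response Network
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell simulator of the DNA damage response signalling
    network connecting ATM, p53, NF-kB and the Wip1 phosphatase.  The
    continuous part of the network (protein and transcript kinetics across
    the extracellular space, cytoplasm and nucleus) is integrated with a
    fixed-step Runge-Kutta scheme, while gene allele switching, DNA
    double-strand break appearance and repair, and TNF receptor turnover are
    simulated as exact discrete events (direct Gillespie method) following
    the Haseltine-Rawlings partitioning.  Virtual experiment protocols
    (ionizing radiation dosing, TNF-alpha pulses, shRNA knockdown),
    population runs with per-cell fate classification (apoptosis, cell-cycle
    arrest, clonogenic viability) and supporting statistics (chi-squared
    comparison against count data, one-at-a-time parameter sensitivity,
    half-life regression) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
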