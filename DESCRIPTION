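Package: ftacv
Title: Simulation and Inference for Fourier-Transformed AC Voltammetry of
    Surface-Confined Redox Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation of low-frequency large-amplitude Fourier
    transformed alternating current voltammetry (FTACV) for surface-confined
    one- and two-electron Butler-Volmer redox processes with a dual cubic
    polynomial capacitive background and Ohmic drop; harmonic decomposition of
    current traces by Fourier band selection; a two-step inverse-problem
    fitting procedure (time-domain capacitance/resistance fit followed by a
    Fourier-domain Faradaic parameter fit) with multi-start derivative-free
    optimization; discrimination between sequential one-electron and concerted
    two-electron transfer mechanisms; and square-scheme (Pourbaix) inference
    of pKa values and reversible potentials from apparent potentials versus
    pH by maximum likelihood and adaptive Metropolis MCMC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
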