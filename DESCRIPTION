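Package: strfdev
Title: Spatiotemporal Receptive Fields, Excitability, and the Development
    of Direction Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vivo intracellular recordings from
    visual cortical simple cells: reverse-correlation estimation of
    spatiotemporal receptive fields (STRFs) from membrane potential
    responses to sparse one-dimensional noise, connected-component and
    ellipse-moment analysis of ON/OFF subunits, prediction of direction
    selectivity from the STRF's two-dimensional Fourier amplitude
    spectrum, F0/F1 grating-response analysis with double-Gaussian
    tuning fits, spike-waveform excitability metrics (maximum dV/dt,
    spike kink, width at half height), rectified power-law fits of the
    voltage-to-firing-rate transform, and a bootstrap mixture model that
    pairs one cell's voltage waveforms with another cell's transform.  A
    synthetic-data module generates stimuli, ground-truth space-time
    kernels, membrane-potential traces, and spikes for naive and
    experienced cell groups so that every stage of the pipeline can be
    validated against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
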