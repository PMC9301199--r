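Package: nasalpbpk
Title: Semi-Physiological PBPK Modelling of Intranasal and Oral Drug
    Delivery to the Human Respiratory Tract
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A semi-physiologically based pharmacokinetic (semi-PBPK) model
    of the human respiratory tract (nasal cavity, pharynx, bronchi,
    bronchioles, alveoli) coupled to a one-compartment systemic disposition
    model, for intranasal and oral drug administration.  Provides derivation
    of permeability-surface area products and nasal volumes from airway
    geometry and Caco-2 permeability scaling, a compiled ODE simulator with
    dosing events and mucociliary clearance, nonlinear least-squares
    estimation of systemic parameters and nasal deposition fractions from
    mean concentration-time profiles, virtual-population Monte Carlo
    simulation with lognormal inter-individual variability, and
    noncompartmental analysis (Cmax, AUC, terminal half-life, accumulation
    ratios, time to steady state).  Includes a synthetic-data generator that
    emulates clinical sampling grids, proportional residual error and
    LLOQ-to-zero censoring, so the full fitting pipeline is testable without
    clinical data.  The worked case is varenicline nasal spray.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
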