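Package: idpcollapse
Title: Coil-Globule Collapse and Heterogeneous Binding Analysis for
    Disordered Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of the temperature-driven coil-to-globule
    collapse of intrinsically disordered proteins and of their heterogeneous
    ligand binding. Converts dynamic light scattering diffusion data to
    hydrodynamic radii via the Stokes-Einstein relation, interconverts
    hydrodynamic radius and radius of gyration for disordered chains, and
    evaluates Flory polymer scaling laws. Extracts absolute molar heat
    capacities from concentration-series differential scanning calorimetry,
    computes folded and unfolded baselines and excess enthalpic fluctuations,
    and fits the variable-barrier (Landau) model of continuous conformational
    transitions. Fits two-state melting curves from multiple spectroscopic
    probes and performs singular value decomposition of wavelength by
    temperature spectral matrices. Implements Hill analysis of binding
    isotherms and a quenched-heterogeneity ensemble model in which
    per-molecule binding free energies are normally distributed, including
    inference of the distribution width that reproduces an observed Hill
    coefficient below one. A seeded synthetic-data module emulates all the
    instrument data classes the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
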