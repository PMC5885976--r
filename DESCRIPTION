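Package: sfgtilt
Title: Orientation Analysis of Interfacial Alpha-Helical Peptides from
    Polarized Sum-Frequency-Generation Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to determine the tilt angle of alpha-helical peptides
    adsorbed at a planar interface from polarized sum-frequency-generation
    (SFG) amide-I spectra.  Fits ssp and ppp intensity spectra with the
    standard nonresonant-plus-Lorentzian interference model, forms the
    chi_ppp/chi_ssp amplitude ratio, computes the forward optical model
    (helix amide-I hyperpolarizability, Euler-angle orientational
    averaging, Fresnel local-field factors) and inverts the measured ratio
    against the resulting orientation curve.  Also post-processes structure
    snapshots in PDB format for helix-axis tilt, helicity and
    surface-contact analysis, and ships a synthetic-data module (ideal
    helices at prescribed orientations, synthetic interference spectra, the
    study peptide sequences) so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
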