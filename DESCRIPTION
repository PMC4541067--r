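Package: starkfp
Title: Internal Electric Fields in Fluorescent Proteins from Stark-Effect Spectroscopy
Version: 0.1.0
Authors@R:
    person("starkfp", "maintainers", email = "starkfp@example.org", role = c("aut", "cre"))
Description: All-optical analysis of internal electrostatic fields in GFP-type
    fluorescent proteins. Converts one- and two-photon absorption spectra into
    the chromophore dipole-moment change via shared-width Gaussian band
    decomposition and a two-level model, maps dipole changes to total and
    long-range internal fields through the quadratic Stark effect, fits the
    transition-frequency parabola and the field-fluctuation broadening model
    across protein ensembles, evaluates Onsager-type solvent reaction fields,
    and computes projected electrostatic fields from charge-annotated
    structures (PQR or PDB plus charge tables) by point-charge potential
    summation. Includes seeded synthetic-data generators with analytic ground
    truth for every stage, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
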