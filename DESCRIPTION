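Package: coordphoto
Title: Coordinated C3 Photosynthesis and the CO2 Fertilization Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling of the CO2 fertilization effect on gross
    primary production with a Farquhar-von Caemmerer C3 leaf, dynamic
    coordination of Rubisco and electron-transport capacity (daily
    optimization of the Jmax:Vcmax ratio under an effective-nitrogen
    constraint), a two-leaf toy canopy with prognostic leaf area, factorial
    driver attribution of GPP trends, a partition of the CO2 effect into
    leaf-level and greening components, and a perturbation-ensemble analysis
    of the seasonal CO2 amplitude using a one-box Northern-Hemisphere
    concentration surrogate. Includes a seeded synthetic forcing generator
    (diurnal meteorology, CO2 trajectories, toy grid) that drives all
    experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
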