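Package: ghef
Title: Hybrid Gradient-Boosting Ensembles with Evidence Fusion for
    Supercritical CO2 Drug Solubility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting equilibrium solubility of lipophilic
    drugs in supercritical carbon dioxide from temperature, pressure,
    molecular weight and melting point. Two gradient-boosted tree
    learners (classic and histogram-binned) are tuned by the Electric
    Eel Foraging Optimization metaheuristic and fused either by
    simplex-weighted averaging or by Dempster-Shafer evidence
    combination over a discretized solubility frame. Includes a
    synthetic data generator emulating factorial temperature-pressure
    solubility designs, k-fold cross-validation, the usual regression
    error statistics, Kruskal-Wallis feature screening, local surrogate
    attribution, and bootstrapped percentile prediction intervals with
    coverage calibration reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
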