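Package: gparchetypes
Title: Discovering GP Practice Archetypes from Prescribing and Geolocation Data
Version: 0.1.0
Authors@R:
    person("Open Health Analytics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A reproducible pipeline for classifying general-practitioner (GP)
    practices into archetypes from open prescribing and dispensing data.
    Practice-level features (pharmacy counts, items dispensed per registered
    patient, item-weighted distance to dispensing pharmacies, local population
    density, list size) are standardised and clustered with k-means; the number
    of clusters is selected by the elbow and silhouette methods and clusters are
    labelled Metropolitan / Non-Metropolitan by their population-density
    centroid. Prescribing behaviour of the discovered clusters is compared by
    British National Formulary (BNF) chapter and section using per-patient
    monthly series and RMSE, with Welch t-tests at section level, and cluster
    membership is cross-tabulated against ward deprivation quartiles. A
    calibrated synthetic-cohort generator emulates the five input tables so the
    whole pipeline is testable without access to the original open datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    cluster,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
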