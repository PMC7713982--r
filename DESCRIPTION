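Package: grousehab
Title: Seasonal Second-Order Habitat Selection Modeling for Greater Sage-Grouse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A use-availability pipeline for mapping seasonal habitat selection of
    greater sage-grouse (Centrocercus urophasianus) at the 1-km grain. Builds
    landscape-context covariates from fine-grain rasters and vector features
    (circular-buffer land cover proportions, vector ruggedness, line densities,
    burned-area fractions, seasonal climate normals), assigns used points to
    biological seasons and Voronoi-defined sites, draws stratum-matched available
    points, fits balanced random-forest classifiers with leave-one-site-out
    spatial cross-validation, evaluates them with pooled confusion matrices and
    use-availability calibration curves, and converts predictions to relative
    selection strength (RSS) surfaces, fold-averaged seasonal maps, year-round
    habitat masks, and single-predictor response curves. Includes a seeded
    synthetic landscape and telemetry simulator with known selection coefficients
    so the full pipeline is testable without protected location data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
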