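Package: fpudose
Title: Fat-Protein Unit Insulin Dosing and Postprandial CGM Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mealtime insulin bolus algorithms for type-1 diabetes
    (carbohydrate counting, the modified 200-kcal fat-protein-unit
    algorithm, and the original 100-kcal Pankowska equation), a complete
    suite of postprandial continuous-glucose-monitoring outcome metrics
    (window means, peak and time to peak, total and incremental AUC, MAGE,
    time in/above/below range, hypoglycemia episode detection, 30-minute
    excursions), a seeded synthetic four-arm crossover CGM simulator, and
    paired within-subject comparison of dosing algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
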