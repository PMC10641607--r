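Package: admark
Title: Exposure and Persuasive-Appeal Analysis of Televised Food Advertising
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for monitoring televised food marketing seen by child
    audiences. Converts instance-level audience rating points into average
    weekly impressions per unique advertisement and demographic stratum,
    selects the most-viewed fraction of ads, classifies advertised products
    as "high-in" critical nutrients under the Pan American Health
    Organization (PAHO) nutrient profile model, scores the variety of
    emotional and rational persuasive appeals coded per ad, assesses
    intercoder reliability (percent agreement, Cohen's kappa), and runs the
    stratified nonparametric and paired comparisons used in food-marketing
    surveillance. A seeded synthetic-data generator emulates proprietary
    ratings exports so the full pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
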