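Package: elderfit
Title: Force of Selection with Intergenerational Food and Information Transfers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Age-structured inclusive-fitness analysis for social species with
    pooled energy budgets. Given one-year age schedules of survival, fertility,
    caloric production and caloric demand, the package calibrates a
    nutrition-dependent Leslie matrix model (food ratio E, vital-rate scalar
    Z = E(gamma+1)/(E+gamma)) and computes three transfer-based extensions of
    Hamilton's force of selection: indirect fitness contributions of production
    transfers (delta-lambda_Px), fitness elasticities to age-specific production
    (e_Px), and productive value (PV_x), the transfer analogue of Fisher's
    reproductive value. Also provides fertility equivalents of production
    transfers, counterfactual life-history by subsistence permutations, a
    synthetic profile generator for chimpanzee-like and human forager-like
    regimes, and a pedagogy module propagating information transfers to fitness
    through accelerated skill acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
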