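Package: foresthealth
Title: Forest Health Assessment with CRITIC Weighting and Interpretable
    Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plot-level forest health assessment for forest inventory data.
    Computes species diversity indices (Gleason, Menhinick, Shannon-Wiener,
    Pielou) from stem-level survey records, derives objective indicator
    weights by the CRITIC method (CRiteria Importance Through Intercriteria
    Correlation), aggregates twelve structural, compositional and functional
    indicators into a composite forest-health score with four health classes,
    and fits an interpretable CART classification tree from first principles
    to explain the classes.  Includes rank-based (Mann-Whitney) one-vs-rest
    multiclass AUC evaluation, a Gaussian-copula synthetic data generator
    emulating the indicator structure of a tropical rainforest plot network,
    and an end-to-end pipeline driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    rpart,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
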