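Package: ipfpfis
Title: Neuro-Fuzzy Prediction of Infrapatellar Fat Pad Volume from Serum
    Adipokine Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle swarm optimisation (PSO) wrapper variable selection over a
    48-column design of osteoarthritis risk factors, serum adipokine and
    inflammatory-marker concentrations and their 36 pairwise ratios, followed by
    an adaptive neuro-fuzzy inference system with fuzzy c-means rule induction
    (ANFIS-FCM) to predict infrapatellar fat pad (IPFP) volume. Includes a
    seeded synthetic-cohort generator emulating an OAI-like feature table,
    Monte-Carlo selection stability, AIC model-size choice, uncertainty bands
    (SDFE and 95 percent WUB), Taylor-diagram statistics, gender-separation and
    inverse-ratio studies, and an external-validation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
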