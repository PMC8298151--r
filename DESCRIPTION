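Package: pvq
Title: Objective Estimation of Parkinsonian Sustained-Vowel Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Acoustic analysis and regression modelling of perceived voice
    quality in sustained vowels, aimed at Parkinsonian dysphonia. Implements
    native extractors for traditional perturbation measures (percent jitter,
    shimmer in dB, harmonics-to-noise ratio, smoothed cepstral peak
    prominence), Gammatone/ERB filterbank cepstral coefficients, linear
    prediction quality descriptors, modulation-spectrogram metrics (SRMR,
    ModA), and recurrence period density entropy; feature-to-quality mapping
    by multivariate linear regression and support vector regression with
    correlation-ranked Monte Carlo feature selection and PCA reduction; and
    the evaluation statistics used to benchmark such estimators (Pearson
    correlation, standard deviation of prediction error, Steiger's Z for
    dependent correlations, intraclass correlation, paired t-tests, repeated
    random splits). A synthetic-vowel generator with a simulated
    visual-analogue-scale rater panel provides ground-truth data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
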