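Package: restalpha
Title: Resting-State EEG Features and Motor-Imagery BCI Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links resting-state EEG features to motor-imagery
    brain-computer interface (MI-BCI) performance. Computes relative power
    level, power spectral entropy and Lempel-Ziv complexity of eyes-open and
    eyes-closed resting EEG per frequency band and channel; scores each
    subject's MI ability with multiclass common spatial patterns and a
    linear support vector machine under repeated stratified cross-validation;
    runs channel-wise Pearson correlation maps, repeated-measures band
    contrasts and group comparisons; and builds screening classifiers that
    separate high from low MI performers. Includes a fully synthetic EEG
    cohort generator with a plantable cross-subject correlation between
    resting alpha power and MI class separability, plus EDF (PhysioNet
    dialect) input/output, so the whole pipeline is exercisable without any
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
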