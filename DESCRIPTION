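Package: trunkentropy
Title: Sample Entropy Analysis of Repeated Trunk Bending Recorded by a
    Single Inertial Measurement Unit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the complexity of repeated trunk bending-and-return
    movements recorded by a sacrum-mounted inertial measurement unit (IMU).
    Provides an exact Sample Entropy (SampEn) implementation with an
    independent exhaustive-count oracle, angular amplitude estimation by
    gyroscope integration with cycle detection, a windowed
    entropy-convergence procedure that selects the shortest clinically
    feasible test duration, agreement statistics (through-origin regression,
    Bland-Altman limits of agreement, paired condition comparisons), a
    synthetic-recording generator with controllable motor variability for
    ground-truth testing, and an end-to-end cohort pipeline producing
    machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
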