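Package: glucadvisor
Title: Rule-Based and K-Nearest-Neighbor Treatment Advice for Blood Glucose Self-Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A blood glucose monitoring and advisory engine for diabetes
    self-management. Computes daily calorie targets from patient body
    information, recommends one of five treatment actions (more exercise,
    eat more, rest, take insulin, maintain) either from a time-windowed
    threshold rule set or from a k-nearest-neighbor classifier with
    min-max feature normalization, and provides an evaluation harness
    that scores and compares the two recommenders on labeled observation
    records. Includes a seeded synthetic patient-record generator so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, class, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
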