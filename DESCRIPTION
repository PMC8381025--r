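Package: dcmastery
Title: Mastery Classification with CTT Subscores, Per-Strand Rasch, and the DINA Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing three engines that classify examinees as
    masters or non-masters of content strands on a licensing-style
    examination: classical-test-theory percent-correct subscores, a
    unidimensional Rasch model fitted per strand (marginal maximum
    likelihood estimation with maximum a posteriori person scoring), and
    the deterministic-inputs noisy "and"-gate (DINA) latent-class model
    fitted jointly over all items. Includes a simple-structure
    multidimensional item response theory simulator with configurable
    inter-attribute correlation, classification accuracy and consistency
    statistics, outfit and item-level RMSEA fit indices, and
    configuration-driven drivers for the full simulation study and for
    analysing any binary response matrix with a simple-structure Q-matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
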