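Package: equistand
Title: Musculoskeletal Statics of the Standing Equine Hindlimb
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse-statics and static-optimization toolkit for the proximal
    equine hindlimb in square standing. Builds net joint moments at the
    coxofemoral, femorotibial and femoropatellar joints from ground reaction
    and segmental gravity loads, assembles the muscle moment-balance system
    from line-of-action geometry, resolves muscle redundancy by minimizing a
    cubic cost normalized by physiological cross-sectional area under
    physiological force bounds, estimates joint contact forces, and exports
    femoral load cases for downstream finite-element analysis. Includes a
    seeded synthetic-limb generator for testing every pipeline stage, plus
    reporting helpers for muscle-group force sums and implant safety factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
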