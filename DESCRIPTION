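Package: catsys
Title: Finite Category Theory Engine for Auditing (Quasi-)Systematicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs and verifies universal constructions in the category
    of finite sets (products, pullbacks, pushouts, equalizers, coequalizers,
    general limits and colimits, and the diagonal-product adjunction) and uses
    them to realize cognitive domains as executable, auditable relational
    architectures. A relation such as subject-verb agreement or kinship is
    realized as a pullback over a shared constraint; role inference,
    membership testing with diagnostic reasons, quotient construction, a
    block-matrix rendering, and a systematicity audit that detects mixed
    (non-mediated) accessor assignments are provided, together with a JSON
    domain-specification dialect, a fixture catalog of worked examples, a
    seeded random-domain generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
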