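Package: unhs
Title: Coding Machinery for a Universal Nomenclature of Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and auditing a meta-classification of health
    services of the kind used to harmonize hospital billing catalogs in
    low- and middle-income countries. Implements bijective base-35
    identifier encoding with a mod-26 check letter, parsing and validation
    of service codes with dot-suffixed national extensions, a concept
    registry over six international source classifications (ICD-10-PCS,
    CPT, HCPCS, LOINC, RxNorm, UB-04) with operational codes, quantitative
    assessment of multi-facility billing-catalog consistency, coverage
    analysis of local catalogs against a registry, seeded synthetic-fixture
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
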