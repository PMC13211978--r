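Package: brapifed
Title: Federated Breeding API Proxy and Marker-Trait Validation Client
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges several independent Breeding API (BrAPI v2.1) endpoints
    into one standards-compliant federated endpoint. Recomputes list
    pagination across backends so that a single consistent paging scheme
    covers the concatenation of all backend lists, merges two-dimensionally
    paged allele matrices into a block-diagonal genotype matrix, namespaces
    backend-local database identifiers with configurable crop prefixes, and
    routes identifier-filtered requests to the backends that own them.
    Ships an in-process synthetic federation (passport/phenotype backend
    plus per-crop genotype backends with a planted marker-trait effect) for
    fully offline testing, a plain-socket HTTP front end with an OpenAPI
    description, and a client pipeline that validates a marker-trait
    relationship through the federated interface: variant selection near a
    genomic position, allele-matrix retrieval, callset-sample-germplasm-
    observation linkage, rank-sum comparison of per-genotype trait
    distributions, and passport breakdowns of alternate-allele carriers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
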