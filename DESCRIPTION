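Package: caresr
Title: Custodian Administered Research Extract Server at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully testable, desk-scale implementation of a custodian
    administered research extract server for linked administrative health
    data: a central hub of de-identified partial copies of data collections
    keyed by one-way encrypted record identifiers, a governed six-step
    extraction engine joining project linkage keys to service records,
    output standardisation and quality-assurance reporting, parallel-run
    validation against reference extracts, and turnaround-time metrics.
    A synthetic-data generator stands in for the source collections so the
    whole system is exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
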