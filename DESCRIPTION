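Package: wuenicr
Title: Rule-Based Estimation of National Immunization Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic, fully explainable rule engine for producing
    national immunization coverage estimates in the style of the WHO and
    UNICEF joint estimates (WUENIC). Coverage reported by national
    authorities is graded against household survey results and expert
    working-group decisions through four processing levels: data grading
    (exclusion of implausible reports and under-powered surveys, recall-bias
    adjustment), anchor-point resolution at years with multiple data
    sources, time-series completion by interpolation and calibration, and
    cross-vaccine reconciliation of DTP1 against DTP3. Every estimate
    carries a rule code, a generated explanation and provenance, and the
    whole pipeline is reproducible from delimited text inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
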