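Package: melscreen
Title: Microsimulation of Melanoma Natural History, Screening and
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event microsimulation platform for cutaneous
    melanoma. Simulates individual lifetime natural history (first and
    subsequent primary melanomas with histology-specific implicit
    progression), detection through opportunistic clinician visits,
    routine skin checks, organised screening rounds and post-diagnosis
    surveillance, melanoma-specific and other-cause mortality, Bayesian
    (ABC-SMC) calibration against registry-style summary targets, and
    cost-effectiveness, overdiagnosis and budget-impact evaluation of
    risk-tailored screening strategies. Ships a self-consistent
    synthetic Australian-like parameter fixture so the whole platform is
    testable without restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
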