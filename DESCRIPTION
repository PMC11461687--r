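Package: careflow
Title: Care Pathway Mining and Stochastic Resource Scheduling for Outpatient Clinics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines dominant patient care pathways and per-activity service-time
    distributions from real-time location system (RTLS) co-location logs, and
    allocates capacitated heterogeneous clinic resources to patient care
    activities while sequencing them to minimize expected total patient waiting
    time. The scheduling problem is formulated as a two-stage stochastic
    mixed-integer linear program without time or rank indices, solved by sample
    average approximation inside a Monte Carlo optimization loop with
    statistical lower/upper bounds and an approximate optimality index stopping
    rule. Includes a synthetic RTLS log generator, log-normal duration
    modelling, an independent schedule feasibility checker, an exhaustive
    scheduling oracle for validation, value-of-the-stochastic-solution
    reporting against a mean-value baseline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with scipy (>= 1.9) on the PATH as
    'python' (mixed-integer programs are solved through scipy.optimize.milp's
    HiGHS backend)
Config/testthat/edition: 3
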