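Package: promptbench
Title: LLM-Driven Data Analysis Automation and Code Executability Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning plain-text data-analysis requests into executed
    analysis code via large language models: prompt-engineering strategies
    (simple, role prompting, chain of thought), injection of data-file headers
    into prompts, extraction of fenced code from model replies, dependency
    detection and policy-controlled installation, sandboxed execution of the
    generated code in a fresh interpreter process, and an error-feedback
    self-correction loop. Includes a complexity-stratified executability
    benchmark (task suites, trial runner, aggregation) with a statistical
    layer (chi-square tests of independence per complexity level with
    Benjamini-Hochberg correction), a deterministic scripted mock backend so
    everything is testable offline, and synthetic fixture generators for
    tabular omics-style data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    processx,
    stats,
    tools,
    utils,
    yaml
Suggests:
    curl,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
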