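# promptbench

Automating data analysis with large language models, and measuring
whether it works. `promptbench` is an R package for researchers who want
to (a) turn plain-text analysis requests — typically over tabular omics
data such as gene-expression matrices — into executed analysis code via a
chat-completion model, and (b) benchmark, honestly and offline, how often
the generated code actually runs.

The package covers the full round trip:

* **Prompt engineering** — fixed system prompts for three strategies
  (*simple*, role-prompted *actAs*, chain-of-thought *cot*), detection of
  data files mentioned in a task, and injection of each file's first
  lines into the prompt (*fileCont*) so the model sees real column
  layouts.
* **Reply processing** — cleaning of typographic characters, extraction
  of triple-backtick code blocks, and regex-based dependency detection
  with policy-controlled installation (`forbid` / `report_only` /
  `install_allowlisted` / `install_all`).
* **Sandboxed execution** — every code string runs in a fresh interpreter
  process confined to a staged workspace, with captured stdout, warnings,
  errors, produced artifacts, and a wall-clock timeout.
* **Self-correction** (*selfCorrect*) — execution errors are fed back to
  the model with a fixed correction instruction, up to 3 attempts.
* **Benchmarking** — a complexity-stratified task suite (complexity =
  number of task components among file reading, wrangling, visualization,
  ML/statistics, multi-dataset handling), a trial runner over tasks ×
  strategies × cycles, and aggregation into executability fractions.
* **Statistics** — per-complexity chi-square tests of independence on the
  strategies × executability contingency tables, with Benjamini–Hochberg
  correction across complexity levels: for level *c* with table
  *O<sub>ij</sub>*, the statistic is
  Σ (O<sub>ij</sub> − E<sub>ij</sub>)² / E<sub>ij</sub> with
  E<sub>ij</sub> = row<sub>i</sub> · col<sub>j</sub> / n and
  df = (r−1)(c−1); the five p-values form one BH family (m = 5).
* **Deterministic mocks** — scripted and probabilistic mock backends so
  every component, including the full benchmark, runs with no API key and
  no network.

A thin CLI wraps the same functions
(`inst/cli/promptbench <fixtures|bench|stats|ask>`).

## Worked example

Run one request through the self-correction loop against a scripted mock
whose first reply contains broken code and whose second contains a fix:

```r
library(promptbench)

agent <- setup_agent(agent_spec("mock",
                                mock_script = make_mock_script("fail_then_fix")))
bundle <- build_prompt_bundle("Compute the mean of 1, 2, 3.",
                              strategy = "selfCorrect")
ws  <- create_workspace()
res <- self_correct(agent, bundle, ws,
                    self_correct_config(dependency_policy = "report_only"))
res
#> <self_correct_result> success after 2 attempt(s)
res$per_attempt[[1]]$result$error_text
#> [1] "Error: could not find function \"undefined_function_1\""
```

The first attempt failed in the sandbox; the error was embedded verbatim
in a correction prompt, and the second reply's code executed. A small
benchmark over the shipped synthetic suite (here: the four complexity-1
tasks, 5 cycles, probabilistic mock with per-attempt success 0.95 at
complexity 1):

```r
d <- tempfile(); dir.create(d)
stage_task_data(d, seed = 1)
tasks <- read_task_suite(pb_task_suite_path())
agent <- make_benchmark_mock(seed = 2026)
records <- run_trials(tasks[1:4], c("simple", "selfCorrect"), agent,
                      cycles = 5,
                      config = self_correct_config(dependency_policy = "report_only"),
                      data_dir = d)
aggregate_trials(records)
#>      strategy complexity n_trials n_executable fraction_executable
#> 1 selfCorrect          1       20           20                 1.0
#> 2      simple          1       20           18                 0.9
```

18/20 single-shot trials executed (close to the mock's p = 0.95), while
the three-attempt correction loop recovered both failures
(expected rate 1 − 0.05³ ≈ 0.9999). `executability_tests()` then turns
full trial sets into the per-complexity chi-square/BH table, and
`write_executability_tests()` renders it as CSV.

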