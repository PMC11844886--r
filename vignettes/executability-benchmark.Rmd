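---
title: "Measuring the executability of LLM-generated analysis code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the executability of LLM-generated analysis code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptbench)
```

## The problem

Large language models can translate a plain-text request — "read this
expression table, keep the most variable genes, cluster the samples" —
into analysis code. Whether that code actually *runs* is a different
question, and the answer degrades as the request grows more involved.
promptbench packages the whole round trip (prompting, code extraction,
dependency resolution, sandboxed execution, error-feedback correction)
together with a benchmark that quantifies executability across prompting
strategies and task complexity, entirely offline when driven by its
scripted mock backend.

## Task complexity

A task is annotated with the subset of five components it requires:
reading data from file(s), data wrangling, visualization, a machine
learning or statistics application, and handling more than one dataset.
Its complexity is the count of distinct components, so a bare file-read
task scores 1 and a task touching everything scores 5. `score_complexity()`
is deliberately nothing more than that count: the point of the scale is
interpretability across the benchmark, not nuance within a task.

## Prompting strategies

Five regimes are compared, all sharing the same user task text:

* **simple** — a fixed system prompt requesting code for the tasks,
  delivered in one triple-backtick block at the end of the reply.
* **actAs** — role prompting: the system prompt first casts the model as
  an expert bioinformatician and R programmer.
* **cot** — chain of thought: the role prompt plus the instruction to work
  step by step before the final code block.
* **fileCont** — the simple system prompt, with the first lines of every
  data file mentioned in the task appended to the user prompt
  (`build_file_header_addendum()`), so the model sees real column layouts
  instead of guessing them.
* **selfCorrect** — fileCont plus the error-feedback loop
  (`self_correct()`): failed executions send the captured error back with
  a fixed correction instruction, up to `max_attempts` model calls
  (default 3, first attempt included).

The three system prompts and the two instruction templates are fixed
strings; the test suite pins them byte for byte, because the benchmark's
comparisons are meaningless if the prompts drift. `fileCont` stacks on the
*simple* prompt (not on `actAs`/`cot`), and `selfCorrect` stacks on
`fileCont`; that composition mirrors how the strategies were evaluated
against each other.

File headers inject `n_lines = 2` lines per file by default. Each injected
line is clipped at 2,000 characters with a `...` marker: header injection
exists to convey column layout, and an unclipped wide matrix row would
spend the model's context window on data values instead. Filename
detection uses an extension allowlist (`txt`, `tsv`, `csv`, `xls(x)`,
`json`, `bed`, `gff`, `gtf`, `fasta`, `fa`, `fastq`, `vcf`) over maximal
word/dot/hyphen tokens, which keeps sentence punctuation out of filenames
without needing the task author to quote them.

## Execution model

`execute_code()` runs each code string in a brand-new interpreter process
(via `processx`) with a fresh workspace directory as working directory.
Fresh processes are non-negotiable for a benchmark: any state leaking
between cycles would contaminate the executability measurement. Inputs are
*copied* into the workspace, so generated code can only see and modify its
own sandbox; a tripwire test asserts nothing escapes. The R adapter wraps
the code in a small runner that collects warnings via condition handlers
while letting errors abort with a nonzero exit. A run is executable when
it exits cleanly within the timeout; warnings do not fail a run by default
(the feedback template mentions warnings, but the metric is error
occurrence — a `strict_warnings` flag flips this for sensitivity
analyses). Timeouts (default 300 s) are recorded as non-executable and fed
back to the model as "execution exceeded the time limit", giving it a
chance to propose cheaper code. Because the interpreter is non-interactive,
graphics fall back to a file device and plots land in the workspace as
artifacts rather than requiring a display.

Dependency handling is policy-controlled. The permissive mode
(`install_all`) matches the original workflow of installing whatever the
generated code loads, but the shipped default is `install_allowlisted`
with a list of common analysis packages, and the test suite runs under
`report_only`/`forbid`: running model-generated code is already a trust
decision, and silently installing arbitrary packages compounds it. A
dependency-installation *failure* is fed back to the model like any other
error — from the model's perspective an unavailable package and a typo in
a package name deserve the same correction opportunity.

## The self-correction loop

Attempt 1 sends the system and user prompts. Each reply is cleaned
(`clean_response()` normalizes typographic quotes, zero-width characters
and line endings — a superset of harmless fixes, since replies sometimes
arrive with word-processor punctuation), the final fenced block is
extracted (the prompts demand a single block at the end, so `last_block`
is the default policy), dependencies are checked, and the code is run. On
failure the next user turn is the fixed correction instruction embedding
the error verbatim, appended to the *same* transcript: the instruction
says "the previous code above", which presumes the model can still see its
failed attempt. A reply with no fenced code counts as a failed attempt
with a synthesized "no code block found" error rather than aborting — the
loop exists to recover, not to give up on formatting slips. The loop makes
exactly `attempts_used` model calls and stops at the first success.

## The benchmark and its synthetic conditions

`run_trials()` evaluates every task under every strategy for a number of
cycles (the reference layout: 20 tasks — four per complexity level — over
10 cycles, i.e. 40 trials per (strategy, complexity) cell, making every
executability fraction a multiple of 0.025). Records carry the final
reply's character count, the executable flag, attempts used, the decoding
settings, and an optional manual correctness annotation; they are
persisted line by line so a crash loses at most the in-flight trial.
Response length is measured on the final reply only, keeping it a
per-response property comparable across strategies.

Live model runs are supported through the OpenAI-compatible remote
backend (temperature 0 by default, for repeatability), but the shipped
benchmark runs against mocks. The probabilistic mock
(`make_benchmark_mock()`) makes each reply independently clean with a
complexity-dependent per-attempt probability, chosen once as
`p = 0.95, 0.80, 0.60, 0.40, 0.25` for complexity 1..5 — a monotone
decline emulating the empirical pattern that executability drops with
task complexity. Under these conditions the expected executable fraction
is `p` for single-shot strategies and `1 - (1 - p)^3` for the
three-attempt correction loop, and the end-to-end test checks the
observed fractions against those targets within three binomial standard
errors (n = 40 per cell).

What the mock does *not* emulate is worth stating plainly: real models
fail in correlated, prompt-dependent ways; their corrected attempts are
not independent draws; and reply length, style and fence discipline vary.
A green synthetic benchmark therefore validates the *machinery* —
counting, stacking of strategies, loop semantics, aggregation and
statistics — not any claim about a particular model's coding ability.
Those claims require the live mode and a budget.

The synthetic data generators are similarly scoped. Expression tables are
log-normal with a per-gene scale and a 20% subset of genes given inflated
log-scale variance, so "top-k most variable genes" tasks have a
well-defined, heavy-tailed answer even at 60 genes x 8 samples; subject
tables draw categorical columns from fixed label pools. Nothing about
leukemia biology is simulated — the files exist so that file reading,
header injection and wrangling steps operate on realistic *shapes*.

## Statistics

Per complexity level, executability counts across strategies form a
strategies x {executable, not executable} contingency table tested with
Pearson's chi-square test of independence (no continuity correction; the
5 x 2 tables have df = 4, where none applies — a Yates flag exists for
2 x 2 inputs, default off). The five per-level p-values form one
Benjamini-Hochberg family (m = 5); adjusted values get the usual star
labels. The pipeline carries full precision internally and rounds only
for display, at three significant figures with halves away from zero —
rounding raw p-values before adjustment produces off-by-one-ulp artifacts
in the last printed digit, which is exactly the discrepancy the
full-precision rule avoids. The chi-square kernel, the survival function
and the BH step are each cross-checked in the test suite against
independent oracles (a brute-force expected-count loop, the closed-form
even-df series, and a hand-written step-up rule).

## Numerical and design choices, in brief

* Mock replay is a pure function of the turn index; strict scripts error
  past their end, which doubles as a call-budget assertion in tests.
* Remote transport retries three times with exponential backoff before
  surfacing; mock errors never retry. A transport failure during a trial
  is recorded as an infrastructure error and excluded from aggregation —
  an API hiccup is not a property of the task.
* Credentials are referenced by environment-variable or file name and
  resolved only at request time; no object, log or serialized transcript
  ever contains the secret.
* Unlabeled code fences are assumed to be in the configured language
  (default R); a `python` adapter executes labeled Python blocks.
* The test suite (and any offline run) arms a network guard that makes a
  remote send an immediate error, so "no network was touched" is an
  asserted property rather than a hope.

## Problem sizes used in the shipped tests

The end-to-end test runs the full 20-task suite over 10 cycles for the
`simple` and `selfCorrect` strategies (400 trials, ~600 sandboxed
interpreter launches); unit tests use two-task mini-suites and 1-2 cycles.
Oracle equivalence checks use 1,000 random contingency tables and 1,000
random p-value vectors. These sizes keep a full run in the low minutes on
one core while leaving the binomial checks enough resolution to be
meaningful.

## Limitations

Executability is a floor, not a ceiling: code can run and still be wrong,
which is why trial records carry a manual `correctness` annotation field
but no automated judgment. OS-level containment (containers, resource
quotas beyond the wall-clock timeout) is a deployment concern left outside
the package; the workspace sandbox bounds *where* code writes, not *what*
it computes. And the complexity scale is coarse by construction — two
complexity-3 tasks can differ greatly in difficulty; the scale orders
strata, it does not measure tasks.
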