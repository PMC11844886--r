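# Synthetic fixtures: tabular data shaped like the benchmark's gene
# expression / subject tables, scripted mock replies, and the probabilistic
# mock used by the end-to-end benchmark. Everything is reproducible from
# (spec, seed) alone; no fixture requires a network connection.

# Run fn() under a private RNG stream without disturbing the caller's.
with_private_rng <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic gene-expression table
#'
#' Tab-separated text file shaped like a bulk expression matrix: a header
#' row (gene column plus sample identifiers), then one row per gene with a
#' unique gene name followed by non-negative expression values. Values are
#' log-normal with a per-gene scale; a controllable subset of genes gets an
#' inflated log-scale standard deviation so that "most variable genes"
#' tasks are meaningful on tiny data. Identical specs produce byte-identical
#' files.
#'
#' @param out_path Destination file.
#' @param n_genes,n_samples Table dimensions.
#' @param seed RNG seed.
#' @param frac_variable Fraction of genes given inflated variance.
#' @return `out_path`, invisibly.
#' @export
gen_expression_table <- function(out_path, n_genes = 50L, n_samples = 6L,
                                 seed = 1L, frac_variable = 0.2) {
  stopifnot(n_genes >= 1L, n_samples >= 1L)
  with_private_rng(seed, function() {
    genes <- sprintf("gene_%03d", seq_len(n_genes))
    samples <- sprintf("sample_%d", seq_len(n_samples))
    meanlog <- stats::rnorm(n_genes, mean = 4, sd = 1)
    sdlog <- stats::runif(n_genes, 0.1, 0.4)
    n_var <- max(1L, round(frac_variable * n_genes))
    hi <- sample.int(n_genes, n_var)
    sdlog[hi] <- stats::runif(n_var, 1.0, 2.0) # heavy-tailed variance spread
    vals <- matrix(stats::rlnorm(n_genes * n_samples,
                                 meanlog = rep(meanlog, each = n_samples),
                                 sdlog = rep(sdlog, each = n_samples)),
                   nrow = n_genes, byrow = TRUE)
    lines <- c(paste(c("gene", samples), collapse = "\t"),
               vapply(seq_len(n_genes), function(i) {
                 paste(c(genes[i], sprintf("%.3f", vals[i, ])),
                       collapse = "\t")
               }, ""))
    con <- file(out_path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  })
  invisible(out_path)
}

# Fixed label pools for categorical subject columns.
.pb_label_pools <- list(
  sex = c("female", "male"),
  group = c("control", "treated"),
  status = c("healthy", "disease"),
  default = c("A", "B", "C")
)

#' Generate a synthetic subjects table
#'
#' Tab-separated file with a header and `n_rows` data rows. Column kinds
#' are `"categorical"` (drawn from a fixed label pool keyed by the column
#' name) or `"numeric"`. Deterministic under a fixed seed.
#'
#' @param out_path Destination file.
#' @param n_rows Number of data rows (>= 1).
#' @param columns Named character vector mapping column name to kind, e.g.
#'   `c(age = "numeric", sex = "categorical")`.
#' @param seed RNG seed.
#' @return `out_path`, invisibly.
#' @export
gen_subjects_table <- function(out_path, n_rows = 10L,
                               columns = c(subject = "categorical",
                                           age = "numeric",
                                           sex = "categorical",
                                           group = "categorical"),
                               seed = 1L) {
  if (n_rows < 1L) stop("n_rows must be at least 1", call. = FALSE)
  if (length(columns) == 0L) stop("columns must be non-empty", call. = FALSE)
  with_private_rng(seed, function() {
    cols <- lapply(names(columns), function(nm) {
      kind <- columns[[nm]]
      if (kind == "numeric") {
        sprintf("%.1f", stats::rnorm(n_rows, mean = 50, sd = 12))
      } else if (kind == "categorical") {
        if (nm == "subject") {
          sprintf("subj_%02d", seq_len(n_rows))
        } else {
          pool <- .pb_label_pools[[nm]] %||% .pb_label_pools$default
          sample(pool, n_rows, replace = TRUE)
        }
      } else {
        stop("unknown column kind: ", kind, call. = FALSE)
      }
    })
    lines <- c(paste(names(columns), collapse = "\t"),
               vapply(seq_len(n_rows), function(i) {
                 paste(vapply(cols, `[[`, "", i), collapse = "\t")
               }, ""))
    con <- file(out_path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  })
  invisible(out_path)
}

#' Canonical mock reply snippets
#'
#' Building blocks for scripted mocks: `pb_reply_clean()` is a reply whose
#' fenced code executes; `pb_reply_broken(i)` calls the undefined function
#' `undefined_function_<i>` so the sandbox reports a recognizable,
#' per-attempt error (useful for checking that correction turns embed the
#' right error verbatim).
#'
#' @param language Language of the fenced snippet (`"r"` or `"python"`).
#' @param i Attempt number baked into the undefined name.
#' @return A reply string containing one fenced code block.
#' @export
pb_reply_clean <- function(language = "r") {
  if (language == "python") {
    "Here is the code.\n\n```python\nx = [1, 2, 3]\nprint(sum(x) / len(x))\n```"
  } else {
    "Here is the code.\n\n```r\nx <- c(1, 2, 3)\ncat(\"mean:\", mean(x), \"\\n\")\n```"
  }
}

#' @rdname pb_reply_clean
#' @export
pb_reply_broken <- function(i = 1L, language = "r") {
  fn <- sprintf("undefined_function_%d", i)
  if (language == "python") {
    sprintf("Let me try.\n\n```python\n%s(1)\n```", fn)
  } else {
    sprintf("Let me try.\n\n```r\n%s(1)\n```", fn)
  }
}

#' Build a scripted mock for a canned model behavior
#'
#' The four behaviors the self-correction loop must handle: `clean` (first
#' reply's code runs), `fail_then_fix` (first reply errors, second runs),
#' `always_fail` (every reply errors, each with a distinct undefined name),
#' and `no_code` (prose without any fence, then a clean fix).
#'
#' @param kind One of `"clean"`, `"fail_then_fix"`, `"always_fail"`,
#'   `"no_code"`.
#' @param language Language tag of the fenced snippets.
#' @param n_replies Script length for `always_fail`.
#' @return A [mock_script()].
#' @export
make_mock_script <- function(kind = c("clean", "fail_then_fix",
                                      "always_fail", "no_code"),
                             language = "r", n_replies = 3L) {
  kind <- match.arg(kind)
  replies <- switch(kind,
    clean = pb_reply_clean(language),
    fail_then_fix = c(pb_reply_broken(1L, language),
                      pb_reply_clean(language)),
    always_fail = vapply(seq_len(n_replies), pb_reply_broken, "",
                         language = language),
    no_code = c("I would first inspect the file, then decide on a method.",
                pb_reply_clean(language)))
  mock_script(replies, replay_policy = "strict")
}

#' Probabilistic mock factory for the end-to-end benchmark
#'
#' Returns a `function(task, strategy, cycle)` suitable as the `agent`
#' argument of [run_trials()]. Each call produces a fresh mock whose
#' replies are independently clean with a probability that depends on the
#' task's complexity — emulating the empirical pattern that executability
#' declines as complexity grows. Under the self-correction loop the success
#' probability over `max_attempts` independent attempts is
#' `1 - (1 - p)^max_attempts`; under single-shot strategies it is `p`.
#' Outcomes are drawn from a private RNG stream seeded once, so a factory
#' replayed over the same trial sequence reproduces the same scripts.
#'
#' @param p_by_complexity Numeric vector of per-attempt success
#'   probabilities indexed by complexity 1..5.
#' @param max_attempts Replies per script (covers the correction loop).
#' @param seed Seed of the factory's private RNG stream.
#' @param model Model name recorded on the trial records.
#' @return A factory function.
#' @export
make_benchmark_mock <- function(p_by_complexity = c(0.95, 0.80, 0.60,
                                                    0.40, 0.25),
                                max_attempts = 3L, seed = 1L,
                                model = "mock-benchmark") {
  stopifnot(length(p_by_complexity) >= 5L,
            all(p_by_complexity >= 0 & p_by_complexity <= 1))
  rng <- new.env(parent = emptyenv())
  rng$state <- with_private_rng(seed, function() {
    stats::runif(1) # burn one draw to materialize the stream
    get(".Random.seed", envir = globalenv())
  })
  function(task, strategy, cycle) {
    p <- p_by_complexity[[task$complexity]]
    has_seed <- exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", rng$state, envir = globalenv())
    ok <- stats::runif(max_attempts) < p
    rng$state <- get(".Random.seed", envir = globalenv())
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    replies <- ifelse(ok, pb_reply_clean(),
                      vapply(seq_len(max_attempts), pb_reply_broken, ""))
    setup_agent(agent_spec("mock", model = model,
                           mock_script = mock_script(replies)))
  }
}

#' Locate the shipped synthetic task suite
#'
#' Twenty synthetic benchmark tasks, four per complexity level 1..5,
#' referencing the synthetic data files that [stage_task_data()] generates.
#'
#' @return Path of the task-suite YAML inside the installed package.
#' @export
pb_task_suite_path <- function() {
  system.file("extdata", "task_suite_synthetic.yaml",
              package = "promptbench", mustWork = TRUE)
}

#' Materialize the data files the shipped suite references
#'
#' Generates every synthetic data file mentioned by the shipped task suite
#' into `data_dir`, deterministically from `seed`.
#'
#' @param data_dir Destination directory (created if missing).
#' @param seed Base RNG seed.
#' @return `data_dir`, invisibly.
#' @export
stage_task_data <- function(data_dir, seed = 1L) {
  if (!dir.exists(data_dir)) dir.create(data_dir, recursive = TRUE)
  gen_subjects_table(file.path(data_dir, "subjects.txt"),
                     n_rows = 12L, seed = seed)
  gen_expression_table(file.path(data_dir, "leukemiaExp.txt"),
                       n_genes = 60L, n_samples = 8L, seed = seed + 1L)
  gen_expression_table(file.path(data_dir, "proteinExp.txt"),
                       n_genes = 40L, n_samples = 8L, seed = seed + 2L)
  gen_subjects_table(file.path(data_dir, "metadata.txt"),
                     n_rows = 8L,
                     columns = c(subject = "categorical",
                                 status = "categorical",
                                 age = "numeric"),
                     seed = seed + 3L)
  invisible(data_dir)
}
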