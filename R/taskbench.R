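#' Task components
#'
#' The five building blocks a benchmark task can require. A task's
#' complexity is the number of distinct components it carries: a task that
#' only reads a file has complexity 1; one that reads, wrangles,
#' visualizes, applies machine learning/statistics and juggles more than
#' one dataset has complexity 5.
#' @export
pb_components <- c("read_file", "wrangle", "visualize", "ml_stats",
                   "multi_dataset")

#' Component-counting complexity score
#'
#' @param components Non-empty subset of [pb_components].
#' @return Integer complexity in 1..5.
#' @export
score_complexity <- function(components) {
  if (length(components) == 0L) {
    stop("a task must have at least one component", call. = FALSE)
  }
  unknown <- setdiff(components, pb_components)
  if (length(unknown)) {
    stop("unrecognized task component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  length(unique(components))
}

#' Define one benchmark task
#'
#' @param id Short identifier.
#' @param prompt_text The plain-text task description sent to the model.
#'   Every file in `data_files` must be mentioned in it.
#' @param data_files Files the task references (staged into the workspace
#'   and available for header injection).
#' @param components Subset of [pb_components]; the task's complexity is
#'   their count.
#' @return An object of class `task_spec` with a derived `complexity`
#'   field.
#' @export
task_spec <- function(id, prompt_text, data_files = character(),
                      components) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(prompt_text), length(prompt_text) == 1L)
  complexity <- score_complexity(components)
  for (fn in data_files) {
    if (!grepl(fn, prompt_text, fixed = TRUE)) {
      stop("task ", id, ": data file '", fn,
           "' is not mentioned in the prompt text", call. = FALSE)
    }
  }
  structure(list(id = id, prompt_text = prompt_text,
                 data_files = as.character(data_files),
                 components = unique(components),
                 complexity = complexity),
            class = "task_spec")
}

#' Read / write a task suite
#'
#' A suite is a YAML file with one document per task (`id`, `prompt`,
#' `files`, `components`); complexity is always re-derived from the
#' component set on read.
#'
#' @param path YAML file path.
#' @return `read_task_suite()` returns a list of [task_spec()] objects.
#' @export
read_task_suite <- function(path) {
  docs <- yaml::read_yaml(path)
  lapply(docs, function(d) {
    task_spec(id = d$id, prompt_text = d$prompt,
              data_files = unlist(d$files) %||% character(),
              components = unlist(d$components))
  })
}

#' @rdname read_task_suite
#' @param tasks List of [task_spec()] objects.
#' @export
write_task_suite <- function(tasks, path) {
  docs <- lapply(tasks, function(t) {
    list(id = t$id, prompt = t$prompt_text,
         files = as.list(t$data_files),
         components = as.list(t$components))
  })
  yaml::write_yaml(docs, path)
  invisible(path)
}

pb_record_fields <- c("task_id", "complexity", "strategy", "model", "cycle",
                      "response_chars", "executable", "attempts_used",
                      "correctness", "temperature", "max_reply_tokens",
                      "infra_error")

pb_make_record <- function(task, strategy, model, cycle, reply, success,
                           attempts_used, spec, infra_error = FALSE) {
  data.frame(
    task_id = task$id, complexity = task$complexity, strategy = strategy,
    model = model, cycle = as.integer(cycle),
    response_chars = if (is.null(reply)) 0L else nchar(reply),
    executable = success, attempts_used = as.integer(attempts_used),
    correctness = "unassessed",
    temperature = if (identical(spec$temperature, "provider-default"))
      NA_real_ else as.numeric(spec$temperature),
    max_reply_tokens = if (is.null(spec$max_reply_tokens)) NA_integer_
      else as.integer(spec$max_reply_tokens),
    infra_error = infra_error,
    stringsAsFactors = FALSE)
}

#' Run the benchmark trials
#'
#' Evaluates every task under every strategy for the requested number of
#' cycles, producing exactly `tasks x strategies x cycles` trial records.
#' The `simple`, `actAs` and `cot` strategies make a single model call and
#' one sandboxed execution; `fileCont` additionally injects data-file
#' headers (on the simple system prompt); `selfCorrect` stacks the
#' error-feedback loop on top of `fileCont`. Records can be persisted
#' incrementally so a crash loses at most the in-flight trial. An agent
#' transport failure marks the affected trial `infra_error = TRUE`
#' (excluded from aggregation) rather than counting as a task failure.
#'
#' @param tasks List of [task_spec()] objects.
#' @param strategies Subset of [pb_strategies].
#' @param agent Either an `agent_handle` used for every trial, or a factory
#'   `function(task, strategy, cycle)` returning a fresh handle per trial
#'   (the natural shape for scripted mocks).
#' @param cycles Number of repetitions per (task, strategy).
#' @param config A [self_correct_config()]; its execution settings apply to
#'   every strategy, its `max_attempts` only to `selfCorrect`.
#' @param data_dir Directory holding the tasks' data files.
#' @param records_path Optional JSONL file; each finished record is
#'   appended immediately.
#' @param language Generated-code language for the system prompts.
#' @return Data frame of trial records (one row per trial).
#' @export
run_trials <- function(tasks, strategies, agent, cycles,
                       config = self_correct_config(),
                       data_dir = NULL, records_path = NULL,
                       language = "R") {
  stopifnot(is.numeric(cycles), length(cycles) == 1L)
  if (cycles < 1) stop("cycles must be a positive integer", call. = FALSE)
  cycles <- as.integer(cycles)
  bad <- setdiff(strategies, pb_strategies)
  if (length(bad)) {
    stop("unknown strategies: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  get_agent <- if (is.function(agent)) agent else function(...) agent
  records <- vector("list", length(tasks) * length(strategies) * cycles)
  k <- 0L
  for (strategy in strategies) {
    for (task in tasks) {
      for (cycle in seq_len(cycles)) {
        k <- k + 1L
        handle <- get_agent(task, strategy, cycle)
        spec <- handle$spec
        ws <- create_workspace(inputs = task$data_files,
                               from_dir = data_dir)
        rec <- tryCatch({
          if (strategy == "selfCorrect") {
            bundle <- build_prompt_bundle(
              task$prompt_text, strategy = "selfCorrect",
              data_dir = data_dir,
              include_file_headers = config$include_file_headers,
              language = language)
            res <- self_correct(handle, bundle, ws, config)
            final_reply <- res$per_attempt[[res$attempts_used]]$reply
            pb_make_record(task, strategy, spec$model, cycle, final_reply,
                           res$success, res$attempts_used, spec)
          } else {
            bundle <- build_prompt_bundle(
              task$prompt_text, strategy = strategy, data_dir = data_dir,
              language = language)
            transcript <- chat_transcript(list(
              chat_message("system", bundle$system_text),
              chat_message("user", bundle$user_text)))
            reply <- send_chat(handle, transcript)
            att <- pb_run_attempt(reply, ws, config)
            pb_make_record(task, strategy, spec$model, cycle, reply,
                           identical(att$result$status, "success"), 1L,
                           spec)
          }
        }, pb_transport_error = function(e) {
          pb_make_record(task, strategy, spec$model, cycle, NULL, NA,
                         length(e$partial$per_attempt), spec,
                         infra_error = TRUE)
        }, error = function(e) {
          if (grepl("transport", conditionMessage(e))) {
            pb_make_record(task, strategy, spec$model, cycle, NULL, NA, 0L,
                           spec, infra_error = TRUE)
          } else {
            stop(e)
          }
        })
        cleanup_workspace(ws)
        records[[k]] <- rec
        if (!is.null(records_path)) {
          cat(jsonlite::toJSON(as.list(rec[1L, ]), auto_unbox = TRUE,
                               na = "null"),
              "\n", sep = "", file = records_path, append = TRUE)
        }
      }
    }
  }
  do.call(rbind, records)
}

#' Read trial records from a JSONL file
#'
#' @param path Line-delimited JSON file written by [run_trials()].
#' @return Data frame of trial records.
#' @export
read_trial_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    x$executable <- if (is.null(x$executable)) NA else x$executable
    x$max_reply_tokens <- if (is.null(x$max_reply_tokens)) NA_integer_
      else x$max_reply_tokens
    x$temperature <- if (is.null(x$temperature)) NA_real_ else x$temperature
    as.data.frame(x[pb_record_fields], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate trials into executability fractions
#'
#' One cell per (strategy, complexity) stratum present in the records:
#' trial and executable counts, the executable fraction, and mean response
#' length split by the executable flag. Infrastructure-errored trials are
#' excluded from the counts.
#'
#' @param records Data frame from [run_trials()] or [read_trial_records()].
#' @return Data frame with one row per stratum.
#' @export
aggregate_trials <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  ok <- records[!isTRUE_vec(records$infra_error), , drop = FALSE]
  strata <- unique(ok[, c("strategy", "complexity")])
  strata <- strata[order(strata$strategy, strata$complexity), , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sub <- ok[ok$strategy == strata$strategy[i] &
              ok$complexity == strata$complexity[i], , drop = FALSE]
    exe <- sub$response_chars[sub$executable %in% TRUE]
    nxe <- sub$response_chars[sub$executable %in% FALSE]
    data.frame(
      strategy = strata$strategy[i], complexity = strata$complexity[i],
      n_trials = nrow(sub), n_executable = sum(sub$executable %in% TRUE),
      fraction_executable = sum(sub$executable %in% TRUE) / nrow(sub),
      mean_chars_executable = if (length(exe)) mean(exe) else NA_real_,
      mean_chars_not_executable = if (length(nxe)) mean(nxe) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

isTRUE_vec <- function(x) !is.na(x) & x
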