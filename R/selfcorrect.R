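#' Configuration for the self-correction loop
#'
#' @param max_attempts Maximum number of model calls, the first attempt
#'   included (default 3).
#' @param include_file_headers Inject data-file headers into the initial
#'   prompt when building bundles (default on).
#' @param extraction_policy Passed to [extract_code()].
#' @param timeout_seconds,strict_warnings Passed to [execute_code()].
#' @param dependency_policy,allowlist Passed to [ensure_dependencies()].
#' @param backend Executor id for unlabeled fences.
#' @param transcript_log Optional path: when set, the session transcript is
#'   appended there as line-delimited JSON.
#' @return An object of class `self_correct_config`.
#' @export
self_correct_config <- function(max_attempts = 3L,
                                include_file_headers = TRUE,
                                extraction_policy = "last_block",
                                timeout_seconds = 300,
                                strict_warnings = FALSE,
                                dependency_policy = "install_allowlisted",
                                allowlist = pb_default_allowlist,
                                backend = "r",
                                transcript_log = NULL) {
  stopifnot(is.numeric(max_attempts), length(max_attempts) == 1L,
            max_attempts >= 1)
  structure(list(max_attempts = as.integer(max_attempts),
                 include_file_headers = isTRUE(include_file_headers),
                 extraction_policy = extraction_policy,
                 timeout_seconds = timeout_seconds,
                 strict_warnings = strict_warnings,
                 dependency_policy = dependency_policy,
                 allowlist = allowlist,
                 backend = backend,
                 transcript_log = transcript_log),
            class = "self_correct_config")
}

# One attempt: clean the reply, extract code, resolve dependencies, run.
# Returns list(code_block, result). A reply without any fenced code counts
# as a failed attempt with a synthesized error so the loop can recover.
pb_run_attempt <- function(reply, workspace, config) {
  cleaned <- clean_response(reply)
  block <- extract_code(cleaned, policy = config$extraction_policy)
  if (block$is_empty) {
    result <- structure(list(status = "error",
                             error_text = "no code block found",
                             warning_texts = character(),
                             stdout_text = "", artifacts = character(),
                             elapsed_seconds = 0),
                        class = "execution_result")
    return(list(code_block = block, result = result))
  }
  deps <- extract_dependencies(block$code, block$fence_label,
                               default_language = config$backend)
  dep_report <- ensure_dependencies(deps, policy = config$dependency_policy,
                                    allowlist = config$allowlist)
  failed <- dep_report$name[dep_report$status == "failed"]
  if (length(failed)) {
    result <- structure(list(
      status = "error",
      error_text = paste("failed to install required packages:",
                         paste(failed, collapse = ", ")),
      warning_texts = character(), stdout_text = "",
      artifacts = character(), elapsed_seconds = 0),
      class = "execution_result")
    return(list(code_block = block, result = result,
                dependency_report = dep_report))
  }
  lang <- normalize_language(block$fence_label, config$backend)
  if (is.null(pb_backends()[[lang]])) lang <- config$backend
  result <- execute_code(block$code, workspace, backend = lang,
                         timeout_seconds = config$timeout_seconds,
                         strict_warnings = config$strict_warnings)
  list(code_block = block, result = result, dependency_report = dep_report)
}

#' Error-feedback self-correction loop
#'
#' Sends the prompt bundle, executes the extracted code, and — while the
#' execution fails and attempts remain — feeds the captured error text back
#' to the model with the fixed correction instruction. The failed assistant
#' replies stay in the transcript so the model can see its own prior code.
#' The loop stops at the first success or after `max_attempts` model calls;
#' exactly `attempts_used` calls are made.
#'
#' @param agent An `agent_handle`.
#' @param bundle A [build_prompt_bundle()] result.
#' @param workspace A [create_workspace()] with the task data staged.
#' @param config A [self_correct_config()].
#' @return An object of class `self_correct_result`: `success`,
#'   `attempts_used`, `per_attempt` (list of `reply`/`code_block`/`result`),
#'   `final_code`, `transcript`.
#' @export
self_correct <- function(agent, bundle, workspace,
                         config = self_correct_config()) {
  stopifnot(inherits(bundle, "prompt_bundle"))
  transcript <- chat_transcript(list(
    chat_message("system", bundle$system_text),
    chat_message("user", bundle$user_text)))
  per_attempt <- list()
  success <- FALSE
  final_code <- ""
  for (attempt in seq_len(config$max_attempts)) {
    reply <- tryCatch(send_chat(agent, transcript), error = function(e) e)
    if (inherits(reply, "error")) {
      partial <- structure(list(success = FALSE,
                                attempts_used = length(per_attempt),
                                per_attempt = per_attempt,
                                final_code = final_code,
                                transcript = transcript),
                           class = "self_correct_result")
      cond <- structure(
        class = c("pb_transport_error", "error", "condition"),
        list(message = paste("agent transport failure:",
                             conditionMessage(reply)),
             call = sys.call(-1), partial = partial))
      stop(cond)
    }
    transcript <- transcript_append(transcript, "assistant", reply)
    att <- pb_run_attempt(reply, workspace, config)
    att$reply <- reply
    per_attempt[[attempt]] <- att
    final_code <- att$code_block$code
    if (identical(att$result$status, "success")) {
      success <- TRUE
      break
    }
    if (attempt < config$max_attempts) {
      transcript <- transcript_append(
        transcript, "user", build_correction_prompt(att$result$error_text))
    }
  }
  if (!is.null(config$transcript_log)) {
    record_transcript(transcript, config$transcript_log,
                      session_id = format(Sys.time(), "%Y%m%d%H%M%OS3"))
  }
  structure(list(success = success, attempts_used = length(per_attempt),
                 per_attempt = per_attempt, final_code = final_code,
                 transcript = transcript),
            class = "self_correct_result")
}

#' @export
print.self_correct_result <- function(x, ...) {
  cat("<self_correct_result>",
      if (x$success) "success" else "failure",
      "after", x$attempts_used, "attempt(s)\n")
  invisible(x)
}
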