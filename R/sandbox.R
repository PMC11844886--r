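#' Create an execution workspace
#'
#' A workspace is a fresh directory that becomes the working directory of
#' every execution staged into it. Input files are copied in (never
#' linked), so generated code can only see and touch the workspace root.
#'
#' @param dir Workspace root; created if missing. Defaults to a fresh
#'   temporary directory.
#' @param inputs Character vector of file names to stage.
#' @param from_dir Directory the inputs are copied from.
#' @param retain Keep the workspace after [cleanup_workspace()]?
#' @return An object of class `pb_workspace`.
#' @export
create_workspace <- function(dir = tempfile("pbws_"), inputs = character(),
                             from_dir = NULL, retain = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  staged <- character()
  for (fn in inputs) {
    src <- if (is.null(from_dir)) fn else file.path(from_dir, fn)
    if (!file.exists(src)) {
      stop("cannot stage input, file not found: ", src, call. = FALSE)
    }
    ok <- file.copy(src, file.path(dir, basename(fn)), overwrite = TRUE)
    if (!ok) stop("failed to stage input: ", src, call. = FALSE)
    staged <- c(staged, basename(fn))
  }
  structure(list(root = normalizePath(dir), staged_inputs = staged,
                 retain = retain),
            class = "pb_workspace")
}

#' @rdname create_workspace
#' @param workspace A `pb_workspace`.
#' @export
cleanup_workspace <- function(workspace) {
  stopifnot(inherits(workspace, "pb_workspace"))
  if (!workspace$retain) unlink(workspace$root, recursive = TRUE)
  invisible(NULL)
}

# Executor backends, keyed by normalized fence label. Each adapter stages a
# code file plus (for R) a runner that separates warnings from errors, and
# says how to invoke a fresh interpreter process.
pb_backends <- function() {
  list(
    r = list(cmd = "Rscript", code_file = ".pb_code.R",
             args = c("--vanilla", ".pb_runner.R"), runner = TRUE),
    python = list(cmd = "python", code_file = ".pb_code.py",
                  args = c(".pb_code.py"), runner = FALSE)
  )
}

.pb_harness_files <- c(".pb_code.R", ".pb_code.py", ".pb_runner.R",
                       ".pb_warnings")

# R runner: sources the code in a clean environment, collecting warnings
# without aborting; an error is reported on stderr and via exit status 1.
# Non-interactive R already routes plots to a file device (Rplots.pdf in
# the working directory), so graphics land in the workspace as artifacts.
pb_r_runner <- function() {
  c(
    '.pb_warnings <- character()',
    '.pb_res <- withCallingHandlers(',
    '  tryCatch({',
    '    source(".pb_code.R", local = new.env(parent = globalenv()),',
    '           echo = FALSE, print.eval = TRUE)',
    '    NULL',
    '  }, error = function(e) e),',
    '  warning = function(w) {',
    '    .pb_warnings <<- c(.pb_warnings, conditionMessage(w))',
    '    tryCatch(invokeRestart("muffleWarning"), error = function(e) NULL)',
    '  })',
    'try(writeLines(.pb_warnings, ".pb_warnings"), silent = TRUE)',
    'if (!is.null(.pb_res)) {',
    '  cat("Error: ", conditionMessage(.pb_res), "\\n", sep = "",',
    '      file = stderr())',
    '  quit(save = "no", status = 1L)',
    '}',
    'quit(save = "no", status = 0L)'
  )
}

#' Execute one code string in a fresh interpreter process
#'
#' The code is written into the workspace and run in a brand-new interpreter
#' with the workspace root as working directory. Nothing is shared between
#' executions. An uncaught error (nonzero exit) yields status `"error"` with
#' the error stream captured; exceeding the timeout terminates the process
#' tree and yields status `"timeout"`. Files newly present under the root
#' afterwards are reported as artifacts. Warnings are captured separately
#' and by default do not make a run non-executable; set `strict_warnings`
#' to treat any warning as a failure.
#'
#' @param code Code text.
#' @param workspace A [create_workspace()] result.
#' @param backend Executor id (normalized fence label): `"r"` or
#'   `"python"`.
#' @param timeout_seconds Wall-clock limit.
#' @param strict_warnings Treat warnings as errors?
#' @return An object of class `execution_result`: `status`
#'   (`success`/`error`/`timeout`), `error_text`, `warning_texts`,
#'   `stdout_text`, `artifacts`, `elapsed_seconds`.
#' @export
execute_code <- function(code, workspace, backend = "r",
                         timeout_seconds = 300, strict_warnings = FALSE) {
  stopifnot(inherits(workspace, "pb_workspace"))
  stopifnot(is.numeric(timeout_seconds), timeout_seconds > 0)
  backend <- normalize_language(backend)
  adapters <- pb_backends()
  ad <- adapters[[backend]]
  if (is.null(ad)) {
    stop("no executor backend for language: ", backend, call. = FALSE)
  }
  if (!nzchar(Sys.which(ad$cmd))) {
    stop("executor backend unavailable: ", ad$cmd, " not on PATH",
         call. = FALSE)
  }
  root <- workspace$root
  before <- list.files(root, recursive = TRUE, all.files = TRUE,
                       no.. = TRUE)
  writeLines(code, file.path(root, ad$code_file))
  if (isTRUE(ad$runner)) {
    writeLines(pb_r_runner(), file.path(root, ".pb_runner.R"))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- processx::run(ad$cmd, ad$args, wd = root,
                       timeout = timeout_seconds,
                       error_on_status = FALSE, cleanup_tree = TRUE)
  elapsed <- proc.time()[["elapsed"]] - t0
  warning_texts <- character()
  wfile <- file.path(root, ".pb_warnings")
  if (file.exists(wfile)) {
    warning_texts <- readLines(wfile, warn = FALSE)
    warning_texts <- warning_texts[nzchar(warning_texts)]
  }
  after <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  artifacts <- setdiff(setdiff(after, before), .pb_harness_files)
  if (isTRUE(res$timeout)) {
    status <- "timeout"
    error_text <- "execution exceeded the time limit"
  } else if (res$status != 0L) {
    status <- "error"
    error_text <- trimws(res$stderr)
    if (!nzchar(error_text)) {
      error_text <- paste("execution failed with exit status", res$status)
    }
  } else if (strict_warnings && length(warning_texts)) {
    status <- "error"
    error_text <- paste(warning_texts, collapse = "\n")
  } else {
    status <- "success"
    error_text <- ""
  }
  structure(list(status = status, error_text = error_text,
                 warning_texts = warning_texts,
                 stdout_text = res$stdout %||% "",
                 artifacts = artifacts,
                 elapsed_seconds = as.numeric(elapsed)),
            class = "execution_result")
}

#' @export
print.execution_result <- function(x, ...) {
  cat("<execution_result>", x$status,
      sprintf("(%.2fs)", x$elapsed_seconds), "\n")
  if (nzchar(x$error_text)) cat("  error:", x$error_text, "\n")
  if (length(x$artifacts)) cat("  artifacts:",
                               paste(x$artifacts, collapse = ", "), "\n")
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a session report
#'
#' Writes a standalone HTML document with, per round: the user prompt, the
#' full model reply, the extracted code in a preformatted block, the
#' execution status with any error/warning text, and links to produced
#' artifacts. An empty session yields a valid report carrying an explicit
#' "no rounds" notice.
#'
#' @param session A list of rounds; each round is a list with elements
#'   `prompt`, `reply`, `code_block` (a `code_block`) and `result` (an
#'   `execution_result`).
#' @param path Destination HTML file.
#' @param title Report title.
#' @return `path`, invisibly.
#' @export
render_html_report <- function(session, path, title = "Analysis session") {
  parts <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             sprintf("<title>%s</title>", html_escape(title)),
             "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}",
             "pre{background:#f4f4f4;padding:1em;overflow-x:auto}",
             ".err{color:#a00}.ok{color:#070}</style></head><body>",
             sprintf("<h1>%s</h1>", html_escape(title)))
  if (length(session) == 0L) {
    parts <- c(parts, "<p><em>No rounds in this session.</em></p>")
  }
  for (i in seq_along(session)) {
    rd <- session[[i]]
    parts <- c(parts, sprintf("<h2>Round %d</h2>", i),
               "<h3>Prompt</h3>",
               sprintf("<pre>%s</pre>", html_escape(rd$prompt)),
               "<h3>Reply</h3>",
               sprintf("<pre>%s</pre>", html_escape(rd$reply)),
               "<h3>Code</h3>",
               sprintf("<pre><code>%s</code></pre>",
                       html_escape(rd$code_block$code %||% "")))
    res <- rd$result
    cls <- if (identical(res$status, "success")) "ok" else "err"
    parts <- c(parts,
               sprintf("<p>Status: <strong class='%s'>%s</strong> (%.2f s)</p>",
                       cls, res$status, res$elapsed_seconds))
    if (nzchar(res$error_text)) {
      parts <- c(parts, sprintf("<pre class='err'>%s</pre>",
                                html_escape(res$error_text)))
    }
    if (length(res$warning_texts)) {
      parts <- c(parts, "<p>Warnings:</p>",
                 sprintf("<pre>%s</pre>",
                         html_escape(paste(res$warning_texts,
                                           collapse = "\n"))))
    }
    if (length(res$artifacts)) {
      links <- sprintf("<li><a href='%s'>%s</a></li>",
                       res$artifacts, html_escape(res$artifacts))
      parts <- c(parts, "<p>Artifacts:</p>",
                 "<ul>", links, "</ul>")
    }
  }
  parts <- c(parts, "</body></html>")
  con <- tryCatch(suppressWarnings(file(path, open = "w",
                                        encoding = "UTF-8")),
                  error = function(e) {
                    stop("cannot write report to ", path, call. = FALSE)
                  })
  on.exit(close(con))
  writeLines(parts, con)
  invisible(path)
}
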