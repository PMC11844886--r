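# System-prompt templates for the three prompting strategies. The default
# generated-code language is R; build_system_prompt() substitutes another
# language name at the template's single language mention.

.pb_templates <- list(
  simple = paste0(
    "Provide R code for the following tasks. ",
    "Provide the code in triple backticks (``` and ```). ",
    "Provide the code as a single block at the end of your response. ",
    "Do not provide code output."),
  actAs = paste0(
    "Act as an expert bioinformatician and R programmer. ",
    "You also have a lot of knowledge about biology. ",
    "Complete the following tasks, using your expertise and always provide ",
    "relevant code. ",
    "When providing the code in triple backticks (``` and ```). ",
    "Provide the code as a single block at the end of your response."),
  cot = paste0(
    "Act as an expert bioinformatician and R programmer. ",
    "You also have a lot of knowledge about biology. ",
    "Answer questions using your expertise and always provide code. ",
    "When providing code, provide the code in triple backticks ",
    "(``` and ```). ",
    "Provide the code as a single block at the end of your response. ",
    "Let's work this out in a step by step way to be sure we have the ",
    "right answer.")
)

#' Prompting strategies
#'
#' The five strategy names understood by the benchmark. `simple`, `actAs`
#' and `cot` differ only in their system prompt; `fileCont` is the simple
#' system prompt plus a file-header addendum on the user prompt; and
#' `selfCorrect` is `fileCont` plus the error-feedback loop.
#' @export
pb_strategies <- c("simple", "actAs", "cot", "fileCont", "selfCorrect")

#' Build the system prompt for a strategy
#'
#' Returns the fixed template for the given strategy. For a language other
#' than `"R"`, the language name is substituted at its single occurrence in
#' the template ("R code" for `simple`, "R programmer" for the role-prompted
#' strategies).
#'
#' @param strategy One of `"simple"`, `"actAs"`, `"cot"`. `"fileCont"` and
#'   `"selfCorrect"` reuse the simple template.
#' @param language Name of the language the model should generate.
#' @return Length-one character vector.
#' @export
build_system_prompt <- function(strategy, language = "R") {
  stopifnot(is.character(strategy), length(strategy) == 1L)
  stopifnot(is.character(language), length(language) == 1L, nzchar(language))
  if (strategy %in% c("fileCont", "selfCorrect")) strategy <- "simple"
  tmpl <- .pb_templates[[strategy]]
  if (is.null(tmpl)) stop("unknown prompting strategy: ", strategy,
                          call. = FALSE)
  if (identical(language, "R")) return(tmpl)
  if (strategy == "simple") {
    sub("R code", paste(language, "code"), tmpl, fixed = TRUE)
  } else {
    sub("R programmer", paste(language, "programmer"), tmpl, fixed = TRUE)
  }
}

# Extensions recognized as data files when scanning task text.
.pb_file_exts <- c("txt", "tsv", "csv", "xls", "xlsx", "json", "bed",
                   "gff", "gtf", "fasta", "fa", "fastq", "vcf")

#' Detect data-file names mentioned in task text
#'
#' Scans for maximal runs of word characters, dots and hyphens ending in a
#' recognized data extension (case-insensitive on the extension). Trailing
#' sentence punctuation is not part of a token. Names are returned
#' deduplicated, in order of first appearance.
#'
#' @param task_text The task description.
#' @return Character vector of filenames (possibly empty).
#' @export
extract_filenames <- function(task_text) {
  stopifnot(is.character(task_text))
  task_text <- paste(task_text, collapse = "\n")
  m <- gregexpr("[A-Za-z0-9_.-]+", task_text)[[1L]]
  if (m[1L] == -1L) return(character())
  tokens <- regmatches(task_text, list(m))[[1L]]
  # strip trailing dots/hyphens (sentence punctuation glued to the token)
  tokens <- sub("[.-]+$", "", tokens)
  ext_re <- paste0("\\.(", paste(.pb_file_exts, collapse = "|"), ")$")
  hits <- tokens[grepl(ext_re, tokens, ignore.case = TRUE)]
  unique(hits)
}

#' Build the file-header addendum for a prompt
#'
#' For every filename, appends a block quoting the first `n_lines` raw lines
#' of the file, introduced by the fixed sentence
#' `"Here are the first two lines of the file <name>:"` (the wording uses
#' "two" only when `n_lines` is 2, otherwise "first <n> lines"). Spreadsheet
#' workbooks (`.xls`/`.xlsx`) are rendered as the first rows of their first
#' sheet, tab-separated. Each injected line is clipped to `max_line_chars`
#' characters with a trailing `"..."` marker, a guard for very wide matrices.
#'
#' @param filenames Character vector of file names (as mentioned in the
#'   task text).
#' @param data_dir Directory the files live in.
#' @param n_lines Number of lines to inject per file (default 2).
#' @param max_line_chars Per-line clip width.
#' @return A single string; empty when `filenames` is empty.
#' @export
build_file_header_addendum <- function(filenames, data_dir, n_lines = 2L,
                                       max_line_chars = 2000L) {
  stopifnot(is.numeric(n_lines), length(n_lines) == 1L)
  if (n_lines < 1) stop("n_lines must be at least 1", call. = FALSE)
  n_lines <- as.integer(n_lines)
  if (length(filenames) == 0L) return("")
  blocks <- vapply(filenames, function(fn) {
    path <- file.path(data_dir, fn)
    if (!file.exists(path)) {
      stop("data file not found: ", fn, " (under ", data_dir, ")",
           call. = FALSE)
    }
    lines <- read_head_lines(path, n_lines)
    too_long <- nchar(lines) > max_line_chars
    lines[too_long] <- paste0(substr(lines[too_long], 1L, max_line_chars),
                              "...")
    intro <- if (n_lines == 2L) {
      sprintf("Here are the first two lines of the file %s:", fn)
    } else {
      sprintf("Here are the first %d lines of the file %s:", n_lines, fn)
    }
    paste(c(intro, lines), collapse = "\n")
  }, "")
  paste(blocks, collapse = "\n")
}

# First n raw lines of a file; spreadsheets are rendered tab-separated.
read_head_lines <- function(path, n) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheet headers requires the 'readxl' package",
           call. = FALSE)
    }
    # header row + data rows of the first sheet
    df <- readxl::read_excel(path, n_max = max(n - 1L, 0L),
                             col_types = "text", .name_repair = "minimal")
    rows <- c(paste(names(df), collapse = "\t"),
              apply(df, 1L, paste, collapse = "\t"))
    utils::head(rows, n)
  } else {
    readLines(path, n = n, warn = FALSE)
  }
}

#' Build the self-correction instruction
#'
#' The fixed error-feedback turn: the captured error/warning text is embedded
#' verbatim between the instruction sentences.
#'
#' @param error_text Non-empty error or warning text from a failed execution.
#' @return A single string.
#' @export
build_correction_prompt <- function(error_text) {
  stopifnot(is.character(error_text), length(error_text) == 1L)
  if (!nzchar(error_text)) {
    stop("error_text must be non-empty", call. = FALSE)
  }
  paste0(
    "The previous code above returned the following errors and/or warnings:\n",
    error_text,
    "\nFix the error and return the fixed code in one block, delimited in ",
    "triple backticks.")
}

#' Assemble the prompt bundle for a task
#'
#' Combines the strategy's system prompt with the task text and, when file
#' headers are requested, detects the files mentioned in the task and
#' appends their header addendum at the end of the user prompt.
#'
#' @param task_text The user's task description.
#' @param strategy One of [pb_strategies].
#' @param data_dir Directory holding the mentioned data files (required when
#'   `include_file_headers` is `TRUE` and the task mentions files).
#' @param include_file_headers Append file headers? Defaults to `TRUE` for
#'   the `fileCont` and `selfCorrect` strategies, `FALSE` otherwise.
#' @param n_lines,max_line_chars Passed to [build_file_header_addendum()].
#' @param language Generated-code language for the system prompt.
#' @return An object of class `prompt_bundle` with fields `system_text`,
#'   `user_text` and `injected_files`.
#' @export
build_prompt_bundle <- function(task_text, strategy = "simple",
                                data_dir = NULL,
                                include_file_headers =
                                  strategy %in% c("fileCont", "selfCorrect"),
                                n_lines = 2L, max_line_chars = 2000L,
                                language = "R") {
  system_text <- build_system_prompt(strategy, language)
  user_text <- task_text
  injected <- data.frame(filename = character(), lines_used = integer(),
                         stringsAsFactors = FALSE)
  if (include_file_headers) {
    fns <- extract_filenames(task_text)
    if (length(fns)) {
      if (is.null(data_dir)) {
        stop("data_dir is required to inject file headers", call. = FALSE)
      }
      addendum <- build_file_header_addendum(fns, data_dir, n_lines,
                                             max_line_chars)
      user_text <- paste(user_text, addendum, sep = "\n")
      injected <- data.frame(filename = fns,
                             lines_used = rep.int(as.integer(n_lines),
                                                  length(fns)),
                             stringsAsFactors = FALSE)
    }
  }
  structure(list(system_text = system_text, user_text = user_text,
                 injected_files = injected),
            class = "prompt_bundle")
}
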