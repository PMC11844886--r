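#' Normalize a raw model reply
#'
#' Model replies occasionally carry typographic characters that break code:
#' curly quotes, prime marks, acute accents standing in for backticks,
#' zero-width and non-breaking spaces, and CRLF line endings. This pass maps
#' them to their straight ASCII equivalents, strips the invisible
#' characters, normalizes line endings to LF and trims trailing whitespace
#' per line. Fenced content is otherwise untouched, and the operation is
#' idempotent.
#'
#' @param reply Raw reply text (length-one character).
#' @return The cleaned reply.
#' @export
clean_response <- function(reply) {
  stopifnot(is.character(reply), length(reply) == 1L)
  x <- reply
  # line endings first
  x <- gsub("\r\n", "\n", x, fixed = TRUE)
  x <- gsub("\r", "\n", x, fixed = TRUE)
  # typographic double quotes -> "
  x <- gsub("[\u201c\u201d\u201e\u201f\u00ab\u00bb]", "\"", x, perl = TRUE)
  # typographic single quotes / primes -> '
  x <- gsub("[\u2018\u2019\u201a\u201b\u2032]", "'", x, perl = TRUE)
  # acute accent / reversed prime masquerading as backtick -> `
  x <- gsub("[\u00b4\u2035]", "`", x, perl = TRUE)
  # zero-width characters and BOM: drop
  x <- gsub("[\u200b\u200c\u200d\ufeff]", "", x, perl = TRUE)
  # non-breaking space -> plain space
  x <- gsub("\u00a0", " ", x, perl = TRUE)
  # trailing whitespace per line
  x <- gsub("[ \t]+(\n|$)", "\\1", x, perl = TRUE)
  x
}

#' Extract fenced code from a cleaned reply
#'
#' Parses triple-backtick fences. The default policy keeps only the final
#' block — the system prompts instruct the model to provide the code as a
#' single block at the end of its response — while `concatenate_all` joins
#' every block in order. A reply without any fence yields an empty marker
#' (`is_empty = TRUE`). An unclosed fence is treated as running to the end
#' of the reply and flagged `unclosed = TRUE`.
#'
#' @param reply Reply text, already passed through [clean_response()].
#' @param policy `"last_block"` or `"concatenate_all"`.
#' @return An object of class `code_block` with fields `code`,
#'   `fence_label`, `position`, `n_blocks`, `is_empty`, `unclosed`.
#' @export
extract_code <- function(reply, policy = c("last_block", "concatenate_all")) {
  policy <- match.arg(policy)
  stopifnot(is.character(reply), length(reply) == 1L)
  lines <- strsplit(reply, "\n", fixed = TRUE)[[1L]]
  blocks <- list()
  open <- FALSE
  label <- ""
  buf <- character()
  unclosed <- FALSE
  for (ln in lines) {
    if (grepl("^\\s*```", ln)) {
      if (!open) {
        open <- TRUE
        label <- trimws(sub("^\\s*```", "", ln))
        buf <- character()
      } else {
        blocks[[length(blocks) + 1L]] <- list(code = paste(buf, collapse = "\n"),
                                              label = label)
        open <- FALSE
      }
    } else if (open) {
      buf <- c(buf, ln)
    }
  }
  if (open) { # fence never closed: runs to end of reply
    blocks[[length(blocks) + 1L]] <- list(code = paste(buf, collapse = "\n"),
                                          label = label)
    unclosed <- TRUE
  }
  if (length(blocks) == 0L) {
    return(structure(list(code = "", fence_label = "", position = 0L,
                          n_blocks = 0L, is_empty = TRUE, unclosed = FALSE),
                     class = "code_block"))
  }
  if (policy == "last_block") {
    b <- blocks[[length(blocks)]]
    code <- b$code
    label <- b$label
    pos <- length(blocks)
  } else {
    code <- paste(vapply(blocks, `[[`, "", "code"), collapse = "\n")
    labels <- vapply(blocks, `[[`, "", "label")
    label <- if (any(nzchar(labels))) labels[nzchar(labels)][1L] else ""
    pos <- 1L
  }
  structure(list(code = code, fence_label = label, position = pos,
                 n_blocks = length(blocks), is_empty = FALSE,
                 unclosed = unclosed),
            class = "code_block")
}

#' Detect package dependencies in generated code
#'
#' Line-wise regex scan with per-language pattern sets. For R code:
#' `library(NAME)`, `require(NAME)`, `NAME::` qualifiers and
#' `install.packages("NAME")`. For Python code: `import NAME` and
#' `from NAME import ...` (top-level module kept). The fence label selects
#' the language; unlabeled fences are assumed to be in `default_language`.
#'
#' @param code Code text.
#' @param fence_label Fence info string (e.g. `"r"`, `"python"`, `""`).
#' @param default_language Language assumed for unlabeled fences.
#' @return An object of class `dependency_set` with fields `names`
#'   (character, unique, in order of first detection) and `detected_from`
#'   (data frame of pattern kind and line number).
#' @export
extract_dependencies <- function(code, fence_label = "",
                                 default_language = "r") {
  stopifnot(is.character(code), length(code) == 1L)
  lang <- normalize_language(fence_label, default_language)
  lines <- strsplit(code, "\n", fixed = TRUE)[[1L]]
  names <- character()
  kinds <- character()
  lnos <- integer()
  add <- function(nm, kind, lno) {
    nm <- nm[nzchar(nm)]
    for (x in nm) {
      names <<- c(names, x); kinds <<- c(kinds, kind); lnos <<- c(lnos, lno)
    }
  }
  if (lang == "r") {
    pats <- c(
      library = "(?:^|[^\\w.])library\\(\\s*[\"']?([A-Za-z][A-Za-z0-9.]*)",
      require = "(?:^|[^\\w.])require\\(\\s*[\"']?([A-Za-z][A-Za-z0-9.]*)",
      colon_qualifier = "([A-Za-z][A-Za-z0-9.]*)\\s*::",
      install_packages = "install\\.packages\\(\\s*[\"']([A-Za-z][A-Za-z0-9.]*)[\"']"
    )
    for (i in seq_along(lines)) {
      for (kind in names(pats)) {
        m <- gregexpr(pats[[kind]], lines[[i]], perl = TRUE)[[1L]]
        if (m[1L] == -1L) next
        starts <- attr(m, "capture.start")[, 1L]
        lens <- attr(m, "capture.length")[, 1L]
        caps <- substring(lines[[i]], starts, starts + lens - 1L)
        add(caps, kind, i)
      }
    }
  } else if (lang == "python") {
    for (i in seq_along(lines)) {
      m <- regmatches(lines[[i]],
                      regexec("^\\s*import\\s+([A-Za-z_][A-Za-z0-9_.,[:space:]]*)",
                              lines[[i]]))[[1L]]
      if (length(m) == 2L) {
        mods <- strsplit(m[2L], ",")[[1L]]
        mods <- sub("\\s+as\\s+.*$", "", trimws(mods))
        mods <- sub("\\..*$", "", mods)
        add(mods, "import", i)
      }
      m <- regmatches(lines[[i]],
                      regexec("^\\s*from\\s+([A-Za-z_][A-Za-z0-9_.]*)\\s+import",
                              lines[[i]]))[[1L]]
      if (length(m) == 2L) add(sub("\\..*$", "", m[2L]), "from_import", i)
    }
  }
  keep <- !duplicated(names)
  structure(list(names = names[keep],
                 detected_from = data.frame(pattern = kinds, line = lnos,
                                            stringsAsFactors = FALSE)),
            class = "dependency_set")
}

normalize_language <- function(fence_label, default_language = "r") {
  lab <- tolower(trimws(fence_label))
  lab <- gsub("[{}]", "", lab)
  if (!nzchar(lab)) return(tolower(default_language))
  if (lab %in% c("r", "rscript")) return("r")
  if (lab %in% c("python", "py", "python3")) return("python")
  lab
}

#' Default installation allowlist
#'
#' Common analysis packages a generated R script may reasonably pull in.
#' Used by [ensure_dependencies()] under the `install_allowlisted` policy.
#' @export
pb_default_allowlist <- c(
  "ggplot2", "dplyr", "tidyr", "readr", "tibble", "stringr", "purrr",
  "data.table", "reshape2", "pheatmap", "cluster", "MASS", "Matrix",
  "caret", "randomForest", "e1071", "glmnet", "survival",
  "DESeq2", "edgeR", "limma", "ComplexHeatmap"
)

#' Check and (optionally) install detected dependencies
#'
#' Availability is probed in the executor's library path. Under
#' `report_only` absent packages are reported `missing`; under `forbid`
#' they are reported `blocked`; neither policy performs any installation.
#' `install_allowlisted` installs absent packages that are on the allowlist
#' and blocks the rest; `install_all` installs everything absent.
#' Installation failure is a recorded status (`failed`), not an exception.
#'
#' @param deps A `dependency_set` from [extract_dependencies()].
#' @param policy One of `"report_only"`, `"forbid"`, `"install_allowlisted"`,
#'   `"install_all"`.
#' @param allowlist Character vector of installable package names.
#' @param lib Library path for installs (default: first on `.libPaths()`).
#' @return Data frame with columns `name` and `status` (one of `present`,
#'   `missing`, `installed`, `blocked`, `failed`).
#' @export
ensure_dependencies <- function(deps,
                                policy = c("report_only", "forbid",
                                           "install_allowlisted",
                                           "install_all"),
                                allowlist = pb_default_allowlist,
                                lib = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(deps, "dependency_set"))
  nms <- deps$names
  if (length(nms) == 0L) {
    return(data.frame(name = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  status <- vapply(nms, function(nm) {
    if (nzchar(system.file(package = nm))) return("present")
    switch(policy,
      report_only = "missing",
      forbid = "blocked",
      install_allowlisted = if (nm %in% allowlist) "install" else "blocked",
      install_all = "install")
  }, "")
  todo <- which(status == "install")
  for (i in todo) {
    ok <- tryCatch({
      suppressWarnings(utils::install.packages(
        nms[[i]], lib = lib, quiet = TRUE,
        repos = getOption("repos")))
      nzchar(system.file(package = nms[[i]]))
    }, error = function(e) FALSE)
    status[[i]] <- if (ok) "installed" else "failed"
  }
  data.frame(name = nms, status = unname(status), stringsAsFactors = FALSE)
}
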