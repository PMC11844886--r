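#' Describe a chat-completion agent
#'
#' An agent spec names either a remote OpenAI-compatible endpoint or a
#' deterministic scripted mock. Credentials are referenced by name (an
#' environment variable or a file path), never stored: the secret is read
#' at request time only and never appears in logs or serialized objects.
#'
#' @param backend `"mock"` or `"remote"`.
#' @param model Model name forwarded to the provider (ignored by mocks).
#' @param endpoint Chat-completions URL (remote only).
#' @param credential Name of the environment variable, or path of the file,
#'   holding the API key (remote only).
#' @param temperature Sampling temperature; `0` by default so that live runs
#'   are as repeatable as the provider allows. Use `"provider-default"` to
#'   omit the field from requests.
#' @param max_reply_tokens Optional cap on the reply length in tokens.
#' @param mock_script A [mock_script()] object or the path of a mock-script
#'   YAML file (mock only).
#' @return An object of class `agent_spec`.
#' @seealso [setup_agent()], [mock_script()]
#' @export
agent_spec <- function(backend = c("mock", "remote"),
                       model = "gpt-3.5-turbo",
                       endpoint = NULL,
                       credential = NULL,
                       temperature = 0,
                       max_reply_tokens = NULL,
                       mock_script = NULL) {
  if (length(backend) == 1L && !backend %in% c("mock", "remote")) {
    stop("unknown backend kind: ", backend, call. = FALSE)
  }
  backend <- match.arg(backend)
  if (!identical(temperature, "provider-default")) {
    stopifnot(is.numeric(temperature), length(temperature) == 1L,
              temperature >= 0)
  }
  if (!is.null(max_reply_tokens)) {
    stopifnot(is.numeric(max_reply_tokens), max_reply_tokens >= 1)
  }
  if (backend == "remote") {
    if (is.null(endpoint) || !nzchar(endpoint)) {
      stop("remote agent spec requires an endpoint URL", call. = FALSE)
    }
    if (is.null(credential) || !nzchar(credential)) {
      stop("remote agent spec requires a credential reference", call. = FALSE)
    }
  } else {
    if (is.null(mock_script)) {
      stop("mock agent spec requires a mock script (object or path)",
           call. = FALSE)
    }
  }
  structure(
    list(backend = backend, model = model, endpoint = endpoint,
         credential = credential, temperature = temperature,
         max_reply_tokens = max_reply_tokens, mock_script = mock_script),
    class = "agent_spec"
  )
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("<agent_spec>", x$backend, "model:", x$model, "\n")
  if (x$backend == "remote") {
    cat("  endpoint:", x$endpoint, "\n  credential ref:", x$credential, "\n")
  }
  invisible(x)
}

#' Scripted mock replies
#'
#' A mock script is an ordered list of canned assistant replies replayed in
#' place of a live model. Replay is a pure function of the turn index, so a
#' given (script, sequence of sends) always yields bitwise-identical replies.
#'
#' @param replies Character vector of replies, at least one.
#' @param replay_policy `"strict"` errors once the replies are exhausted;
#'   `"cycle"` wraps around.
#' @return An object of class `mock_script`.
#' @export
mock_script <- function(replies, replay_policy = c("strict", "cycle")) {
  replay_policy <- match.arg(replay_policy)
  replies <- as.character(replies)
  if (length(replies) < 1L) {
    stop("a mock script needs at least one reply", call. = FALSE)
  }
  structure(list(replies = replies, replay_policy = replay_policy),
            class = "mock_script")
}

#' Read / write mock scripts as YAML
#'
#' Scripts are stored as one YAML document with the keys `replay_policy`
#' and `replies`.
#'
#' @param path File path.
#' @return `read_mock_script()` returns a [mock_script()];
#'   `write_mock_script()` returns `path` invisibly.
#' @export
read_mock_script <- function(path) {
  if (!file.exists(path)) {
    stop("mock script file not readable: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$replies)) {
    stop("mock script file has no 'replies' key: ", path, call. = FALSE)
  }
  mock_script(unlist(doc$replies),
              replay_policy = doc$replay_policy %||% "strict")
}

#' @rdname read_mock_script
#' @param script A [mock_script()] object.
#' @export
write_mock_script <- function(script, path) {
  stopifnot(inherits(script, "mock_script"))
  yaml::write_yaml(list(replay_policy = script$replay_policy,
                        replies = as.list(script$replies)), path)
  invisible(path)
}

#' Set up an agent handle
#'
#' Validates the spec and returns an opaque handle usable with
#' [send_chat()]. No network call is made at setup time; for remote specs
#' only the resolvability of the credential is checked.
#'
#' @param spec An [agent_spec()].
#' @return An object of class `agent_handle` carrying per-session state
#'   (for mocks, the replay cursor).
#' @export
setup_agent <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  state <- new.env(parent = emptyenv())
  state$turn <- 0L
  if (spec$backend == "mock") {
    script <- spec$mock_script
    if (is.character(script)) script <- read_mock_script(script)
    if (!inherits(script, "mock_script")) {
      stop("mock_script must be a mock_script object or a file path",
           call. = FALSE)
    }
    state$script <- script
  } else {
    resolve_credential(spec$credential) # errors if unresolvable; value dropped
  }
  structure(list(spec = spec, state = state), class = "agent_handle")
}

# Resolve a credential reference to its secret value. The value is returned
# to the transport layer only and must never be attached to any object,
# message or log.
resolve_credential <- function(ref) {
  if (file.exists(ref)) {
    key <- readLines(ref, n = 1L, warn = FALSE)
  } else {
    key <- Sys.getenv(ref, unset = "")
  }
  if (!nzchar(key)) {
    stop("credential reference '", ref,
         "' resolves to neither a readable file nor a non-empty ",
         "environment variable", call. = FALSE)
  }
  key
}

#' Chat messages and transcripts
#'
#' A transcript is the ordered, role-tagged message list of one session:
#' at most one leading `system` message, then strictly alternating
#' `user`/`assistant` messages.
#'
#' @param role `"system"`, `"user"` or `"assistant"`.
#' @param content Message text; must be non-empty for user and assistant
#'   messages.
#' @return `chat_message()` returns a `chat_message`; `chat_transcript()`
#'   a validated `chat_transcript`.
#' @export
chat_message <- function(role = c("system", "user", "assistant"), content) {
  role <- match.arg(role)
  stopifnot(is.character(content), length(content) == 1L)
  if (role != "system" && !nzchar(content)) {
    stop("user/assistant message content must be non-empty", call. = FALSE)
  }
  structure(list(role = role, content = content), class = "chat_message")
}

#' @rdname chat_message
#' @param messages List of `chat_message` objects.
#' @export
chat_transcript <- function(messages = list()) {
  out <- structure(list(messages = messages), class = "chat_transcript")
  validate_transcript(out)
  out
}

validate_transcript <- function(transcript) {
  stopifnot(inherits(transcript, "chat_transcript"))
  roles <- vapply(transcript$messages, `[[`, "", "role")
  body <- roles
  if (length(body) && body[1L] == "system") body <- body[-1L]
  if (any(body == "system")) {
    stop("transcript may hold at most one leading system message",
         call. = FALSE)
  }
  if (length(body)) {
    expected <- rep_len(c("user", "assistant"), length(body))
    if (!all(body == expected)) {
      stop("user/assistant messages must alternate, starting with user",
           call. = FALSE)
    }
  }
  invisible(transcript)
}

#' @rdname chat_message
#' @param transcript A `chat_transcript`.
#' @export
transcript_append <- function(transcript, role, content) {
  msgs <- c(transcript$messages, list(chat_message(role, content)))
  chat_transcript(msgs)
}

#' Send one chat turn
#'
#' The transcript must end with a user message; the assistant reply text is
#' returned and it is the caller's responsibility to append it to the
#' transcript. Mock backends replay their script: the k-th send of a session
#' returns the k-th reply (strict scripts error when exhausted; cycling
#' scripts wrap). Remote backends POST the chat-completions JSON wire format
#' and retry transient transport failures up to 3 times with exponential
#' backoff.
#'
#' @param handle An `agent_handle` from [setup_agent()].
#' @param transcript A valid [chat_transcript()] ending in a user message.
#' @return The assistant reply, as a length-one character vector.
#' @export
send_chat <- function(handle, transcript) {
  stopifnot(inherits(handle, "agent_handle"))
  validate_transcript(transcript)
  n <- length(transcript$messages)
  if (n == 0L || transcript$messages[[n]]$role != "user") {
    stop("transcript must end with a user message", call. = FALSE)
  }
  if (handle$spec$backend == "mock") {
    send_mock(handle)
  } else {
    send_remote(handle, transcript)
  }
}

send_mock <- function(handle) {
  st <- handle$state
  script <- st$script
  idx <- st$turn + 1L
  if (idx > length(script$replies)) {
    if (script$replay_policy == "strict") {
      stop("strict mock script exhausted after ",
           length(script$replies), " replies", call. = FALSE)
    }
    idx <- ((idx - 1L) %% length(script$replies)) + 1L
  }
  st$turn <- st$turn + 1L
  script$replies[[idx]]
}

send_remote <- function(handle, transcript) {
  if (isTRUE(getOption("promptbench.network_guard"))) {
    stop("network access attempted while the network guard is active",
         call. = FALSE)
  }
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop("the 'curl' package is required for remote agents", call. = FALSE)
  }
  spec <- handle$spec
  body <- list(
    model = spec$model,
    messages = lapply(transcript$messages, function(m) {
      list(role = m$role, content = m$content)
    })
  )
  if (!identical(spec$temperature, "provider-default")) {
    body$temperature <- spec$temperature
  }
  if (!is.null(spec$max_reply_tokens)) {
    body$max_tokens <- as.integer(spec$max_reply_tokens)
  }
  payload <- jsonlite::toJSON(body, auto_unbox = TRUE)
  key <- resolve_credential(spec$credential)
  last_err <- NULL
  for (attempt in 1:3) {
    h <- curl::new_handle()
    curl::handle_setheaders(h,
      "Content-Type" = "application/json",
      "Authorization" = paste("Bearer", key))
    curl::handle_setopt(h, postfields = payload, post = TRUE)
    res <- tryCatch(curl::curl_fetch_memory(spec$endpoint, handle = h),
                    error = function(e) e)
    if (!inherits(res, "error") && res$status_code < 500L) {
      if (res$status_code >= 400L) {
        stop("chat endpoint returned HTTP ", res$status_code, call. = FALSE)
      }
      parsed <- jsonlite::fromJSON(rawToChar(res$content),
                                   simplifyVector = FALSE)
      reply <- parsed$choices[[1L]]$message$content
      handle$state$turn <- handle$state$turn + 1L
      return(reply)
    }
    last_err <- res
    wait <- 0.5 * 2^(attempt - 1L)
    message("transient chat transport failure (attempt ", attempt,
            "/3), retrying in ", wait, "s")
    Sys.sleep(wait)
  }
  stop("chat transport failed after 3 attempts: ",
       if (inherits(last_err, "error")) conditionMessage(last_err)
       else paste("HTTP", last_err$status_code), call. = FALSE)
}

#' Append a session transcript to a line-delimited audit file
#'
#' One JSON object per message, tagged with a session identifier, so that
#' benchmark responses can be inspected post hoc. Credentials are never part
#' of a transcript.
#'
#' @param transcript A [chat_transcript()].
#' @param path Destination file; created if missing, appended otherwise.
#' @param session_id Free-text tag grouping the lines of one session.
#' @return `path`, invisibly.
#' @export
record_transcript <- function(transcript, path, session_id = "session") {
  validate_transcript(transcript)
  lines <- vapply(transcript$messages, function(m) {
    jsonlite::toJSON(list(session = session_id, role = m$role,
                          content = m$content), auto_unbox = TRUE)
  }, "")
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
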