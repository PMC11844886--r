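test_that("execution captures success, errors, and timeouts", {
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  ok <- execute_code("x <- 1", ws, timeout_seconds = 30)
  expect_identical(ok$status, "success")
  expect_identical(ok$error_text, "")
  bad <- execute_code("y <- undefined_name_abc + 1", ws,
                      timeout_seconds = 30)
  expect_identical(bad$status, "error")
  expect_true(grepl("undefined_name_abc", bad$error_text))
  t0 <- Sys.time()
  slow <- execute_code("while (TRUE) {}", ws, timeout_seconds = 2)
  expect_identical(slow$status, "timeout")
  expect_identical(slow$error_text, "execution exceeded the time limit")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 15)
})

test_that("warnings are captured separately and gate only in strict mode", {
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  code <- "warning(\"careful now\")\ncat(\"done\\n\")"
  lax <- execute_code(code, ws, timeout_seconds = 30)
  expect_identical(lax$status, "success")
  expect_identical(lax$warning_texts, "careful now")
  expect_true(grepl("done", lax$stdout_text))
  strict <- execute_code(code, ws, timeout_seconds = 30,
                         strict_warnings = TRUE)
  expect_identical(strict$status, "error")
  expect_true(grepl("careful now", strict$error_text))
})

test_that("artifacts are the files the run newly created under the root", {
  with_tmpdir(function(d) {
    writeLines("a\tb", file.path(d, "in.txt"))
    ws <- create_workspace(inputs = "in.txt", from_dir = d)
    on.exit(cleanup_workspace(ws))
    res <- execute_code(
      "x <- readLines(\"in.txt\")\nwrite.csv(data.frame(n = nchar(x)), \"out.csv\")",
      ws, timeout_seconds = 30)
    expect_identical(res$status, "success")
    expect_identical(res$artifacts, "out.csv")
    expect_true(file.exists(file.path(ws$root, "out.csv")))
  })
})

test_that("staging copies inputs and rejects missing files", {
  with_tmpdir(function(d) {
    writeLines("x", file.path(d, "a.txt"))
    ws <- create_workspace(inputs = "a.txt", from_dir = d)
    on.exit(cleanup_workspace(ws))
    expect_identical(ws$staged_inputs, "a.txt")
    # a copy, not a link: mutating the staged file leaves the source alone
    writeLines("mutated", file.path(ws$root, "a.txt"))
    expect_identical(readLines(file.path(d, "a.txt")), "x")
    expect_error(create_workspace(inputs = "ghost.txt", from_dir = d),
                 "ghost.txt")
  })
})

test_that("consecutive executions share no interpreter state", {
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  first <- execute_code("leaky_var <- 42", ws, timeout_seconds = 30)
  expect_identical(first$status, "success")
  second <- execute_code("print(leaky_var)", ws, timeout_seconds = 30)
  expect_identical(second$status, "error")
  expect_true(grepl("leaky_var", second$error_text))
})

test_that("runs confine file writes to the workspace root", {
  with_tmpdir(function(parent) {
    tripwire <- file.path(parent, "tripwire")
    dir.create(tripwire)
    ws <- create_workspace(dir = file.path(parent, "ws"))
    snapshot <- list.files(parent, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE)
    res <- execute_code(
      "writeLines(\"hi\", \"inside.txt\")\ncat(getwd(), \"\\n\")",
      ws, timeout_seconds = 30)
    expect_identical(res$status, "success")
    expect_identical(res$artifacts, "inside.txt")
    expect_length(list.files(tripwire, recursive = TRUE, all.files = TRUE,
                             no.. = TRUE), 0L)
    after <- list.files(parent, recursive = TRUE, all.files = TRUE,
                        no.. = TRUE)
    new_outside <- setdiff(after, snapshot)
    expect_true(all(startsWith(new_outside, "ws/")))
    cleanup_workspace(ws)
    expect_false(dir.exists(ws$root)) # retain = FALSE removes the root
  })
})

test_that("deterministic code gives a deterministic harness verdict", {
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  statuses <- vapply(1:3, function(i) {
    execute_code("set.seed(1)\ncat(sum(rnorm(5)), \"\\n\")", ws,
                 timeout_seconds = 30)$status
  }, "")
  expect_identical(statuses, rep("success", 3L))
})

test_that("an unknown executor backend is a distinct failure", {
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  expect_error(execute_code("x", ws, backend = "cobol"), "backend")
})

test_that("the python executor adapter runs fenced python code", {
  skip_if(Sys.which("python") == "")
  ws <- create_workspace()
  on.exit(cleanup_workspace(ws))
  ok <- execute_code("print(sum([1, 2, 3]))", ws, backend = "python",
                     timeout_seconds = 30)
  expect_identical(ok$status, "success")
  expect_true(grepl("6", ok$stdout_text))
  bad <- execute_code("undefined_name_abc", ws, backend = "python",
                      timeout_seconds = 30)
  expect_identical(bad$status, "error")
  expect_true(grepl("undefined_name_abc", bad$error_text))
})

test_that("the session report holds prompts, code, errors, and artifacts", {
  with_tmpdir(function(d) {
    ws <- create_workspace()
    on.exit(cleanup_workspace(ws))
    good <- execute_code("cat(\"hello\\n\")", ws, timeout_seconds = 30)
    bad <- execute_code("stop(\"kaboom-xyz\")", ws, timeout_seconds = 30)
    session <- list(
      list(prompt = "Say <hello>", reply = "```r\ncat(\"hello\\n\")\n```",
           code_block = extract_code("```r\ncat(\"hello\\n\")\n```"),
           result = good),
      list(prompt = "Fail", reply = "```r\nstop(\"kaboom-xyz\")\n```",
           code_block = extract_code("```r\nstop(\"kaboom-xyz\")\n```"),
           result = bad))
    path <- render_html_report(session, file.path(d, "report.html"))
    html <- paste(readLines(path), collapse = "\n")
    expect_true(grepl("cat(\"hello\\n\")", html, fixed = TRUE))
    expect_true(grepl("kaboom-xyz", html))
    expect_true(grepl("Say &lt;hello&gt;", html)) # escaping
    empty <- render_html_report(list(), file.path(d, "empty.html"))
    expect_true(grepl("No rounds", paste(readLines(empty), collapse = "")))
    expect_error(render_html_report(list(), file.path(d, "no/such/dir/x.html")),
                 "cannot write")
  })
})
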