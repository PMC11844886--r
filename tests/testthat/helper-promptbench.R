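# The whole suite runs offline: the network guard makes any remote
# transport attempt fail loudly, so a test that accidentally reached the
# network would error instead of silently connecting.
options(promptbench.network_guard = TRUE)

# Execution settings shared by tests: no installations, short timeout.
test_config <- function(...) {
  defaults <- list(dependency_policy = "report_only", timeout_seconds = 30)
  do.call(self_correct_config, utils::modifyList(defaults, list(...)))
}

mock_agent <- function(script) {
  if (is.character(script) && length(script) == 1L &&
      script %in% c("clean", "fail_then_fix", "always_fail", "no_code")) {
    script <- make_mock_script(script)
  } else if (is.character(script)) {
    script <- mock_script(script)
  }
  setup_agent(agent_spec("mock", mock_script = script))
}

with_tmpdir <- function(fn) {
  d <- tempfile("pbtest_")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  fn(d)
}

# A two-task mini suite (one simple, one complex) with stageable data.
make_mini_suite <- function(data_dir) {
  stage_task_data(data_dir, seed = 7L)
  list(
    task_spec("mini_read",
              "Read the tab separated file \"subjects.txt\" and print its dimensions.",
              data_files = "subjects.txt",
              components = "read_file"),
    task_spec("mini_full",
              paste("Read \"leukemiaExp.txt\" and \"subjects.txt\", keep the",
                    "most variable genes, cluster samples, test clusters",
                    "against group and save a plot to a PDF file."),
              data_files = c("leukemiaExp.txt", "subjects.txt"),
              components = pb_components)
  )
}
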