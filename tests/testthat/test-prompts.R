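# Frozen golden copies of the three strategy system prompts and the fixed
# instruction templates; the builders must reproduce them byte for byte.
golden_simple <- paste0(
  "Provide R code for the following tasks. Provide the code in triple ",
  "backticks (``` and ```). Provide the code as a single block at the end ",
  "of your response. Do not provide code output.")
golden_actas <- paste0(
  "Act as an expert bioinformatician and R programmer. You also have a ",
  "lot of knowledge about biology. Complete the following tasks, using ",
  "your expertise and always provide relevant code. When providing the ",
  "code in triple backticks (``` and ```). Provide the code as a single ",
  "block at the end of your response.")
golden_cot <- paste0(
  "Act as an expert bioinformatician and R programmer. You also have a ",
  "lot of knowledge about biology. Answer questions using your expertise ",
  "and always provide code. When providing code, provide the code in ",
  "triple backticks (``` and ```). Provide the code as a single block at ",
  "the end of your response. Let's work this out in a step by step way ",
  "to be sure we have the right answer.")

test_that("system prompts byte-match their fixed templates", {
  expect_identical(build_system_prompt("simple"), golden_simple)
  expect_identical(build_system_prompt("actAs"), golden_actas)
  expect_identical(build_system_prompt("cot"), golden_cot)
  # fileCont and selfCorrect ride on the simple template
  expect_identical(build_system_prompt("fileCont"), golden_simple)
  expect_identical(build_system_prompt("selfCorrect"), golden_simple)
  expect_error(build_system_prompt("mystery"), "unknown")
})

test_that("another code language is substituted at its single mention", {
  py <- build_system_prompt("simple", language = "Python")
  expect_true(startsWith(py, "Provide Python code for the following tasks."))
  expect_identical(sub("Python", "R", py, fixed = TRUE), golden_simple)
  pa <- build_system_prompt("actAs", language = "Python")
  expect_true(grepl("bioinformatician and Python programmer", pa))
  expect_identical(length(gregexpr("Python", pa, fixed = TRUE)[[1L]]), 1L)
})

# Independent oracle: split the text into runs of token characters, strip
# trailing punctuation, keep tokens whose extension is allowlisted, first
# occurrences only.
oracle_filenames <- function(text) {
  exts <- c("txt", "tsv", "csv", "xls", "xlsx", "json", "bed", "gff",
            "gtf", "fasta", "fa", "fastq", "vcf")
  toks <- strsplit(text, "[^A-Za-z0-9_.-]+")[[1L]]
  toks <- sub("[.-]+$", "", toks)
  keep <- vapply(toks, function(t) {
    parts <- strsplit(t, ".", fixed = TRUE)[[1L]]
    length(parts) > 1L && tolower(parts[length(parts)]) %in% exts
  }, TRUE)
  unique(toks[keep])
}

test_that("filename detection matches the scan oracle and dedupes in order", {
  txt <- paste("I have a file called leukemiaExp.txt, which holds",
               "information about gene expression data.")
  expect_identical(extract_filenames(txt), "leukemiaExp.txt")
  expect_identical(extract_filenames("Cluster the samples using k-means."),
                   character(0))
  txt2 <- paste("Merge subjects.txt with leukemiaExp.txt, then check",
                "subjects.txt again.")
  expect_identical(extract_filenames(txt2),
                   c("subjects.txt", "leukemiaExp.txt"))
  # sentence-final period and quoting do not leak into the token
  expect_identical(extract_filenames("Open \"subjects.txt\"."),
                   "subjects.txt")
  # unrecognized trailing extension disqualifies the whole token
  expect_identical(extract_filenames("archive data.txt.bak today"),
                   character(0))

  cases <- c(
    "Use counts.tsv and meta-data_v2.csv; ignore readme.md and run.sh.",
    "Files: a.b.c.txt then A.XLSX then nothing.dat",
    "x.fa x.fa x.fastq x.fa",
    "sentence ends with genes.gtf.",
    "no files at all",
    "weird spacing\tvariants.vcf\nand regions.bed!")
  for (cs in cases) {
    expect_identical(extract_filenames(cs), oracle_filenames(cs), info = cs)
  }
})

test_that("filename detection is idempotent over its own rendered output", {
  txt <- "Join subjects.txt with leukemiaExp.txt and counts.tsv."
  fns <- extract_filenames(txt)
  expect_identical(extract_filenames(paste(fns, collapse = " ")), fns)
})

test_that("file-header addendum quotes the head lines with exact wording", {
  with_tmpdir(function(d) {
    writeLines(c("a\tb", "1\t2", "3\t4"), file.path(d, "f.txt"))
    add <- build_file_header_addendum("f.txt", d, n_lines = 2)
    expect_identical(add,
                     "Here are the first two lines of the file f.txt:\na\tb\n1\t2")
    # n != 2 switches to the generic wording and keeps n content lines
    add3 <- build_file_header_addendum("f.txt", d, n_lines = 3)
    expect_true(startsWith(add3, "Here are the first 3 lines of the file f.txt:"))
    expect_length(strsplit(add3, "\n")[[1L]], 4L)
    expect_identical(build_file_header_addendum(character(), d, 2), "")
    expect_error(build_file_header_addendum("ghost.txt", d, 2), "ghost.txt")
    expect_error(build_file_header_addendum("f.txt", d, 0), "n_lines")
  })
})

test_that("addendum line budget holds per file and long lines are clipped", {
  with_tmpdir(function(d) {
    writeLines(c("h1\th2", "1\t2", "3\t4"), file.path(d, "a.txt"))
    writeLines(c(strrep("x", 50), "short"), file.path(d, "b.txt"))
    add <- build_file_header_addendum(c("a.txt", "b.txt"), d, n_lines = 2,
                                      max_line_chars = 10)
    lines <- strsplit(add, "\n")[[1L]]
    expect_length(lines, 6L) # 2 intros + 2 content lines each
    expect_identical(lines[5L], paste0(strrep("x", 10), "..."))
  })
})

test_that("spreadsheet headers are rendered tab-separated", {
  skip_if_not_installed("readxl")
  with_tmpdir(function(d) {
    wb <- file.path(d, "wb.xlsx")
    pycode <- sprintf(paste0(
      "import openpyxl\nwb = openpyxl.Workbook()\nws = wb.active\n",
      "ws.append(['gene', 's1'])\nws.append(['g1', 1])\n",
      "ws.append(['g2', 2])\nwb.save(r'%s')"), wb)
    processx::run(Sys.which("python"), c("-c", pycode))
    add <- build_file_header_addendum("wb.xlsx", d, n_lines = 2)
    lines <- strsplit(add, "\n")[[1L]]
    expect_identical(lines[2L], "gene\ts1")
    expect_identical(lines[3L], "g1\t1")
  })
})

test_that("correction prompt embeds the error verbatim between fixed text", {
  p <- build_correction_prompt("could not find function foo")
  expect_true(startsWith(
    p, "The previous code above returned the following errors and/or warnings:"))
  expect_true(endsWith(
    p, "Fix the error and return the fixed code in one block, delimited in triple backticks."))
  traceback <- "Error in f(x):\n  could not find function \"f\"\nCalls: g -> f"
  expect_true(grepl(traceback,
                    build_correction_prompt(traceback), fixed = TRUE))
  expect_error(build_correction_prompt(""), "non-empty")
})

test_that("prompt bundles append the addendum at the end of the user text", {
  with_tmpdir(function(d) {
    writeLines(c("a\tb", "1\t2"), file.path(d, "f.txt"))
    task <- "Read the file f.txt and summarize it."
    b <- build_prompt_bundle(task, strategy = "fileCont", data_dir = d)
    expect_identical(b$system_text, golden_simple)
    expect_true(startsWith(b$user_text, task))
    expect_true(endsWith(b$user_text, "a\tb\n1\t2"))
    expect_identical(b$injected_files$filename, "f.txt")
    expect_identical(b$injected_files$lines_used, 2L)
    # non-file strategies leave the user text untouched
    b2 <- build_prompt_bundle(task, strategy = "simple", data_dir = d)
    expect_identical(b2$user_text, task)
    expect_identical(nrow(b2$injected_files), 0L)
  })
})
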