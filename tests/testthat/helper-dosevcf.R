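# shared test helpers: tiny GEN/sample writers and a subprocess runner

write_tmp <- function(lines, ext = ".gen") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

write_sample_file <- function(n, ids = sprintf("ind%d", seq_len(n))) {
  write_tmp(c("ID_1 ID_2 missing", "0 0 0",
              sprintf("fam%d %s 0", seq_len(n), ids)),
            ext = ".sample")
}

# run the installed CLI script in a subprocess (for pipe/exit-code tests);
# the private test library must be visible to the child R process
run_cli <- function(args, stdin_file = NULL) {
  script <- file.path(find.package("dosevcf"), "exec", "dosevcf")
  stdout_file <- tempfile()
  stderr_file <- tempfile()
  status <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2("Rscript", c(shQuote(script), shQuote(args)),
            stdout = stdout_file, stderr = stderr_file,
            stdin = if (is.null(stdin_file)) "" else stdin_file)
  )
  list(status = status,
       stdout = readLines(stdout_file, warn = FALSE),
       stderr = readLines(stderr_file, warn = FALSE))
}

strip_date <- function(lines) lines[!startsWith(lines, "##fileDate=")]
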