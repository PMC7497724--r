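test_that("dialect detection resolves 5- vs 6-column layouts from token counts", {
  d5 <- detect_dialect(11)
  expect_equal(d5$leading_columns, 5L)
  expect_false(d5$has_chrom_column)
  expect_equal(d5$n_samples, 2L)

  d6 <- detect_dialect(12)
  expect_equal(d6$leading_columns, 6L)
  expect_true(d6$has_chrom_column)
  expect_equal(d6$n_samples, 2L)

  expect_error(detect_dialect(13), class = "dosevcf_malformed_line")
  expect_error(detect_dialect(7), class = "dosevcf_malformed_line")

  # exhaustive over N: detection is total and unambiguous
  for (n in 1:500) {
    expect_identical(detect_dialect(5L + 3L * n)$leading_columns, 5L)
    expect_identical(detect_dialect(5L + 3L * n)$n_samples, n)
    expect_identical(detect_dialect(6L + 3L * n)$leading_columns, 6L)
  }
  # every count == 1 (mod 3) is rejected
  for (tc in seq(10, 100, by = 3)) {
    expect_error(detect_dialect(tc), class = "dosevcf_malformed_line")
  }
})

test_that("declared sample count must agree with the token count", {
  expect_equal(detect_dialect(11, declared_samples = 2)$leading_columns, 5L)
  expect_error(detect_dialect(11, declared_samples = 3),
               class = "dosevcf_malformed_line")
})

test_that("GEN lines map positionally onto records in both layouts", {
  rec <- parse_gen_line("1 snp1 rs1 1000 A G 1 0 0", detect_dialect(9), 1)
  expect_equal(rec$chrom, "1")
  expect_equal(rec$varid, "snp1")
  expect_equal(rec$rsid, "rs1")
  expect_equal(rec$pos, 1000)
  expect_equal(rec$allele_a, "A")
  expect_equal(rec$allele_b, "G")
  expect_equal(unname(rec$probs[1, ]), c(1, 0, 0))

  rec5 <- parse_gen_line("snp1 rs1 1000 A G 0 0 0", detect_dialect(8), 1)
  expect_true(is.na(rec5$chrom))
  expect_equal(rec5$varid, "snp1")
  expect_equal(unname(rec5$probs[1, ]), c(0, 0, 0))
})

test_that("malformed GEN lines are rejected with their line number", {
  d <- detect_dialect(9)
  expect_error(parse_gen_line("1 snp1 rs1 1000 A G 0.5 x 0.5", d, 1, 42),
               "line 42.*non-numeric", class = "dosevcf_malformed_line")
  expect_error(parse_gen_line("1 snp1 rs1 1000 A G 0.5 0.5", d, 1),
               class = "dosevcf_malformed_line")
  expect_error(parse_gen_line("1 snp1 rs1 -5 A G 1 0 0", d, 1),
               class = "dosevcf_malformed_line")
  expect_error(parse_gen_line("1 snp1 rs1 x A G 1 0 0", d, 1),
               class = "dosevcf_malformed_line")
})

test_that("out-of-range probabilities error in strict mode, clamp in lenient", {
  d <- detect_dialect(9)
  strict <- conversion_config(strict = TRUE)
  lenient <- conversion_config(strict = FALSE)

  expect_error(parse_gen_line("1 s r 10 A G -0.1 0.5 0.6", d, 1, 1, strict),
               class = "dosevcf_malformed_line")
  expect_error(parse_gen_line("1 s r 10 A G 0 0 1.5", d, 1, 1, strict),
               class = "dosevcf_malformed_line")

  rec <- parse_gen_line("1 s r 10 A G -0.1 0.5 1.5", d, 1, 1, lenient)
  expect_equal(unname(rec$probs[1, ]), c(0, 0.5, 1))
  expect_equal(rec$n_clamped_probs, 2L)

  # within the rounding tolerance of 1: accepted in strict mode too
  rec2 <- parse_gen_line("1 s r 10 A G 0 0 1.0000005", d, 1, 1, strict)
  expect_equal(unname(rec2$probs[1, ]), c(0, 0, 1))
})

test_that("streaming yields records in order and conserves line count", {
  lines <- c("1 s1 r1 100 A G 1 0 0",
             "1 s2 r2 200 A C 0 1 0",
             "1 s3 r3 300 G T 0 0 1")
  s <- gen_stream(write_tmp(lines))
  recs <- list()
  while (!is.null(r <- s$read_next())) recs[[length(recs) + 1L]] <- r
  s$close()
  expect_length(recs, 3L)
  expect_equal(vapply(recs, `[[`, 0, "pos"), c(100, 200, 300))
  expect_equal(vapply(recs, `[[`, 0L, "line_number"), 1:3)
})

test_that("empty input and blank lines stream without error", {
  s <- gen_stream(write_tmp(character(0)))
  expect_null(s$read_next())
  s$close()

  s2 <- gen_stream(write_tmp(c("", "1 s1 r1 100 A G 1 0 0", "  ", "")))
  expect_equal(s2$read_next()$varid, "s1")
  expect_null(s2$read_next())
  expect_equal(s2$stats()$blank_lines, 3L)
  s2$close()
})

test_that("lenient streaming skips and counts malformed lines; strict aborts", {
  lines <- c("1 s1 r1 100 A G 1 0 0",
             "1 s2 r2 200 A C 0 1",      # truncated
             "1 s3 r3 300 G T 0 0 1")
  f <- write_tmp(lines)

  s <- gen_stream(f, conversion_config(strict = FALSE))
  recs <- list()
  while (!is.null(r <- s$read_next())) recs[[length(recs) + 1L]] <- r
  expect_length(recs, 2L)
  expect_equal(s$stats()$malformed_lines, 1L)
  s$close()

  s2 <- gen_stream(f, conversion_config(strict = TRUE))
  expect_equal(s2$read_next()$varid, "s1")
  expect_error(s2$read_next(), "line 2", class = "dosevcf_malformed_line")
  s2$close()
})

test_that("the dialect of the first line is enforced for the rest of the file", {
  f <- write_tmp(c("1 s1 r1 100 A G 1 0 0",        # 6-col, N=1
                   "s2 r2 200 A C 0 1 0"))          # 5-col width
  s <- gen_stream(f)
  s$read_next()
  expect_error(s$read_next(), class = "dosevcf_malformed_line")
  s$close()
})

test_that("gzip-compressed GEN input parses identically to plain text", {
  lines <- c("1 s1 r1 100 A G 0.1 0.2 0.7")
  gz <- tempfile(fileext = ".gen.gz")
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  s <- gen_stream(gz)
  rec <- s$read_next()
  s$close()
  expect_equal(unname(rec$probs[1, ]), c(0.1, 0.2, 0.7))
})

test_that("parsed probabilities re-serialize to the original tokens", {
  fx <- generate_gen_fixture(20, 5, seed = 11)
  s <- gen_stream(fx$gen)
  i <- 0L
  while (!is.null(rec <- s$read_next())) {
    i <- i + 1L
    toks <- strsplit(readLines(fx$gen)[i], " ")[[1]][-(1:6)]
    expect_identical(format_float(as.vector(t(rec$probs)), 3), toks)
  }
  s$close()
})

test_that("the Oxford sample file yields one row per sample, in order", {
  f <- write_tmp(c("ID_1 ID_2 missing sex", "0 0 0 D",
                   "fam1 ind1 0.01 M", "fam2 ind2 0 F"), ".sample")
  si <- read_sample_file(f)
  expect_equal(nrow(si), 2L)
  expect_equal(si$id_1, c("fam1", "fam2"))
  expect_equal(si$id_2, c("ind1", "ind2"))
  expect_equal(si$missing, c("0.01", "0"))   # passed through, not parsed
  expect_equal(si$extra_1, c("M", "F"))
})

test_that("degenerate sample files are handled per the two-header convention", {
  empty <- read_sample_file(write_tmp(c("ID_1 ID_2 missing", "0 0 0"),
                                      ".sample"))
  expect_equal(nrow(empty), 0L)

  expect_error(read_sample_file(write_tmp("ID_1 ID_2 missing", ".sample")),
               class = "dosevcf_malformed_sample_file")
  expect_error(
    read_sample_file(write_tmp(c("ID_1 ID_2 missing", "0 0 0", "fam1 ind1"),
                               ".sample")),
    class = "dosevcf_malformed_sample_file")
})
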