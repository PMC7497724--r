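#' Detect the GEN column dialect from a line's token count
#'
#' GEN files come in two common layouts: five leading metadata columns
#' (varid, rsid, pos, alleleA, alleleB) or six (a chromosome column
#' first). With three probabilities per diploid sample, the token count
#' mod 3 identifies the layout uniquely: 5 + 3N is 2 (mod 3) and
#' 6 + 3N is 0 (mod 3); a count of 1 (mod 3) fits neither.
#'
#' @param token_count Number of whitespace-separated tokens on the line;
#'   must be at least 8 (five metadata columns plus one sample).
#' @param declared_samples Optional known sample count; when given, the
#'   token count must equal `leading_columns + 3 * declared_samples`.
#' @return A list of class `"gen_dialect"` with `leading_columns`
#'   (5 or 6), `has_chrom_column`, and `n_samples` implied by the count.
#' @examples
#' detect_dialect(11) # 5-column, 2 samples
#' detect_dialect(12) # 6-column, 2 samples
#' @export
detect_dialect <- function(token_count, declared_samples = NULL) {
  token_count <- as.integer(token_count)
  if (length(token_count) != 1L || is.na(token_count) || token_count < 8L) {
    malformed_line(sprintf(
      "too few columns (%s) for a GEN line: need at least 5 metadata columns plus 3 probabilities",
      paste(token_count, collapse = ",")
    ))
  }
  rem <- token_count %% 3L
  if (rem == 1L) {
    malformed_line(sprintf(
      "column count %d fits neither the 5- nor the 6-leading-column GEN layout",
      token_count
    ))
  }
  leading <- if (rem == 2L) 5L else 6L
  n <- (token_count - leading) %/% 3L
  if (!is.null(declared_samples)) {
    declared_samples <- as.integer(declared_samples)
    if (n != declared_samples) {
      malformed_line(sprintf(
        "column count %d implies %d samples in the %d-column layout, but %d samples were declared",
        token_count, n, leading, declared_samples
      ))
    }
  }
  structure(
    list(
      leading_columns = leading,
      has_chrom_column = leading == 6L,
      n_samples = n
    ),
    class = "gen_dialect"
  )
}

gen_dialect <- function(leading_columns) {
  leading_columns <- as.integer(leading_columns)
  stopifnot(leading_columns %in% c(5L, 6L))
  structure(
    list(
      leading_columns = leading_columns,
      has_chrom_column = leading_columns == 6L,
      n_samples = NA_integer_
    ),
    class = "gen_dialect"
  )
}

#' Parse one GEN line into a record
#'
#' Maps the leading metadata columns positionally (6-column layout:
#' chrom, varid, rsid, pos, alleleA, alleleB; 5-column layout the same
#' without chrom) and parses the remaining `3 * expected_samples` tokens
#' as genotype probabilities. Allele A becomes the VCF REF allele and
#' allele B the ALT allele.
#'
#' In strict mode any probability outside \[0, 1 + prob_eps\] aborts; in
#' lenient mode negative values are clamped to 0 and values in
#' (1, 1 + prob_eps\] to 1, and the number of clamped values is recorded
#' in the `n_clamped_probs` field of the result.
#'
#' @param line A single line of GEN text.
#' @param dialect A `"gen_dialect"`, e.g. from [detect_dialect()].
#' @param expected_samples Number of samples the line must carry.
#' @param line_number 1-based line number, used in error messages.
#' @param config A [conversion_config()] (strict flag and tolerances).
#' @return A list of class `"gen_record"`: `chrom` (NA for the 5-column
#'   layout), `varid`, `rsid`, `pos`, `allele_a`, `allele_b`, `probs`
#'   (an `expected_samples` x 3 matrix with columns p_aa, p_ab, p_bb),
#'   `line_number`, `n_clamped_probs`.
#' @examples
#' rec <- parse_gen_line("1 snp1 rs1 1000 A G 0 1 0", detect_dialect(9), 1)
#' rec$probs
#' @export
parse_gen_line <- function(line, dialect, expected_samples,
                           line_number = 1L,
                           config = conversion_config()) {
  config <- as_conversion_config(config)
  tokens <- strsplit(trimws(line), "[ \t]+")[[1L]]
  expected_samples <- as.integer(expected_samples)
  stopifnot(expected_samples >= 1L)
  lead <- dialect$leading_columns
  want <- lead + 3L * expected_samples
  if (length(tokens) != want) {
    malformed_line(sprintf(
      "expected %d columns (%d metadata + 3 x %d samples), found %d",
      want, lead, expected_samples, length(tokens)
    ), line_number)
  }
  meta <- tokens[seq_len(lead)]
  if (dialect$has_chrom_column) {
    chrom <- meta[1L]
    meta <- meta[-1L]
  } else {
    chrom <- NA_character_
  }
  pos_tok <- meta[3L]
  if (!grepl("^[0-9]+$", pos_tok) || as.numeric(pos_tok) < 1) {
    malformed_line(sprintf("position '%s' is not a positive integer", pos_tok),
                   line_number)
  }
  allele_a <- meta[4L]
  allele_b <- meta[5L]
  if (!nzchar(allele_a) || !nzchar(allele_b)) {
    malformed_line("empty allele column", line_number)
  }
  p <- suppressWarnings(as.numeric(tokens[(lead + 1L):length(tokens)]))
  bad <- which(is.na(p))
  if (length(bad)) {
    malformed_line(sprintf(
      "non-numeric probability token '%s' (sample %d)",
      tokens[lead + bad[1L]], (bad[1L] - 1L) %/% 3L + 1L
    ), line_number)
  }
  n_clamped <- 0L
  lo <- p < 0
  hi <- p > 1 + config$prob_eps
  slight_hi <- p > 1 & !hi
  if (any(lo) || any(hi)) {
    if (config$strict) {
      i <- which(lo | hi)[1L]
      malformed_line(sprintf(
        "probability %.6g out of [0, 1] (sample %d)", p[i], (i - 1L) %/% 3L + 1L
      ), line_number)
    }
    n_clamped <- sum(lo) + sum(hi)
    p[lo] <- 0
    p[hi] <- 1
  }
  if (any(slight_hi)) {
    # within tolerance of 1: always clamped (rounding noise); counted
    # only in lenient mode, where clamps are reported
    p[slight_hi] <- 1
    if (!config$strict) n_clamped <- n_clamped + sum(slight_hi)
  }
  probs <- matrix(p, ncol = 3L, byrow = TRUE,
                  dimnames = list(NULL, c("p_aa", "p_ab", "p_bb")))
  structure(
    list(
      chrom = chrom,
      varid = meta[1L],
      rsid = meta[2L],
      pos = as.numeric(pos_tok),
      allele_a = allele_a,
      allele_b = allele_b,
      probs = probs,
      line_number = as.integer(line_number),
      n_clamped_probs = n_clamped
    ),
    class = "gen_record"
  )
}

open_gen_source <- function(source) {
  if (inherits(source, "connection")) {
    return(list(con = source, own = FALSE))
  }
  stopifnot(is.character(source), length(source) == 1L)
  if (source == "-") {
    return(list(con = file("stdin", open = "r"), own = TRUE))
  }
  if (!file.exists(source)) {
    dv_error("dosevcf_io_error", sprintf("cannot open '%s': no such file", source))
  }
  con <- if (grepl("\\.gz$", source)) gzfile(source, open = "r")
         else file(source, open = "r")
  list(con = con, own = TRUE)
}

#' Stream a GEN file record by record
#'
#' Opens a GEN source (path, gzip-compressed path, `"-"` for standard
#' input, or an open connection) and returns a reader object whose
#' `$read_next()` yields one parsed [gen_record][parse_gen_line] at a
#' time, in file order, holding only a bounded buffer of lines in
#' memory. The dialect is detected from the first non-empty line and
#' enforced for all subsequent lines. Blank lines are skipped and
#' counted. In lenient mode (`strict = FALSE` in the config) malformed
#' lines are skipped and counted instead of aborting.
#'
#' @param source Path, `"-"`, or connection.
#' @param config A [conversion_config()].
#' @param n_samples Declared sample count (e.g. from the sample file);
#'   if `NULL`, inferred from the first data line.
#' @param chunk_lines Number of lines buffered per read; memory use is
#'   proportional to this constant, never to the file length.
#' @return An object of class `"gen_stream"` with functions
#'   `read_next()` (a `gen_record`, or `NULL` at end of input),
#'   `dialect()`, `n_samples()`, `stats()` (blank/malformed/clamped
#'   counters), and `close()`.
#' @examples
#' f <- tempfile(fileext = ".gen")
#' writeLines("1 snp1 rs1 1000 A G 0 1 0", f)
#' s <- gen_stream(f)
#' rec <- s$read_next()
#' s$close()
#' @export
gen_stream <- function(source, config = conversion_config(),
                       n_samples = NULL, chunk_lines = 500L) {
  config <- as_conversion_config(config)
  src <- open_gen_source(source)
  con <- src$con

  buffer <- character(0)
  buf_pos <- 0L
  line_no <- 0L
  dialect <- NULL
  n <- if (is.null(n_samples)) NA_integer_ else as.integer(n_samples)
  counters <- list(blank_lines = 0L, malformed_lines = 0L,
                   clamped_probs = 0L)
  done <- FALSE

  next_line <- function() {
    if (buf_pos >= length(buffer)) {
      if (done) return(NULL)
      buffer <<- readLines(con, n = chunk_lines, warn = FALSE)
      buf_pos <<- 0L
      if (length(buffer) == 0L) {
        done <<- TRUE
        return(NULL)
      }
    }
    buf_pos <<- buf_pos + 1L
    line_no <<- line_no + 1L
    buffer[[buf_pos]]
  }

  read_next <- function() {
    repeat {
      line <- next_line()
      if (is.null(line)) return(NULL)
      if (!nzchar(trimws(line))) {
        counters$blank_lines <<- counters$blank_lines + 1L
        next
      }
      if (is.null(dialect)) {
        ntok <- length(strsplit(trimws(line), "[ \t]+")[[1L]])
        dialect <<- detect_dialect(ntok, if (is.na(n)) NULL else n)
        if (is.na(n)) n <<- dialect$n_samples
      }
      rec <- if (config$strict) {
        parse_gen_line(line, dialect, n, line_no, config)
      } else {
        tryCatch(
          parse_gen_line(line, dialect, n, line_no, config),
          dosevcf_malformed_line = function(e) {
            counters$malformed_lines <<- counters$malformed_lines + 1L
            NULL
          }
        )
      }
      if (is.null(rec)) next
      counters$clamped_probs <<- counters$clamped_probs + rec$n_clamped_probs
      return(rec)
    }
  }

  structure(
    list(
      read_next = read_next,
      dialect = function() dialect,
      n_samples = function() n,
      stats = function() counters,
      close = function() if (src$own) close(con) else invisible(NULL)
    ),
    class = "gen_stream"
  )
}

#' Read an Oxford sample file
#'
#' The companion metadata file of GEN/BGEN data: a header line (first
#' three columns conventionally `ID_1 ID_2 missing`), a column-type line
#' (`0 0 0` ...), then one row per sample. The number of data rows
#' defines the sample count of the GEN file.
#'
#' @param path Path to the sample file.
#' @return A data frame of class `"sample_info"` with columns `id_1`,
#'   `id_2`, `missing` (passed through untouched) and any extra columns
#'   as `extra_1`, `extra_2`, ...; zero rows if the file holds only the
#'   two header lines.
#' @export
read_sample_file <- function(path) {
  if (!file.exists(path)) {
    dv_error("dosevcf_io_error",
             sprintf("cannot open sample file '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    malformed_sample_file(
      "sample file must have a header line and a column-type line")
  }
  rows <- lines[-(1:2)]
  if (length(rows) == 0L) {
    out <- data.frame(id_1 = character(0), id_2 = character(0),
                      missing = character(0), stringsAsFactors = FALSE)
    class(out) <- c("sample_info", class(out))
    return(out)
  }
  toks <- strsplit(trimws(rows), "[ \t]+")
  ncols <- lengths(toks)
  if (any(ncols < 3L)) {
    malformed_sample_file(sprintf(
      "sample row %d has %d columns; at least 3 (ID_1, ID_2, missing) required",
      which(ncols < 3L)[1L], min(ncols)
    ))
  }
  id_1 <- vapply(toks, `[[`, "", 1L)
  id_2 <- vapply(toks, `[[`, "", 2L)
  if (any(!nzchar(id_1)) || any(!nzchar(id_2))) {
    malformed_sample_file("empty sample identifier")
  }
  out <- data.frame(id_1 = id_1, id_2 = id_2,
                    missing = vapply(toks, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  extra <- max(ncols) - 3L
  if (extra > 0L) {
    for (j in seq_len(extra)) {
      out[[paste0("extra_", j)]] <-
        vapply(toks, function(t) if (length(t) >= 3L + j) t[[3L + j]]
               else NA_character_, "")
    }
  }
  class(out) <- c("sample_info", class(out))
  out
}
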