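#' Fixed-precision decimal formatting
#'
#' Renders numbers with exactly `precision` digits after the decimal
#' point — never exponent notation, never trimmed zeros — using the C
#' library's correctly-rounded conversion (round-half-to-even on the
#' underlying binary value). This is the formatter used for every GP
#' and DS field, so a value re-parsed from the VCF is within half a
#' unit in the last printed decimal of the exact value.
#'
#' @param x Finite numeric vector.
#' @param precision Integer in \[1, 10\].
#' @return Character vector, same length as `x`.
#' @examples
#' format_float(1.6, 3)   # "1.600"
#' format_float(2/3, 3)   # "0.667"
#' @export
format_float <- function(x, precision = 3L) {
  precision <- as.integer(precision)
  stopifnot(length(precision) == 1L, precision >= 1L, precision <= 10L,
            is.numeric(x), all(is.finite(x)))
  sprintf("%.*f", precision, x)
}

#' Build a VCF header
#'
#' Emits, in order: the `##fileformat=VCFv4.2` line; the three FORMAT
#' declarations for GT (Number=1, String), GP (Number=G, Float — the
#' genotype-ordered probabilities P(0/0), P(0/1), P(1/1)) and DS
#' (Number=1, Float); a `##source` line; optionally a `##fileDate`
#' line and `##contig` lines; then the `#CHROM ... FORMAT` column line
#' followed by the sample IDs in input order.
#'
#' @param sample_ids Character vector of unique sample identifiers
#'   (at least one).
#' @param source_label Text for the `##source` line.
#' @param file_date `NULL` to omit the date line (reproducible output),
#'   or a string such as `format(Sys.Date(), "%Y%m%d")`.
#' @param contigs Optional character vector of contig names to declare.
#' @return Character vector of header lines.
#' @export
vcf_header <- function(sample_ids,
                       source_label = paste0("dosevcf-", dosevcf_version()),
                       file_date = NULL,
                       contigs = NULL) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 1L) {
    stop("a VCF with genotype columns needs at least one sample", call. = FALSE)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) {
    dv_error("dosevcf_duplicate_sample_id",
             sprintf("duplicate sample id(s): %s",
                     paste(utils::head(dup, 3L), collapse = ", ")))
  }
  c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype (maximum posterior probability)\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities P(0/0),P(0/1),P(1/1)\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed ALT allele dosage: P(0/1) + 2*P(1/1), range [0,2]\">",
    sprintf("##source=%s", source_label),
    if (!is.null(file_date)) sprintf("##fileDate=%s", file_date),
    if (!is.null(contigs)) sprintf("##contig=<ID=%s>", contigs),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
}

dosevcf_version <- function() {
  as.character(utils::packageVersion("dosevcf"))
}

vcf_id <- function(rec, id_policy) {
  blank <- function(x) is.na(x) | !nzchar(x) | x == "."
  switch(id_policy,
    rsid = if (blank(rec$rsid)) "." else rec$rsid,
    varid = if (blank(rec$varid)) "." else rec$varid,
    auto = {
      if (!blank(rec$rsid)) rec$rsid
      else if (!blank(rec$varid)) rec$varid
      else sprintf("%s:%s_%s_%s", rec$chrom, format_pos(rec$pos),
                   rec$allele_a, rec$allele_b)
    }
  )
}

format_pos <- function(pos) sprintf("%.0f", pos)

#' Render one VCF data line
#'
#' Composes the 9 fixed columns and one `GT:GP:DS` field per sample.
#' Allele A is written as REF and allele B as ALT; QUAL, FILTER and
#' INFO carry no information in GEN and are emitted as `.`. A missing
#' genotype renders as `./.:.:.`; a genotype blanked by the hard-call
#' threshold keeps its GP and DS (`./.:<gp>:<ds>`).
#'
#' @param rec A [gen_record][parse_gen_line] whose `chrom` is resolved
#'   (non-missing).
#' @param cg The matching [compute_genotype()] result.
#' @param config A [conversion_config()] (precision, id policy).
#' @return A single tab-separated VCF line (no trailing newline).
#' @export
render_record <- function(rec, cg, config = conversion_config()) {
  config <- as_conversion_config(config)
  if (is.na(rec$chrom) || !nzchar(rec$chrom)) {
    dv_error("dosevcf_unresolved_chromosome", sprintf(
      "record at line %d has no chromosome; 5-column GEN input needs a chromosome override",
      rec$line_number
    ))
  }
  n <- length(cg$gt)
  stopifnot(n == nrow(rec$probs))
  fields <- character(n)
  live <- !cg$missing
  if (any(live)) {
    fm <- format_float(cg$gp[live, , drop = FALSE], config$precision)
    dim(fm) <- c(sum(live), 3L)
    fields[live] <- paste0(
      gt_string(cg$gt[live]), ":",
      fm[, 1L], ",", fm[, 2L], ",", fm[, 3L], ":",
      format_float(cg$ds[live], config$precision)
    )
  }
  fields[!live] <- "./.:.:."
  paste(c(rec$chrom, format_pos(rec$pos), vcf_id(rec, config$id_policy),
          rec$allele_a, rec$allele_b, ".", ".", ".", "GT:GP:DS", fields),
        collapse = "\t")
}

#' Write a VCF record stream to a destination
#'
#' Writes the header and then records one at a time (bounded memory).
#' For file destinations ending in `.gz` (or when `compress = TRUE`)
#' the output is BGZF-compressed via Rsamtools, and — if the records
#' arrived coordinate-sorted — a tabix index is built. `"-"` writes
#' plain text to standard output. Indexing of an unsorted stream is
#' refused with a warning; the conversion itself still succeeds.
#'
#' @param header Character vector of header lines ([vcf_header()]).
#' @param record_stream A function returning, per call, either `NULL`
#'   (end of stream) or a list with `line` (rendered VCF line), `chrom`
#'   and `pos` (for the sortedness check).
#' @param destination Output path or `"-"`.
#' @param compress `NA` (default): BGZF iff the path ends `.gz`;
#'   otherwise a logical. Ignored (plain text) for `"-"`.
#' @param index Build a tabix index (only for compressed, sorted file
#'   output).
#' @return A list with `records` written, `sorted`, and `index_path`
#'   (`NA` if no index was built).
#' @export
write_vcf <- function(header, record_stream, destination,
                      compress = NA, index = TRUE) {
  to_stdout <- identical(destination, "-")
  if (to_stdout) {
    compress <- FALSE
  } else if (is.na(compress)) {
    compress <- grepl("\\.gz$", destination)
  }

  # records are staged as plain text; BGZF compression is applied to the
  # finished stream so memory stays bounded by the write buffer
  plain_path <- if (to_stdout) {
    NULL
  } else if (compress) {
    tempfile(fileext = ".vcf")
  } else {
    destination
  }
  con <- if (to_stdout) stdout() else {
    tryCatch(file(plain_path, open = "w"),
             error = function(e) dv_error("dosevcf_io_error", conditionMessage(e)))
  }
  ok <- FALSE
  on.exit({
    if (!to_stdout) {
      close(con)
      if (!ok && compress) unlink(plain_path)
    }
  })

  writeLines(header, con)
  n <- 0L
  sorted <- TRUE
  last_chrom <- NA_character_
  last_pos <- -Inf
  seen_chroms <- character(0)
  buf <- character(0)
  flush_at <- 256L
  repeat {
    item <- record_stream()
    if (is.null(item)) break
    n <- n + 1L
    if (!identical(item$chrom, last_chrom)) {
      if (item$chrom %in% seen_chroms) sorted <- FALSE
      seen_chroms <- c(seen_chroms, item$chrom)
      last_chrom <- item$chrom
      last_pos <- -Inf
    }
    if (item$pos < last_pos) sorted <- FALSE
    last_pos <- item$pos
    buf[length(buf) + 1L] <- item$line
    if (length(buf) >= flush_at) {
      writeLines(buf, con)
      buf <- character(0)
    }
  }
  if (length(buf)) writeLines(buf, con)
  if (!to_stdout) {
    close(con)
    on.exit()
  }

  index_path <- NA_character_
  if (!to_stdout && compress) {
    Rsamtools::bgzip(plain_path, dest = destination, overwrite = TRUE)
    unlink(plain_path)
    if (index) {
      if (!sorted) {
        warning(paste("records are not coordinate-sorted;",
                      "tabix indexing refused (output written unindexed)"),
                call. = FALSE)
      } else if (n > 0L) {
        index_path <- Rsamtools::indexTabix(destination, format = "vcf")
      }
    }
  }
  ok <- TRUE
  list(records = n, sorted = sorted, index_path = index_path)
}
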