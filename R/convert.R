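#' Convert a GEN file to VCF with GT, GP and DS
#'
#' The single-pass driver: streams GEN records ([gen_stream()]), derives
#' each sample's best-guess genotype, genotype probabilities and dosage
#' ([compute_genotype()]), and writes a VCF 4.2 with FORMAT `GT:GP:DS`
#' ([write_vcf()]), BGZF-compressed and tabix-indexed when the
#' destination is a `.gz` path. Memory use is bounded by a constant
#' number of lines regardless of the number of variants, so the
#' converter works in shell pipelines (`gen = "-"`, `out = "-"`).
#'
#' @param gen GEN input: a path (plain or `.gz`), `"-"` for standard
#'   input, or an open connection.
#' @param out Output path (`.vcf` plain, `.vcf.gz` BGZF-compressed) or
#'   `"-"` for plain text on standard output.
#' @param sample_file Optional Oxford sample file; supplies the sample
#'   count and the VCF header IDs. Without it, IDs `sample_1..N` are
#'   synthesized from the first data line's width.
#' @param chrom Chromosome override: required for 5-column GEN input
#'   (which carries no chromosome), takes precedence for 6-column input.
#' @param id_column Which sample-file column becomes the VCF sample ID:
#'   `"id_2"` (default), `"id_1"`, or `"both"` (`id_1_id_2`).
#' @param config A [conversion_config()]; the remaining arguments are
#'   shorthands that override its fields.
#' @param precision,gt_threshold,renormalize,strict,id_policy See
#'   [conversion_config()].
#' @param compress `NA`: decide from the output suffix.
#' @param index Build a tabix index for sorted compressed output.
#' @param no_date Omit the `##fileDate` header line (byte-reproducible
#'   output).
#' @return (Invisibly) a `"conversion_stats"` object: records and
#'   samples written, missing genotypes, clamped dosages and
#'   probabilities, malformed and blank lines skipped.
#' @examples
#' fx <- generate_gen_fixture(n_variants = 5, n_samples = 3, seed = 1)
#' out <- tempfile(fileext = ".vcf")
#' stats <- gen_to_vcf(fx$gen, out, sample_file = fx$sample)
#' stats
#' @export
gen_to_vcf <- function(gen, out,
                       sample_file = NULL,
                       chrom = NULL,
                       id_column = c("id_2", "id_1", "both"),
                       config = conversion_config(),
                       precision = NULL, gt_threshold = NULL,
                       renormalize = NULL, strict = NULL, id_policy = NULL,
                       compress = NA, index = TRUE, no_date = FALSE) {
  id_column <- match.arg(id_column)
  config <- as_conversion_config(config)
  for (f in c("precision", "gt_threshold", "renormalize", "strict",
              "id_policy")) {
    v <- get(f)
    if (!is.null(v)) config[[f]] <- v
  }
  config <- as_conversion_config(unclass(config))

  sample_ids <- NULL
  n_samples <- NULL
  if (!is.null(sample_file)) {
    si <- read_sample_file(sample_file)
    n_samples <- nrow(si)
    sample_ids <- switch(id_column,
      id_2 = si$id_2,
      id_1 = si$id_1,
      both = paste(si$id_1, si$id_2, sep = "_"))
  }

  stream <- gen_stream(gen, config, n_samples = n_samples)
  on.exit(stream$close())

  first <- stream$read_next()
  if (is.null(first)) {
    # empty input: a header-only VCF; without a sample file the sample
    # count is unknowable, so emit a sites-only header (8 fixed columns)
    header <- if (is.null(sample_ids) || length(sample_ids) == 0L) {
      c("##fileformat=VCFv4.2",
        sprintf("##source=dosevcf-%s", dosevcf_version()),
        if (!no_date) sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")),
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO"), collapse = "\t"))
    } else {
      vcf_header(sample_ids,
                 file_date = if (no_date) NULL else format(Sys.Date(), "%Y%m%d"))
    }
    res <- write_vcf(header, function() NULL, out,
                     compress = compress, index = index)
    return(invisible(new_conversion_stats(stream, res, 0L,
                                          length(sample_ids), 0L, 0L)))
  }

  dialect <- stream$dialect()
  if (!dialect$has_chrom_column && is.null(chrom)) {
    dv_error("dosevcf_chrom_required", paste(
      "5-column GEN input carries no chromosome;",
      "supply one with `chrom` (CLI: --chr)"))
  }
  n <- stream$n_samples()
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(n))
  if (length(sample_ids) != n) {
    malformed_line(sprintf(
      "sample file declares %d samples but the GEN line carries %d",
      length(sample_ids), n), first$line_number)
  }

  header <- vcf_header(
    sample_ids,
    file_date = if (no_date) NULL else format(Sys.Date(), "%Y%m%d"))

  n_missing <- 0L
  n_clamped_ds <- 0L
  pending <- first
  record_stream <- function() {
    rec <- pending
    if (is.null(rec)) rec <- stream$read_next()
    pending <<- NULL
    if (is.null(rec)) return(NULL)
    if (!is.null(chrom)) rec$chrom <- chrom
    cg <- compute_genotype(rec$probs, config)
    n_missing <<- n_missing + sum(cg$missing)
    n_clamped_ds <<- n_clamped_ds + cg$n_clamped_ds
    list(line = render_record(rec, cg, config),
         chrom = rec$chrom, pos = rec$pos)
  }

  res <- write_vcf(header, record_stream, out,
                   compress = compress, index = index)
  invisible(new_conversion_stats(stream, res, res$records, n,
                                 n_missing, n_clamped_ds))
}

new_conversion_stats <- function(stream, res, records, samples,
                                 n_missing, n_clamped_ds) {
  cs <- stream$stats()
  structure(
    list(
      records = records,
      samples = samples,
      missing_genotypes = n_missing,
      clamped_dosages = n_clamped_ds,
      clamped_probs = cs$clamped_probs,
      malformed_lines = cs$malformed_lines,
      blank_lines = cs$blank_lines,
      sorted = res$sorted,
      index_path = res$index_path
    ),
    class = "conversion_stats"
  )
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat(sprintf("GEN -> VCF conversion: %d record(s), %d sample(s)\n",
              x$records, x$samples))
  cat(sprintf("  missing genotypes : %d\n", x$missing_genotypes))
  cat(sprintf("  clamped dosages   : %d\n", x$clamped_dosages))
  cat(sprintf("  clamped probs     : %d\n", x$clamped_probs))
  cat(sprintf("  malformed lines   : %d\n", x$malformed_lines))
  cat(sprintf("  blank lines       : %d\n", x$blank_lines))
  if (!is.na(x$index_path)) cat(sprintf("  tabix index       : %s\n",
                                        x$index_path))
  invisible(x)
}
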