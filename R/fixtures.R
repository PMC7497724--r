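#' Generate a seeded GEN + sample fixture with a truth table
#'
#' Emulates IMPUTE output for testing: per sample and variant a
#' genotype-probability triple is drawn from the symmetric (flat)
#' Dirichlet distribution on the 2-simplex and rounded to
#' `prob_decimals` places — so, as in real files, the written triples
#' need not sum to exactly 1. A `missing_rate` fraction of genotypes is
#' written as `0 0 0`. Positions are strictly increasing. The truth
#' table holds, for every (variant, sample) pair, the as-written
#' probabilities and the dosage and best-guess genotype they imply —
#' computed from the rounded values, since those are all a converter
#' can see. Identical spec and seed give byte-identical files.
#'
#' @param n_variants Number of variants (lines) to write.
#' @param n_samples Number of diploid samples per line.
#' @param seed RNG seed; the caller's RNG state is restored on exit.
#' @param missing_rate Fraction of genotypes written as `0 0 0`.
#' @param leading_columns 6 (chromosome column first, default) or 5.
#' @param prob_decimals Decimal places of the written probabilities.
#' @param chrom Chromosome label (used in the 6-column layout).
#' @param dir Directory to write into (created if needed).
#' @return A list of class `"gen_fixture"`: paths `gen`, `sample`,
#'   `truth` (a data frame: `variant`, `sample`, `pos`, `p_aa`, `p_ab`,
#'   `p_bb`, `ds`, `gt`, `missing`), and the generating parameters.
#' @examples
#' fx <- generate_gen_fixture(n_variants = 3, n_samples = 2, seed = 42)
#' readLines(fx$gen)
#' @export
generate_gen_fixture <- function(n_variants, n_samples, seed = 1L,
                                 missing_rate = 0,
                                 leading_columns = 6L,
                                 prob_decimals = 3L,
                                 chrom = "1",
                                 dir = tempfile("genfix")) {
  stopifnot(n_variants >= 0L, n_samples >= 1L,
            missing_rate >= 0, missing_rate <= 1,
            leading_columns %in% c(5L, 6L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  pos <- 1000L + cumsum(sample.int(200L, n_variants, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n_variants, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, n_variants, replace = TRUE)) %% 4L) + 1L
  rsid <- sprintf("rs%06d", seq_len(n_variants))
  rsid[seq_len(n_variants) %% 7L == 0L] <- "."  # exercise the ID fallback

  g <- matrix(stats::rgamma(3L * n_variants * n_samples, shape = 1),
              ncol = 3L)
  p <- round(g / rowSums(g), prob_decimals)
  miss <- stats::runif(n_variants * n_samples) < missing_rate
  p[miss, ] <- 0

  fmt <- sprintf("%%.%df", prob_decimals)
  gen_path <- file.path(dir, "fixture.gen")
  lines <- character(n_variants)
  if (n_variants > 0L) {
    ptxt <- matrix(sprintf(fmt, t(p)), nrow = 3L * n_samples)
  }
  for (i in seq_len(n_variants)) {
    meta <- c(if (leading_columns == 6L) chrom,
              sprintf("snp%06d", i), rsid[i], pos[i],
              bases[ref_i[i]], bases[alt_i[i]])
    lines[i] <- paste(c(meta, ptxt[, i]), collapse = " ")
  }
  writeLines(lines, gen_path)

  sample_path <- file.path(dir, "fixture.sample")
  writeLines(c(
    "ID_1 ID_2 missing",
    "0 0 0",
    sprintf("fam%04d ind%04d 0", seq_len(n_samples), seq_len(n_samples))
  ), sample_path)

  cfg <- conversion_config(missing_eps = 1e-6)
  # truth rows are variant-major, matching the row order of p
  is_miss <- classify_missing(p, cfg$missing_eps)
  truth <- data.frame(
    variant = rep(seq_len(n_variants), each = n_samples),
    sample = rep(seq_len(n_samples), times = n_variants),
    pos = rep(pos, each = n_samples),
    p_aa = p[, 1L], p_ab = p[, 2L], p_bb = p[, 3L],
    ds = ifelse(is_miss, NA_real_, dosage(p)),
    gt = ifelse(is_miss, "missing", best_guess(p)),
    missing = is_miss,
    stringsAsFactors = FALSE
  )

  structure(
    list(gen = gen_path, sample = sample_path, truth = truth,
         n_variants = n_variants, n_samples = n_samples, seed = seed,
         missing_rate = missing_rate, leading_columns = leading_columns,
         prob_decimals = prob_decimals, chrom = chrom),
    class = "gen_fixture"
  )
}

#' Naive in-memory reference conversion
#'
#' A deliberately simple whole-file-in-memory implementation of the
#' same GEN-to-VCF conversion, written independently of the streaming
#' path and used only as a test oracle: it reads every line, loops over
#' samples with scalar arithmetic, and returns the full VCF as a
#' character vector (no date line, so its output matches the streaming
#' converter run with `no_date = TRUE`).
#'
#' @param gen_path Path to a GEN file (plain text).
#' @param sample_path Optional Oxford sample file path.
#' @param chrom Chromosome override (required for 5-column input).
#' @param id_column Sample-file column used for VCF sample IDs.
#' @param config A [conversion_config()].
#' @return Character vector of VCF lines (header + records).
#' @export
oracle_convert <- function(gen_path, sample_path = NULL, chrom = NULL,
                           id_column = c("id_2", "id_1", "both"),
                           config = conversion_config()) {
  id_column <- match.arg(id_column)
  config <- as_conversion_config(config)
  prec <- config$precision
  num <- function(x) sprintf("%.*f", prec, x)

  lines <- readLines(gen_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  ids <- NULL
  if (!is.null(sample_path)) {
    sl <- readLines(sample_path, warn = FALSE)
    sl <- sl[nzchar(trimws(sl))][-(1:2)]
    parts <- strsplit(trimws(sl), "[ \t]+")
    ids <- vapply(parts, function(t) switch(id_column,
      id_2 = t[[2L]], id_1 = t[[1L]],
      both = paste(t[[1L]], t[[2L]], sep = "_")), "")
  }

  out <- character(0)
  for (li in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[li]]), "[ \t]+")[[1L]]
    six <- length(toks) %% 3L == 0L
    lead <- if (six) 6L else 5L
    m <- if (six) toks[2:6] else toks[1:5]
    ch <- if (!is.null(chrom)) chrom else if (six) toks[1L] else
      stop("oracle: chromosome unresolved")
    n <- (length(toks) - lead) %/% 3L
    if (is.null(ids)) ids <- sprintf("sample_%d", seq_len(n))

    fields <- character(n)
    for (s in seq_len(n)) {
      tri <- as.numeric(toks[lead + (3L * (s - 1L) + 1L):(3L * s)])
      if (!config$strict) {
        tri[tri < 0] <- 0
        tri[tri > 1] <- 1
      } else {
        tri[tri > 1 & tri <= 1 + config$prob_eps] <- 1
      }
      if (sum(tri) < config$missing_eps) {
        fields[s] <- "./.:.:."
        next
      }
      if (config$renormalize) tri <- tri / sum(tri)
      ds <- min(max(tri[2L] + 2 * tri[3L], 0), 2)
      w <- which(tri == max(tri))[1L]
      gt <- if (tri[w] < config$gt_threshold) "./."
            else c("0/0", "0/1", "1/1")[w]
      fields[s] <- paste0(gt, ":", num(tri[1L]), ",", num(tri[2L]), ",",
                          num(tri[3L]), ":", num(ds))
    }

    id <- switch(config$id_policy,
      rsid = if (m[2L] %in% c(".", "")) "." else m[2L],
      varid = if (m[1L] %in% c(".", "")) "." else m[1L],
      auto = if (!m[2L] %in% c(".", "")) m[2L]
             else if (!m[1L] %in% c(".", "")) m[1L]
             else paste0(ch, ":", m[3L], "_", m[4L], "_", m[5L]))
    out[length(out) + 1L] <- paste(
      c(ch, m[3L], id, m[4L], m[5L], ".", ".", ".", "GT:GP:DS", fields),
      collapse = "\t")
  }

  if (is.null(ids)) {
    header <- c("##fileformat=VCFv4.2",
                sprintf("##source=dosevcf-%s", dosevcf_version()),
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  } else {
    header <- vcf_header(ids)
  }
  c(header, out)
}
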