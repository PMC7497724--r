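#' Conversion configuration
#'
#' Bundles the tunable options of the GEN-to-VCF conversion. Defaults
#' reproduce the plainest behaviour: 3-decimal output (matching the
#' precision IMPUTE prints), always call a best-guess genotype, no
#' renormalization of probability triples, strict input validation.
#'
#' @param precision Integer number of decimal places used when rendering
#'   GP and DS values (1--10).
#' @param gt_threshold Hard-call threshold in \[0, 1\]: if the maximum
#'   genotype probability falls below it, GT is emitted as missing
#'   (`./.`) while GP and DS are still written. The default 0 always
#'   calls.
#' @param renormalize If `TRUE`, each non-missing probability triple is
#'   divided by its sum before computing GP, DS and GT, repairing
#'   rounding in the input. Off by default: raw values are used and the
#'   dosage is clamped into \[0, 2\] if rounding pushed it outside.
#' @param missing_eps Positive tolerance: a triple whose components sum
#'   to less than this is treated as a missing genotype (the GEN
#'   convention writes missing genotypes as `0 0 0`).
#' @param strict If `TRUE` (default), malformed lines and out-of-range
#'   probabilities abort the conversion; if `FALSE`, bad lines are
#'   skipped and slightly out-of-range probabilities are clamped, with
#'   counters reported in the conversion statistics.
#' @param id_policy How the VCF ID column is filled: `"auto"` uses the
#'   rsid unless it is missing (`.` or empty), then the variant id, then
#'   `chrom:pos_ref_alt`; `"rsid"` and `"varid"` use that column
#'   verbatim.
#' @param prob_eps Tolerance on the \[0, 1\] probability bounds,
#'   accommodating 3-decimal rounding in IMPUTE output.
#' @return An object of class `"conversion_config"` (a validated list).
#' @examples
#' conversion_config(precision = 4, gt_threshold = 0.9)
#' @export
conversion_config <- function(precision = 3L,
                              gt_threshold = 0,
                              renormalize = FALSE,
                              missing_eps = 1e-6,
                              strict = TRUE,
                              id_policy = c("auto", "rsid", "varid"),
                              prob_eps = 1e-6) {
  precision <- as.integer(precision)
  if (length(precision) != 1L || is.na(precision) ||
      precision < 1L || precision > 10L) {
    stop("`precision` must be a single integer in [1, 10]", call. = FALSE)
  }
  if (!is.numeric(gt_threshold) || length(gt_threshold) != 1L ||
      is.na(gt_threshold) || gt_threshold < 0 || gt_threshold > 1) {
    stop("`gt_threshold` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(missing_eps) || length(missing_eps) != 1L ||
      !is.finite(missing_eps) || missing_eps <= 0) {
    stop("`missing_eps` must be a single positive number", call. = FALSE)
  }
  id_policy <- match.arg(id_policy)
  structure(
    list(
      precision = precision,
      gt_threshold = as.numeric(gt_threshold),
      renormalize = isTRUE(renormalize),
      missing_eps = as.numeric(missing_eps),
      strict = isTRUE(strict),
      id_policy = id_policy,
      prob_eps = as.numeric(prob_eps)
    ),
    class = "conversion_config"
  )
}

as_conversion_config <- function(config) {
  if (inherits(config, "conversion_config")) return(config)
  if (is.null(config)) return(conversion_config())
  do.call(conversion_config, as.list(config))
}
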