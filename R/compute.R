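#' Imputed alternate-allele dosage
#'
#' The dosage is the posterior mean count of the alternate (B) allele:
#' `0 * P(AA) + 1 * P(AB) + 2 * P(BB)`. For a biallelic diploid
#' genotype it lies in \[0, 2\]; values pushed outside by rounded,
#' unnormalized input probabilities are clamped back to the range.
#'
#' @param probs A length-3 numeric vector `c(p_aa, p_ab, p_bb)` or an
#'   N x 3 matrix of such triples (one row per sample).
#' @param clamp Clamp the result into \[0, 2\] (default `TRUE`).
#' @return Numeric vector of dosages, one per triple.
#' @examples
#' dosage(c(0, 1, 0))          # 1
#' dosage(c(0, 0, 1))          # 2
#' dosage(c(0.1, 0.2, 0.7))    # 1.6
#' @export
dosage <- function(probs, clamp = TRUE) {
  probs <- as_prob_matrix(probs)
  d <- probs[, 2L] + 2 * probs[, 3L]
  if (clamp) d <- pmin(pmax(d, 0), 2)
  unname(d)
}

as_prob_matrix <- function(probs) {
  if (is.matrix(probs)) {
    stopifnot(ncol(probs) == 3L)
    return(probs)
  }
  stopifnot(is.numeric(probs), length(probs) %% 3L == 0L)
  matrix(probs, ncol = 3L, byrow = TRUE)
}

#' Classify missing genotypes
#'
#' GEN files denote a missing genotype by an (effectively) all-zero
#' probability triple. A triple is missing when its component sum falls
#' below `missing_eps`.
#'
#' @inheritParams dosage
#' @param missing_eps Positive tolerance (see [conversion_config()]).
#' @return Logical vector, one per triple.
#' @examples
#' classify_missing(c(0, 0, 0))
#' classify_missing(c(0.333, 0.333, 0.334))
#' @export
classify_missing <- function(probs, missing_eps = 1e-6) {
  probs <- as_prob_matrix(probs)
  unname(rowSums(probs) < missing_eps)
}

#' Best-guess genotype call
#'
#' Returns the genotype with the maximum posterior probability. Exact
#' ties break towards the lowest genotype index
#' (hom-ref < het < hom-alt). If the maximum probability is below
#' `gt_threshold` the call is `"missing"` (the hard-call filter blanks
#' GT only; GP and DS are still emitted downstream).
#'
#' @inheritParams dosage
#' @param gt_threshold Hard-call threshold in \[0, 1\]; 0 always calls.
#' @return Character vector with elements `"hom_ref"`, `"het"`,
#'   `"hom_alt"` or `"missing"`.
#' @examples
#' best_guess(c(0.9, 0.06, 0.04))            # "hom_ref"
#' best_guess(c(0.2, 0.2, 0.6), 0.9)          # "missing"
#' best_guess(c(0.5, 0.5, 0))                 # tie -> "hom_ref"
#' @export
best_guess <- function(probs, gt_threshold = 0) {
  probs <- as_prob_matrix(probs)
  # ties.method = "first" implements the lowest-index tie rule
  idx <- max.col(probs, ties.method = "first")
  out <- c("hom_ref", "het", "hom_alt")[idx]
  if (gt_threshold > 0) {
    pmax_ <- probs[cbind(seq_len(nrow(probs)), idx)]
    out[pmax_ < gt_threshold] <- "missing"
  }
  out
}

#' Renormalize probability triples to sum to one
#'
#' Divides each component by the triple's sum, repairing rounding in
#' 3-decimal input. Triples whose sum is below `missing_eps` are
#' degenerate (they should have been classified missing upstream) and
#' raise an error.
#'
#' @inheritParams classify_missing
#' @return A matrix (or vector, matching the input shape) of
#'   renormalized triples, each summing to 1 within 1e-12.
#' @examples
#' renormalize_probs(c(0.5, 0.5, 0.5)) # 1/3 each
#' @export
renormalize_probs <- function(probs, missing_eps = 1e-6) {
  vec_in <- !is.matrix(probs) && length(probs) == 3L
  probs <- as_prob_matrix(probs)
  s <- rowSums(probs)
  if (any(s < missing_eps)) {
    dv_error("dosevcf_degenerate_triple", sprintf(
      "cannot renormalize triple with component sum %.3g (< %.3g); classify it missing instead",
      min(s), missing_eps
    ))
  }
  out <- probs / s
  if (vec_in) out[1L, ] else out
}

#' Derive GT, GP and DS for a set of probability triples
#'
#' The core per-sample computation: missing triples (component sum below
#' `missing_eps`) yield missing GT, GP and DS; otherwise GP is the
#' triple itself (renormalized first when `config$renormalize`), DS is
#' its [dosage()] clamped into \[0, 2\], and GT is the [best_guess()]
#' under `config$gt_threshold`.
#'
#' @inheritParams dosage
#' @param config A [conversion_config()].
#' @return A list of class `"computed_genotype"`: `gt` (character
#'   codes), `gp` (N x 3 matrix, `NA` rows for missing genotypes), `ds`
#'   (numeric, `NA` when missing), `missing` (logical), and
#'   `n_clamped_ds` (how many dosages needed clamping).
#' @examples
#' compute_genotype(c(0.25, 0.5, 0.25))
#' @export
compute_genotype <- function(probs, config = conversion_config()) {
  config <- as_conversion_config(config)
  probs <- as_prob_matrix(probs)
  miss <- classify_missing(probs, config$missing_eps)
  gp <- probs
  if (config$renormalize && any(!miss)) {
    gp[!miss, ] <- renormalize_probs(gp[!miss, , drop = FALSE],
                                     config$missing_eps)
  }
  raw <- gp[, 2L] + 2 * gp[, 3L]
  ds <- pmin(pmax(raw, 0), 2)
  n_clamped <- sum(ds != raw & !miss)
  gt <- best_guess(gp, config$gt_threshold)
  gt[miss] <- "missing"
  gp[miss, ] <- NA_real_
  ds[miss] <- NA_real_
  structure(
    list(gt = gt, gp = gp, ds = unname(ds), missing = miss,
         n_clamped_ds = as.integer(n_clamped)),
    class = "computed_genotype"
  )
}

gt_string <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[gt]
}
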