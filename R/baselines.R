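#' Original decoy-based mix-max FDR estimate
#'
#' The classical mix-max estimator, which uses decoy matches from a separated
#' target-decoy search as the null score sample. It is the special case of
#' the entrapment-query estimator with the decoy scores standing in for
#' entrapment scores: when the number of decoy matches equals the number of
#' sample spectra (the original method's design assumption) the rescaling
#' factor \eqn{f_g} is exactly 1. If the counts differ, a warning is emitted
#' and the generalized rescaled form is used.
#'
#' @param targets Numeric vector of sample match scores, or a tibble with a
#'   `score` column.
#' @param decoys Numeric vector of decoy match scores, or a tibble with a
#'   `score` column.
#' @param pi0 Fraction of incorrect sample matches due to foreign spectra.
#' @param threshold Score threshold (strict `>` defines the critical region).
#' @return A non-negative number, or `NA_real_` when no target score exceeds
#'   the threshold.
#' @seealso [qmm_fdr()], [mixmax_curve()]
#' @export
mixmax_fdr <- function(targets, decoys, pi0, threshold) {
  inputs <- .mixmax_inputs(targets, decoys, pi0)
  qmm_fdr(inputs, threshold)
}

#' Decoy-based mix-max FDR estimates over the full threshold grid
#'
#' @inheritParams mixmax_fdr
#' @return An `fdr_curve` tibble, as from [qmm_curve()].
#' @export
mixmax_curve <- function(targets, decoys, pi0) {
  inputs <- .mixmax_inputs(targets, decoys, pi0)
  qmm_curve(inputs)
}

.mixmax_inputs <- function(targets, decoys, pi0) {
  w <- if (is.data.frame(targets)) targets$score else targets
  z <- if (is.data.frame(decoys)) decoys$score else decoys
  if (length(z) == 0) stop("decoy score set is empty", call. = FALSE)
  if (length(z) != length(w)) {
    warning(sprintf(paste0("number of decoy matches (%d) differs from number ",
                           "of sample matches (%d); proceeding with effective ",
                           "f_g = %.4g"),
                    length(z), length(w), length(w) / length(z)),
            call. = FALSE)
  }
  qmm_inputs(w, z, pi0)
}

#' Target-decoy competition FDR estimate
#'
#' FDR of a critical region from the counts of decoy (`D`) and target (`T`)
#' matches it contains after competition: `(D + 1) / T` by default, or the
#' uncorrected `D / T` with `plus_one = FALSE`. Vectorized over both counts.
#'
#' @param n_decoy_above Number of decoy matches in the critical region.
#' @param n_target_above Number of target matches in the critical region.
#' @param plus_one Use the +1-corrected estimator (default `TRUE`).
#' @return Numeric FDR estimate(s); `NA_real_` where `n_target_above` is 0.
#' @export
#' @examples
#' tdc_fdr(1, 100)
#' tdc_fdr(0, 50, plus_one = FALSE)
tdc_fdr <- function(n_decoy_above, n_target_above, plus_one = TRUE) {
  stopifnot(all(n_decoy_above >= 0, na.rm = TRUE),
            all(n_target_above >= 0, na.rm = TRUE))
  out <- (n_decoy_above + as.numeric(plus_one)) / n_target_above
  out[n_target_above == 0] <- NA_real_
  out
}

#' Target-decoy competition FDR estimates over the full threshold grid
#'
#' Builds the per-threshold curve of TDC estimates on the same grid
#' convention as [qmm_curve()]: one row per distinct target score group,
#' strict `>` critical regions, plus the full acceptance set. Inputs are
#' assumed to be already competed (one winner per spectrum).
#'
#' @param targets Numeric vector of target winner scores, or a tibble with a
#'   `score` column.
#' @param decoys Numeric vector of decoy winner scores, or a tibble with a
#'   `score` column.
#' @inheritParams tdc_fdr
#' @return An `fdr_curve` tibble with columns `threshold`, `n_target_above`,
#'   `n_decoy_above`, `fdr_hat`, `fdr_hat_capped`, `fdr_hat_monotone`.
#' @export
tdc_curve <- function(targets, decoys, plus_one = TRUE) {
  w <- if (is.data.frame(targets)) targets$score else targets
  z <- if (is.data.frame(decoys)) decoys$score else decoys
  stopifnot(length(w) >= 1)
  if (length(z) == 0) stop("decoy score set is empty", call. = FALSE)
  sw <- sort(w)
  sz <- sort(z)
  s_desc <- sort(unique(w), decreasing = TRUE)
  thresholds <- c(s_desc[-1], -Inf)
  n_target_above <- length(w) - findInterval(thresholds, sw)
  n_decoy_above <- length(z) - findInterval(thresholds, sz)
  fdr_hat <- tdc_fdr(n_decoy_above, n_target_above, plus_one = plus_one)
  fdr_hat_capped <- pmin(fdr_hat, 1)
  out <- tibble::tibble(
    threshold = thresholds,
    n_target_above = as.integer(n_target_above),
    n_decoy_above = as.integer(n_decoy_above),
    fdr_hat = fdr_hat,
    fdr_hat_capped = fdr_hat_capped,
    fdr_hat_monotone = rev(cummin(rev(fdr_hat_capped)))
  )
  class(out) <- c("fdr_curve", class(out))
  out
}
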