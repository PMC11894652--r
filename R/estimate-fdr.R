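#' Estimate FDR for a PSM table
#'
#' High-level, data-frame-first interface tying the pieces together: optional
#' peptide-level rollup, pi0 estimation from entrapment-derived empirical
#' p-values, and the per-threshold FDR curve under the chosen estimator.
#'
#' @param targets PSM tibble of sample matches (from [read_psm_table()]), or
#'   a numeric score vector.
#' @param entrapment PSM tibble or score vector of entrapment matches
#'   (required for `method = "qmm"`).
#' @param decoys PSM tibble or score vector of decoy matches (required for
#'   `method = "mixmax"` and `method = "tdc"`).
#' @param method `"qmm"` (entrapment-query mix-max), `"mixmax"` (decoy-based
#'   mix-max) or `"tdc"` (target-decoy competition).
#' @param level `"psm"` (use the table as given, one match per query
#'   spectrum) or `"peptide"` (apply [peptide_rollup()] to each table first).
#' @param pi0 Fixed pi0 to use; `NULL` (default) estimates it with
#'   [estimate_pi0()] from the null-score set the method uses. Ignored by
#'   `"tdc"`.
#' @param pi0_lambda Tuning point for Storey's estimator.
#' @param tdc_plus_one Use the +1-corrected TDC estimator.
#' @return An `fdr_curve` tibble (see [qmm_curve()]); its `"sidecar"`
#'   attribute is a list recording method, level, counts, `f_g` and the pi0
#'   used, suitable for [jsonlite::write_json()].
#' @export
estimate_fdr <- function(targets, entrapment = NULL, decoys = NULL,
                         method = c("qmm", "mixmax", "tdc"),
                         level = c("psm", "peptide"),
                         pi0 = NULL, pi0_lambda = 0.95,
                         tdc_plus_one = TRUE) {
  method <- match.arg(method)
  level <- match.arg(level)
  null_set <- switch(method, qmm = entrapment, mixmax = decoys, tdc = decoys)
  if (is.null(null_set)) {
    stop(if (method == "qmm") "method 'qmm' requires an entrapment table"
         else sprintf("method '%s' requires a decoy table", method),
         call. = FALSE)
  }
  if (level == "peptide") {
    if (is.data.frame(targets)) targets <- peptide_rollup(targets)
    if (is.data.frame(null_set)) null_set <- peptide_rollup(null_set)
  }
  w <- if (is.data.frame(targets)) targets$score else targets
  v <- if (is.data.frame(null_set)) null_set$score else null_set

  pi0_used <- NA_real_
  if (method %in% c("qmm", "mixmax")) {
    pi0_used <- if (is.null(pi0)) {
      estimate_pi0(empirical_pvalues(w, v), lambda = pi0_lambda)$value
    } else {
      pi0
    }
  }
  curve <- switch(method,
    qmm = qmm_curve(qmm_inputs(w, v, pi0_used)),
    mixmax = mixmax_curve(w, v, pi0_used),
    tdc = tdc_curve(w, v, plus_one = tdc_plus_one)
  )
  attr(curve, "sidecar") <- list(
    method = method, level = level,
    n_target = length(w), n_null = length(v), f_g = length(w) / length(v),
    pi0 = pi0_used, pi0_source = if (is.null(pi0)) "estimated" else "fixed",
    pi0_lambda = pi0_lambda, tdc_plus_one = tdc_plus_one,
    package_version = as.character(utils::packageVersion("qmmfdr"))
  )
  curve
}
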