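#' Bundle sample and entrapment scores for QMM estimation
#'
#' Constructs the input object for the query mix-max (QMM) estimators from the
#' observed sample match scores \eqn{w} (size \eqn{n_\Sigma}), the entrapment
#' match scores \eqn{q} (size \eqn{n_E}) and the fraction \eqn{\pi_0} of
#' sample matches that are incorrect because their spectra are foreign. The
#' scale factor \eqn{f_g = n_\Sigma / n_E} is always derived from the stored
#' counts, never supplied independently.
#'
#' Either numeric score vectors or PSM tibbles (anything with a `score`
#' column, as returned by [read_psm_table()]) are accepted.
#'
#' @param targets Numeric vector of sample match scores, or a tibble with a
#'   `score` column.
#' @param entrapment Numeric vector of entrapment match scores, or a tibble
#'   with a `score` column.
#' @param pi0 Fraction of incorrect sample matches due to foreign spectra, in
#'   `[0, 1]`. Typically [estimate_pi0()]`$value`.
#' @return An object of class `qmm_inputs`: a list with `w`, `q`, `pi0`,
#'   `n_target`, `n_entrap`, and the derived `f_g`.
#' @seealso [qmm_curve()], [qmm_fdr()]
#' @export
qmm_inputs <- function(targets, entrapment, pi0) {
  w <- if (is.data.frame(targets)) targets$score else targets
  q <- if (is.data.frame(entrapment)) entrapment$score else entrapment
  stopifnot(is.numeric(w), is.numeric(q))
  if (length(w) < 1) stop("need at least one sample score", call. = FALSE)
  if (length(q) < 1) stop("need at least one entrapment score", call. = FALSE)
  if (!all(is.finite(w)) || !all(is.finite(q))) {
    stop("all scores must be finite", call. = FALSE)
  }
  if (!is.numeric(pi0) || length(pi0) != 1 || pi0 < 0 || pi0 > 1) {
    stop("pi0 must be a single value in [0, 1]", call. = FALSE)
  }
  structure(
    list(w = as.numeric(w), q = as.numeric(q), pi0 = pi0,
         n_target = length(w), n_entrap = length(q),
         f_g = length(w) / length(q)),
    class = "qmm_inputs"
  )
}

#' @export
print.qmm_inputs <- function(x, ...) {
  cat(sprintf("QMM inputs: n_target = %d, n_entrap = %d, f_g = %.4g, pi0 = %.4g\n",
              x$n_target, x$n_entrap, x$f_g, x$pi0))
  invisible(x)
}

# pi0 this close to 1 zeroes the native-incorrect component (1 - pi0 divides)
.PI0_ONE_EPS <- 1e-12

#' Estimated number of foreign-incorrect matches above a threshold
#'
#' The QMM estimate of \eqn{F_0}, the number of accepted incorrect matches
#' originating from foreign spectra:
#' \deqn{\hat F_0(T) = \pi_0 \, f_g \sum_j 1[q_j > T],}
#' i.e. the entrapment count above the threshold rescaled to the sample size
#' and weighted by \eqn{\pi_0}. The critical region is strict: a score equal
#' to `threshold` is excluded.
#'
#' @param inputs A [qmm_inputs()] object.
#' @param threshold Score threshold \eqn{T}, the lower bound of the critical
#'   region.
#' @return A non-negative number.
#' @export
estimate_f0 <- function(inputs, threshold) {
  stopifnot(inherits(inputs, "qmm_inputs"))
  inputs$pi0 * inputs$f_g * sum(inputs$q > threshold)
}

#' Empirical CDF of the entrapment (null) score distribution
#'
#' \eqn{\hat P(Y \le v)}: the fraction of entrapment matches with scores less
#' than or equal to `value` (ties included).
#'
#' @param q Numeric vector of entrapment scores, or a [qmm_inputs()] object.
#' @param value Score at which to evaluate the CDF.
#' @return A number in `[0, 1]`.
#' @export
entrapment_cdf_at <- function(q, value) {
  if (inherits(q, "qmm_inputs")) q <- q$q
  if (length(q) == 0) stop("entrapment score set is empty", call. = FALSE)
  mean(q <= value)
}

#' Estimated CDF of observed sample scores net of the foreign component
#'
#' The QMM estimate of \eqn{P(W \le q_j)} used inside the native-incorrect
#' component, the entrapment-rescaled form of the mix-max deconvolution:
#' \deqn{\hat P(W \le q_j) = \left[\frac{\sum_k 1[w_k \le q_j] -
#'   \pi_0 f_g \sum_k 1[q_k \le q_j]}{(1 - \pi_0)\, n_\Sigma}\right]_0^1,}
#' clamped to `[0, 1]` (the numerator can be negative in the lower tail).
#'
#' @param inputs A [qmm_inputs()] object with `pi0 < 1`.
#' @param q_j Entrapment score at which to evaluate.
#' @return A number in `[0, 1]`.
#' @export
estimate_pw <- function(inputs, q_j) {
  stopifnot(inherits(inputs, "qmm_inputs"))
  if (inputs$pi0 >= 1 - .PI0_ONE_EPS) {
    stop("estimate_pw is undefined at pi0 = 1; the caller must short-circuit",
         call. = FALSE)
  }
  num <- sum(inputs$w <= q_j) - inputs$pi0 * inputs$f_g * sum(inputs$q <= q_j)
  min(1, max(0, num / ((1 - inputs$pi0) * inputs$n_target)))
}

#' Estimated expected number of native-incorrect matches above a threshold
#'
#' The QMM estimate of \eqn{E[F_1]}, the expected number of accepted
#' incorrect matches whose spectra are native (their correct peptide is in
#' the search space but was outscored). Monte-Carlo form over the entrapment
#' scores above the threshold:
#' \deqn{\hat E[F_1](T) = (1 - \pi_0)\, f_g \sum_{j: q_j > T}
#'   \left[\frac{\hat P(W \le q_j)}{\hat P(Y \le q_j)}\right]_0^1,}
#' with each summand clamped to `[0, 1]` so it keeps the properties of a
#' p-value. Returns 0 when \eqn{\pi_0 = 1} (no native spectra) or when no
#' entrapment score exceeds the threshold.
#'
#' @inheritParams estimate_f0
#' @return A non-negative number, at most \eqn{(1-\pi_0) f_g \#\{q_j > T\}}.
#' @export
estimate_f1 <- function(inputs, threshold) {
  stopifnot(inherits(inputs, "qmm_inputs"))
  if (inputs$pi0 >= 1 - .PI0_ONE_EPS) {
    return(0)
  }
  qa <- inputs$q[inputs$q > threshold]
  if (length(qa) == 0) {
    return(0)
  }
  summands <- vapply(qa, function(qj) {
    pw <- estimate_pw(inputs, qj)
    py <- entrapment_cdf_at(inputs$q, qj)
    min(1, max(0, pw / py))
  }, numeric(1))
  (1 - inputs$pi0) * inputs$f_g * sum(summands)
}

#' QMM FDR estimate at a single threshold
#'
#' Combines the foreign and native incorrect-match estimates into the FDR of
#' the critical region above `threshold`:
#' \deqn{\widehat{FDR}(T) = \frac{\hat F_0(T) + \hat E[F_1](T)}
#'   {\#\{w_i > T\}}.}
#' The raw ratio is returned (it can exceed 1); [qmm_curve()] additionally
#' reports a capped version. If no target score exceeds the threshold the
#' estimate is undefined and `NA` is returned.
#'
#' @inheritParams estimate_f0
#' @return A non-negative number, or `NA_real_` when the critical region
#'   contains no target.
#' @export
qmm_fdr <- function(inputs, threshold) {
  stopifnot(inherits(inputs, "qmm_inputs"))
  n_above <- sum(inputs$w > threshold)
  if (n_above == 0) {
    return(NA_real_)
  }
  (estimate_f0(inputs, threshold) + estimate_f1(inputs, threshold)) / n_above
}

#' QMM FDR estimates over the full threshold grid
#'
#' Evaluates the QMM estimator at every useful score cutoff. The FDR estimate
#' is a step function that changes only at observed sample scores, so the
#' grid consists of one row per distinct sample score group: the critical
#' region above the k+1-th distinct score (strict `>`) accepts exactly the
#' top k distinct score groups, and a final `-Inf` threshold accepts
#' everything. Rows are ordered from the most stringent region to the full
#' acceptance set, and every row contains at least one accepted target.
#'
#' `fdr_hat_monotone` is the q-value transform: for each row, the smallest
#' capped FDR estimate over that row and all looser thresholds, so it is
#' non-decreasing as the threshold decreases and is the column used by
#' [threshold_at_level()].
#'
#' @param inputs A [qmm_inputs()] object.
#' @return A tibble of class `fdr_curve` with columns `threshold`,
#'   `n_target_above`, `n_entrap_above`, `f0_hat`, `f1_hat`, `fdr_hat`,
#'   `fdr_hat_capped` (`min(fdr_hat, 1)`) and `fdr_hat_monotone`. Attributes
#'   `pi0`, `f_g`, `n_target`, `n_entrap` record the estimation context.
#' @export
qmm_curve <- function(inputs) {
  stopifnot(inherits(inputs, "qmm_inputs"))
  w <- inputs$w
  q <- inputs$q
  pi0 <- inputs$pi0
  f_g <- inputs$f_g
  n_t <- inputs$n_target
  n_e <- inputs$n_entrap

  sw <- sort(w)
  sq <- sort(q)
  s_desc <- sort(unique(w), decreasing = TRUE)
  thresholds <- c(s_desc[-1], -Inf)

  n_target_above <- n_t - findInterval(thresholds, sw)
  n_entrap_above <- n_e - findInterval(thresholds, sq)
  f0_hat <- pi0 * f_g * n_entrap_above

  if (pi0 >= 1 - .PI0_ONE_EPS) {
    f1_hat <- rep(0, length(thresholds))
  } else {
    qd <- sort(q, decreasing = TRUE)
    cw <- findInterval(qd, sw)            # #{w <= q_j}
    cq <- findInterval(qd, sq)            # #{q <= q_j}
    pw <- pmin(1, pmax(0, (cw - pi0 * f_g * cq) / ((1 - pi0) * n_t)))
    py <- cq / n_e
    cums <- cumsum(pmin(1, pmax(0, pw / py)))
    f1_hat <- (1 - pi0) * f_g *
      ifelse(n_entrap_above == 0, 0, cums[pmax(n_entrap_above, 1)])
  }

  fdr_hat <- (f0_hat + f1_hat) / n_target_above
  fdr_hat_capped <- pmin(fdr_hat, 1)
  fdr_hat_monotone <- rev(cummin(rev(fdr_hat_capped)))

  out <- tibble::tibble(
    threshold = thresholds,
    n_target_above = as.integer(n_target_above),
    n_entrap_above = as.integer(n_entrap_above),
    f0_hat = f0_hat,
    f1_hat = f1_hat,
    fdr_hat = fdr_hat,
    fdr_hat_capped = fdr_hat_capped,
    fdr_hat_monotone = fdr_hat_monotone
  )
  attr(out, "pi0") <- pi0
  attr(out, "f_g") <- f_g
  attr(out, "n_target") <- n_t
  attr(out, "n_entrap") <- n_e
  class(out) <- c("fdr_curve", class(out))
  out
}

#' Pick the score threshold attaining a nominal FDR level
#'
#' Scans an FDR curve for the largest acceptance set whose monotonized FDR
#' estimate (`fdr_hat_monotone`) is at most `alpha`. If no threshold
#' qualifies, a sentinel row with `threshold = Inf` and zero accepted targets
#' is returned.
#'
#' @param curve An `fdr_curve` tibble from [qmm_curve()], [mixmax_curve()] or
#'   [tdc_curve()].
#' @param alpha Nominal FDR level in `(0, 1]`.
#' @return A one-row tibble with columns `threshold`, `n_accepted` and
#'   `fdr_hat_monotone`.
#' @export
threshold_at_level <- function(curve, alpha) {
  stopifnot(is.data.frame(curve), length(alpha) == 1, alpha > 0, alpha <= 1)
  ok <- which(curve$fdr_hat_monotone <= alpha)
  if (length(ok) == 0) {
    return(tibble::tibble(threshold = Inf, n_accepted = 0L,
                          fdr_hat_monotone = NA_real_))
  }
  i <- ok[which.max(curve$n_target_above[ok])]
  tibble::tibble(threshold = curve$threshold[i],
                 n_accepted = curve$n_target_above[i],
                 fdr_hat_monotone = curve$fdr_hat_monotone[i])
}

#' Write an FDR curve to a tab-separated file
#'
#' @param curve An `fdr_curve` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fdr_curve <- function(curve, path) {
  readr::write_tsv(as.data.frame(curve), path, progress = FALSE)
  invisible(path)
}
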