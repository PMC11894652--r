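#' Empirical p-values of sample scores against the entrapment null
#'
#' Converts each observed sample score \eqn{w_i} into an empirical p-value
#' under the null model that incorrect sample matches score like entrapment
#' matches:
#' \deqn{p_i = \frac{1 + \#\{q_j \ge w_i\}}{n_E + 1}.}
#' The pseudo-count keeps every p-value in \eqn{(0, 1]}, and ties between a
#' sample score and an entrapment score count toward the null exceedance, so
#' the p-values are conservative. The result depends only on ranks: any common
#' strictly increasing transform of both score sets leaves it unchanged.
#'
#' @param scores Numeric vector of observed sample match scores (higher is
#'   better).
#' @param null_scores Numeric vector of entrapment match scores drawn from the
#'   same search space.
#' @return Numeric vector of p-values in `(0, 1]`, one per element of
#'   `scores`.
#' @seealso [estimate_pi0()]
#' @export
#' @examples
#' empirical_pvalues(c(5, 0, 2), c(1, 2, 3))
empirical_pvalues <- function(scores, null_scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1, all(is.finite(scores)))
  if (length(null_scores) == 0) {
    stop("null_scores must be non-empty", call. = FALSE)
  }
  stopifnot(all(is.finite(null_scores)))
  n_e <- length(null_scores)
  sq <- sort(null_scores)
  # #{q >= w} = n_E - #{q < w}; findInterval with left.open counts strict <
  n_ge <- n_e - findInterval(scores, sq, left.open = TRUE)
  (1 + n_ge) / (n_e + 1)
}

#' Estimate pi0 from p-values (Storey's single-lambda estimator)
#'
#' Estimates \eqn{\pi_0}, the fraction of sample matches that are incorrect
#' because their spectra are foreign to the search space, from the upper tail
#' of a p-value distribution:
#' \deqn{\hat\pi_0 = \frac{\#\{p_i > \lambda\}}{n (1 - \lambda)},}
#' clamped to \eqn{[0, 1]}. A single fixed tuning point \eqn{\lambda = 0.95}
#' is used (no spline over a \eqn{\lambda} grid).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter strictly between 0 and 1; p-values above it
#'   are taken to come from the null component. Default 0.95.
#' @return An object of class `pi0_estimate`: a list with elements `value`
#'   (clamped estimate), `raw_value` (before clamping), `lambda` and
#'   `n_pvalues`. Use [tidy()] to get a one-row tibble.
#' @export
#' @examples
#' estimate_pi0(c(0.96, 0.98, 0.5, 0.2, 0.7))
estimate_pi0 <- function(pvalues, lambda = 0.95) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda >= 1) {
    stop("lambda must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  stopifnot(is.numeric(pvalues), length(pvalues) >= 1)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues)) {
    stop("pvalues must all lie in [0, 1]", call. = FALSE)
  }
  n <- length(pvalues)
  raw <- sum(pvalues > lambda) / (n * (1 - lambda))
  structure(
    list(value = min(1, max(0, raw)), raw_value = raw,
         lambda = lambda, n_pvalues = n),
    class = "pi0_estimate"
  )
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 estimate: %.4f (raw %.4f, lambda = %g, n = %d)\n",
              x$value, x$raw_value, x$lambda, x$n_pvalues))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pi0 estimate
#'
#' @param x A `pi0_estimate` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `pi0`, `raw_pi0`, `lambda`,
#'   `n_pvalues`.
#' @export
tidy.pi0_estimate <- function(x, ...) {
  tibble::tibble(pi0 = x$value, raw_pi0 = x$raw_value,
                 lambda = x$lambda, n_pvalues = x$n_pvalues)
}
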