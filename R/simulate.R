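#' Default grid of nominal FDR levels (0.1% to 10%)
#'
#' 0.1% steps up to 1% and 1% steps up to 10%, the range over which
#' calibration of the FDR estimates is evaluated.
#'
#' @return A strictly increasing numeric vector of levels in `(0, 1)`.
#' @export
default_fdr_grid <- function() {
  c(seq(0.001, 0.009, by = 0.001), seq(0.01, 0.10, by = 0.01))
}

#' Configuration of a synthetic PSM score simulation
#'
#' Defines one simulated data set of `N` sample match scores drawn from a
#' two-component mixture. Incorrect-match scores (and the entrapment scores
#' that model them) come from `Normal(mu0, sigma0^2)`; correct-match scores
#' come from `Normal(mu1, sigma1^2)`. A fraction `pi0` of the sample spectra
#' are foreign (their match is incorrect by construction); the remaining
#' native spectra carry the maximum of a correct and an incorrect draw, which
#' yields a native-incorrect match whenever the incorrect draw wins. The
#' entrapment set has `floor(N / f_g)` scores.
#'
#' @param N Number of sample data points per repetition.
#' @param pi0 Fraction of sample matches incorrect due to foreign spectra.
#' @param f_g Ratio of sample to entrapment matches; the entrapment set size
#'   is `floor(N / f_g)` and must be at least 1.
#' @param mu0,sigma0 Mean and SD of the incorrect (null) score distribution.
#' @param mu1,sigma1 Mean and SD of the correct score distribution.
#' @param seed Integer root seed; fully determines the data set (and, through
#'   per-repetition child seeds, a whole scenario).
#' @param reps Number of repetitions summarized by [run_scenario()].
#' @param fdr_grid Strictly increasing nominal FDR levels in `(0, 1)`.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(N = 10000, pi0 = 0.7, f_g = 1,
                              mu0 = 0, sigma0 = 1, mu1 = 2.5, sigma1 = 1,
                              seed = 1L, reps = 100,
                              fdr_grid = default_fdr_grid()) {
  stopifnot(N >= 1, pi0 >= 0, pi0 <= 1, f_g > 0, sigma0 > 0, sigma1 > 0,
            reps >= 1, length(fdr_grid) >= 1)
  if (floor(N / f_g) < 1) {
    stop("floor(N / f_g) must be at least 1 entrapment score", call. = FALSE)
  }
  if (any(fdr_grid <= 0 | fdr_grid >= 1) || is.unsorted(fdr_grid, strictly = TRUE)) {
    stop("fdr_grid must be strictly increasing with values in (0, 1)",
         call. = FALSE)
  }
  structure(
    list(N = as.integer(N), pi0 = pi0, f_g = f_g, mu0 = mu0, sigma0 = sigma0,
         mu1 = mu1, sigma1 = sigma1, seed = as.integer(seed),
         reps = as.integer(reps), fdr_grid = fdr_grid),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation config: N = %d, pi0 = %g, f_g = %g, null N(%g, %g^2), correct N(%g, %g^2), seed = %d, reps = %d\n",
    x$N, x$pi0, x$f_g, x$mu0, x$sigma0, x$mu1, x$sigma1, x$seed, x$reps))
  invisible(x)
}

#' Simulate one labelled PSM score data set
#'
#' Draws the score vectors that define a simulated search result with known
#' ground truth:
#' * `N` incorrect-match scores from the null distribution; the first
#'   `floor(N * pi0)` are kept unchanged as `foreign_incorrect`;
#' * for each of the remaining native positions, a correct-match score is
#'   drawn and the maximum of the correct and incorrect draw is retained,
#'   labelled `correct` when the correct draw wins (ties included) and
#'   `native_incorrect` otherwise;
#' * `floor(N / f_g)` entrapment scores from the same null distribution,
#'   reflecting the assumption that entrapment queries model incorrect sample
#'   matches.
#'
#' The output is fully determined by `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `labeled_scores`: a list with `psms` (a tibble
#'   with columns `score` and `label`), `entrapment` (numeric vector) and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_e <- floor(config$N / config$f_g)
  set.seed(config$seed)
  v0 <- stats::rnorm(config$N, config$mu0, config$sigma0)
  v_e <- stats::rnorm(n_e, config$mu0, config$sigma0)
  n0 <- floor(config$N * config$pi0)
  n1 <- config$N - n0
  if (n1 > 0) {
    x <- stats::rnorm(n1, config$mu1, config$sigma1)
    y <- v0[(n0 + 1):config$N]
    scores <- c(v0[seq_len(n0)], pmax(x, y))
    labels <- c(rep("foreign_incorrect", n0),
                ifelse(x >= y, "correct", "native_incorrect"))
  } else {
    scores <- v0
    labels <- rep("foreign_incorrect", config$N)
  }
  structure(
    list(psms = tibble::tibble(score = scores, label = labels),
         entrapment = v_e,
         config = config),
    class = "labeled_scores"
  )
}

#' @export
print.labeled_scores <- function(x, ...) {
  tab <- table(x$psms$label)
  cat(sprintf("labelled scores: N = %d (%s), n_entrap = %d\n",
              nrow(x$psms),
              paste(names(tab), tab, sep = " = ", collapse = ", "),
              length(x$entrapment)))
  invisible(x)
}

#' False discovery proportion of a critical region
#'
#' The realized FDP from ground-truth labels: the fraction of accepted scores
#' (strictly above `threshold`) whose label is `foreign_incorrect` or
#' `native_incorrect`. An empty acceptance set yields 0 with attribute
#' `infeasible = TRUE` so that downstream means are not silently distorted.
#'
#' @param labeled A `labeled_scores` object from [simulate_dataset()], or a
#'   tibble with `score` and `label` columns.
#' @param threshold Score threshold.
#' @return A number in `[0, 1]` (with attribute `infeasible` when no score
#'   exceeds the threshold).
#' @export
compute_fdp <- function(labeled, threshold) {
  psms <- if (inherits(labeled, "labeled_scores")) labeled$psms else labeled
  stopifnot(all(c("score", "label") %in% names(psms)))
  acc <- psms$score > threshold
  n_acc <- sum(acc)
  if (n_acc == 0) {
    return(structure(0, infeasible = TRUE))
  }
  sum(psms$label[acc] != "correct") / n_acc
}

#' Run a repeated simulation scenario and summarize calibration
#'
#' Repeats `config$reps` times: simulate a labelled data set, obtain pi0
#' (either estimated by Storey's method from entrapment-derived empirical
#' p-values, or the known generating value), build the QMM FDR curve, and for
#' every nominal level of `config$fdr_grid` select the threshold via
#' [threshold_at_level()] and record the realized FDP and acceptance count.
#' Per-repetition child seeds are drawn deterministically from the root seed,
#' so two runs with the same configuration are bit-identical.
#'
#' @param config A [simulation_config()] object.
#' @param pi0_mode `"estimate"` (Storey, lambda = `pi0_lambda`) or `"oracle"`
#'   (use `config$pi0`).
#' @param pi0_lambda Tuning point for Storey's estimator when
#'   `pi0_mode = "estimate"`.
#' @return A tibble of class `scenario_summary`, one row per nominal level,
#'   with columns `nominal_fdr`, `mean_fdp`, `band_low` and `band_high`
#'   (pointwise 16th/84th percentiles across repetitions, a 68% band),
#'   `mean_n_accepted` and `n_infeasible` (repetitions in which no threshold
#'   attained the level). Attributes `config`, `pi0_mode`, `reps` and
#'   `pi0_values` (per-rep pi0 actually used) record the run.
#' @export
run_scenario <- function(config, pi0_mode = c("estimate", "oracle"),
                         pi0_lambda = 0.95) {
  stopifnot(inherits(config, "simulation_config"))
  pi0_mode <- match.arg(pi0_mode)
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, config$reps)
  grid <- config$fdr_grid

  per_rep <- purrr::map(seq_len(config$reps), function(r) {
    cfg_r <- config
    cfg_r$seed <- child_seeds[r]
    ds <- simulate_dataset(cfg_r)
    pi0 <- if (pi0_mode == "oracle") {
      config$pi0
    } else {
      estimate_pi0(empirical_pvalues(ds$psms$score, ds$entrapment),
                   lambda = pi0_lambda)$value
    }
    curve <- qmm_curve(qmm_inputs(ds$psms$score, ds$entrapment, pi0))
    sel <- purrr::map_dfr(grid, function(a) threshold_at_level(curve, a))
    fdp <- purrr::map2_dbl(sel$threshold, sel$n_accepted, function(th, n) {
      if (n == 0) 0 else as.numeric(compute_fdp(ds, th))
    })
    list(fdp = fdp, n_accepted = sel$n_accepted,
         infeasible = sel$n_accepted == 0, pi0 = pi0)
  })

  fdp_mat <- do.call(rbind, purrr::map(per_rep, "fdp"))
  acc_mat <- do.call(rbind, purrr::map(per_rep, "n_accepted"))
  inf_mat <- do.call(rbind, purrr::map(per_rep, "infeasible"))

  out <- tibble::tibble(
    nominal_fdr = grid,
    mean_fdp = colMeans(fdp_mat),
    band_low = apply(fdp_mat, 2, stats::quantile, probs = 0.16, names = FALSE),
    band_high = apply(fdp_mat, 2, stats::quantile, probs = 0.84, names = FALSE),
    mean_n_accepted = colMeans(acc_mat),
    n_infeasible = as.integer(colSums(inf_mat))
  )
  attr(out, "config") <- config
  attr(out, "pi0_mode") <- pi0_mode
  attr(out, "reps") <- config$reps
  attr(out, "pi0_values") <- purrr::map_dbl(per_rep, "pi0")
  class(out) <- c("scenario_summary", class(out))
  out
}

#' Summarize a scenario run in one row
#'
#' @param x A `scenario_summary` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the run's configuration and the maximum
#'   absolute deviation between mean FDP and nominal FDR over the grid.
#' @export
glance.scenario_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    N = cfg$N, pi0 = cfg$pi0, f_g = cfg$f_g, mu1 = cfg$mu1,
    reps = attr(x, "reps"), pi0_mode = attr(x, "pi0_mode"),
    mean_pi0_used = mean(attr(x, "pi0_values")),
    max_abs_calibration_error = max(abs(x$mean_fdp - x$nominal_fdr))
  )
}

#' Write a scenario summary (and its provenance) to JSON
#'
#' @param summary A `scenario_summary` tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_scenario_summary <- function(summary, path) {
  cfg <- attr(summary, "config")
  obj <- list(
    config = cfg[setdiff(names(cfg), "fdr_grid")],
    fdr_grid = cfg$fdr_grid,
    pi0_mode = attr(summary, "pi0_mode"),
    reps = attr(summary, "reps"),
    summary = as.data.frame(summary)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
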