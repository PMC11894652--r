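# The six-target / three-entrapment toy used throughout:
toy_w <- c(0.1, 0.9, 1.5, 2.5, 2.6, 3.0)
toy_q <- c(0.5, 1.2, 2.0)

test_that("foreign-incorrect estimate counts entrapments above the cutoff", {
  inp <- qmm_inputs(rep(0, 8), c(0.5, 1.2, 2.0, 3.1), pi0 = 0.5)
  expect_equal(inp$f_g, 2)
  expect_equal(estimate_f0(inp, 1.0), 3.0)
  expect_equal(estimate_f0(inp, 3.2), 0.0)
  expect_equal(estimate_f0(qmm_inputs(rep(0, 8), c(0.5, 1.2, 2.0, 3.1), 0), 1.0), 0.0)
})

test_that("entrapment CDF includes ties and spans [0, 1]", {
  q <- c(0.5, 1.2, 2.0, 3.1)
  expect_equal(entrapment_cdf_at(q, 1.2), 0.5)
  expect_equal(entrapment_cdf_at(q, 0.4), 0.0)
  expect_equal(entrapment_cdf_at(q, 3.1), 1.0)
  expect_error(entrapment_cdf_at(numeric(0), 1), "empty")
})

test_that("sample-score CDF net of the foreign component matches hand values", {
  inp <- qmm_inputs(toy_w, toy_q, pi0 = 0.25)
  expect_equal(estimate_pw(inp, 2.0), 1 / 3)
  inp50 <- qmm_inputs(toy_w, toy_q, pi0 = 0.5)
  expect_equal(estimate_pw(inp50, 2.0), 0.0)
  # pi0 = 0 reduces to the plain empirical CDF of sample scores
  inp0 <- qmm_inputs(toy_w, toy_q, pi0 = 0)
  for (v in c(0.0, 1.0, 2.0, 3.5)) {
    expect_equal(estimate_pw(inp0, v), mean(toy_w <= v))
  }
  expect_error(estimate_pw(qmm_inputs(toy_w, toy_q, 1), 2.0), "pi0 = 1")
})

test_that("native-incorrect estimate matches the hand-evaluated toy", {
  inp <- qmm_inputs(toy_w, toy_q, pi0 = 0.25)
  expect_equal(estimate_f1(inp, 1.0), 1.0)
  expect_equal(estimate_f1(qmm_inputs(toy_w, toy_q, 1), 1.0), 0.0)
  expect_equal(estimate_f1(inp, 2.5), 0.0)  # no entrapment above
})

test_that("combined FDR estimate composes the two parts", {
  inp <- qmm_inputs(toy_w, toy_q, pi0 = 0.25)
  expect_equal(qmm_fdr(inp, 1.0), 0.5)
  expect_equal(qmm_fdr(inp, 2.1), 0.0)      # no entrapment above: both vanish
  expect_equal(qmm_fdr(qmm_inputs(toy_w, toy_q, 1), 1.0), 1.0)
  expect_true(is.na(qmm_fdr(inp, 3.0)))     # empty critical region sentinel
})

test_that("estimators agree with the brute-force double-loop oracle", {
  set.seed(51)
  for (rep in 1:60) {
    inst <- random_instance()
    inp <- qmm_inputs(inst$w, inst$q, inst$pi0)
    expect_equal(estimate_f0(inp, inst$T),
                 oracle_f0(inst$w, inst$q, inst$pi0, inst$T), tolerance = 1e-12)
    expect_equal(estimate_f1(inp, inst$T),
                 oracle_f1(inst$w, inst$q, inst$pi0, inst$T), tolerance = 1e-12)
    expect_equal(qmm_fdr(inp, inst$T),
                 oracle_fdr(inst$w, inst$q, inst$pi0, inst$T), tolerance = 1e-12)
  }
})

test_that("estimates are rank-invariant and satisfy the structural bounds", {
  set.seed(61)
  for (rep in 1:25) {
    inst <- random_instance()
    inp <- qmm_inputs(inst$w, inst$q, inst$pi0)
    tinp <- qmm_inputs(exp(inst$w), exp(inst$q), inst$pi0)
    expect_equal(estimate_f0(tinp, exp(inst$T)), estimate_f0(inp, inst$T))
    expect_equal(estimate_f1(tinp, exp(inst$T)), estimate_f1(inp, inst$T))
    expect_equal(qmm_fdr(tinp, exp(inst$T)), qmm_fdr(inp, inst$T))

    f0 <- estimate_f0(inp, inst$T)
    f1 <- estimate_f1(inp, inst$T)
    expect_gte(f0, 0)
    expect_gte(f1, 0)
    expect_lte(f1, (1 - inst$pi0) * inp$f_g * sum(inst$q > inst$T) + 1e-12)

    # duplicating the entrapment set (halving f_g) changes nothing
    dup <- qmm_inputs(inst$w, c(inst$q, inst$q), inst$pi0)
    expect_equal(estimate_f0(dup, inst$T), f0)
    expect_equal(estimate_f1(dup, inst$T), f1, tolerance = 1e-12)
  }
})

test_that("the curve matches the scalar estimators row by row", {
  set.seed(71)
  for (rep in 1:15) {
    inst <- random_instance()
    inp <- qmm_inputs(inst$w, inst$q, inst$pi0)
    cv <- qmm_curve(inp)
    expect_equal(nrow(cv), length(unique(inst$w)))
    for (i in seq_len(nrow(cv))) {
      T <- cv$threshold[i]
      expect_equal(cv$n_target_above[i], sum(inst$w > T))
      expect_equal(cv$f0_hat[i], estimate_f0(inp, T), tolerance = 1e-12)
      expect_equal(cv$f1_hat[i], estimate_f1(inp, T), tolerance = 1e-12)
      expect_equal(cv$fdr_hat[i], qmm_fdr(inp, T), tolerance = 1e-12)
    }
    expect_true(all(diff(cv$n_target_above) > 0))
    expect_true(all(diff(cv$fdr_hat_monotone) >= 0))
    expect_true(all(cv$fdr_hat_monotone <= pmin(cv$fdr_hat, 1) + 1e-15))
  }
})

test_that("self-matched inputs at pi0 = 1 estimate FDR 1 at full acceptance", {
  set.seed(81)
  w <- stats::rnorm(50)
  cv <- qmm_curve(qmm_inputs(w, w, pi0 = 1))
  expect_equal(cv$fdr_hat[nrow(cv)], 1.0)
  expect_identical(cv$threshold[nrow(cv)], -Inf)
  expect_equal(cv$n_target_above[nrow(cv)], length(w))
})

test_that("threshold selection returns the largest feasible acceptance set", {
  curve <- tibble::tibble(threshold = c(3, 2, 1),
                          n_target_above = c(1L, 10L, 50L),
                          fdr_hat_monotone = c(0.0, 0.02, 0.08))
  expect_equal(threshold_at_level(curve, 0.05)$n_accepted, 10L)
  expect_equal(threshold_at_level(curve, 0.05)$threshold, 2)

  infeasible <- threshold_at_level(dplyr::mutate(curve,
                                                 fdr_hat_monotone = c(0.2, 0.3, 0.4)),
                                   0.05)
  expect_equal(infeasible$n_accepted, 0L)
  expect_equal(infeasible$threshold, Inf)

  expect_equal(threshold_at_level(curve, 1)$n_accepted, 50L)
})

test_that("curve writing round-trips through TSV", {
  cv <- qmm_curve(qmm_inputs(toy_w, toy_q, 0.25))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fdr_curve(cv, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$fdr_hat, cv$fdr_hat)
  expect_equal(nrow(back), nrow(cv))
})
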