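test_that("label counts follow the floor-based foreign/native split", {
  set.seed(121)
  for (rep in 1:10) {
    N <- sample(10:500, 1)
    pi0 <- stats::runif(1)
    cfg <- simulation_config(N = N, pi0 = pi0, f_g = 1, seed = rep)
    ds <- simulate_dataset(cfg)
    n0 <- floor(N * pi0)
    expect_equal(sum(ds$psms$label == "foreign_incorrect"), n0)
    expect_equal(sum(ds$psms$label %in% c("correct", "native_incorrect")),
                 N - n0)
    expect_equal(length(ds$entrapment), floor(N / cfg$f_g))
  }

  ds10 <- simulate_dataset(simulation_config(N = 10, pi0 = 0.7, seed = 1))
  expect_equal(sum(ds10$psms$label == "foreign_incorrect"), 7)

  all_foreign <- simulate_dataset(simulation_config(N = 50, pi0 = 1, seed = 1))
  expect_true(all(all_foreign$psms$label == "foreign_incorrect"))
})

test_that("entrapment sizes track f_g and degenerate configs are rejected", {
  ds <- simulate_dataset(simulation_config(N = 100, f_g = 2, seed = 1))
  expect_equal(length(ds$entrapment), 50)
  ds <- simulate_dataset(simulation_config(N = 100, f_g = 0.83, seed = 1))
  expect_equal(length(ds$entrapment), 120)
  expect_error(simulation_config(N = 5, f_g = 10), "at least 1")
  expect_error(simulation_config(N = 100, fdr_grid = c(0.1, 0.05)),
               "increasing")
})

test_that("well-separated mixtures produce almost no native-incorrect matches", {
  ds <- simulate_dataset(simulation_config(N = 100000, pi0 = 0.7, mu1 = 6,
                                           seed = 7))
  n_native <- sum(ds$psms$label == "native_incorrect")
  n_incorrect <- sum(ds$psms$label != "correct")
  expect_lt(n_native / n_incorrect, 0.01)
})

test_that("FDP from labels matches hand counts and the brute-force oracle", {
  lab <- tibble::tibble(
    score = c(3.0, 2.5, 2.6, 1.0),
    label = c("correct", "correct", "foreign_incorrect", "native_incorrect")
  )
  expect_equal(compute_fdp(lab, 2.4), 1 / 3)
  expect_equal(compute_fdp(lab, 0.5), 2 / 4)     # full acceptance
  expect_equal(compute_fdp(lab, 2.55), 1 / 2)
  clean <- tibble::tibble(score = c(3, 2), label = c("correct", "correct"))
  expect_equal(compute_fdp(clean, 1), 0.0)

  empty <- compute_fdp(lab, 10)
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "infeasible"))

  set.seed(131)
  for (rep in 1:10) {
    n <- sample(5:80, 1)
    scores <- stats::rnorm(n)
    labels <- sample(c("correct", "foreign_incorrect", "native_incorrect"),
                     n, replace = TRUE)
    T <- stats::rnorm(1)
    if (sum(scores > T) > 0) {
      expect_equal(compute_fdp(tibble::tibble(score = scores, label = labels), T),
                   oracle_fdp(scores, labels, T))
    }
  }
})

test_that("simulation and scenario runs are deterministic given the seed", {
  cfg <- simulation_config(N = 400, pi0 = 0.7, f_g = 1, seed = 99, reps = 3)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  s1 <- run_scenario(cfg, pi0_mode = "oracle")
  s2 <- run_scenario(cfg, pi0_mode = "oracle")
  expect_identical(s1, s2)

  other <- run_scenario(simulation_config(N = 400, pi0 = 0.7, f_g = 1,
                                          seed = 100, reps = 3),
                        pi0_mode = "oracle")
  expect_false(identical(s1$mean_fdp, other$mean_fdp))
})

test_that("a single-repetition scenario collapses its band onto the mean", {
  cfg <- simulation_config(N = 300, pi0 = 0.5, f_g = 1, seed = 5, reps = 1)
  s <- run_scenario(cfg, pi0_mode = "oracle")
  expect_equal(s$band_low, s$mean_fdp)
  expect_equal(s$band_high, s$mean_fdp)
  expect_equal(nrow(s), length(cfg$fdr_grid))
})

test_that("scenario summaries carry ordered bands and provenance", {
  cfg <- simulation_config(N = 500, pi0 = 0.7, f_g = 1, seed = 17, reps = 5)
  s <- run_scenario(cfg, pi0_mode = "estimate")
  expect_true(all(s$band_low <= s$band_high))
  expect_equal(attr(s, "reps"), 5)
  expect_equal(length(attr(s, "pi0_values")), 5)
  expect_true(all(attr(s, "pi0_values") >= 0 & attr(s, "pi0_values") <= 1))

  g <- glance(s)
  expect_equal(g$reps, 5)
  expect_equal(g$pi0_mode, "estimate")

  tf <- withr::local_tempfile(fileext = ".json")
  write_scenario_summary(s, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$config$N, 500)
  expect_equal(back$summary$mean_fdp, s$mean_fdp)
})
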