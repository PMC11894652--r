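# Naive double-loop reference implementations of the estimators, kept
# deliberately independent of the package's vectorized code paths.

oracle_f0 <- function(w, q, pi0, T) {
  s <- 0
  for (qj in q) s <- s + as.numeric(qj > T)
  pi0 * (length(w) / length(q)) * s
}

oracle_py <- function(q, value) {
  s <- 0
  for (qk in q) s <- s + as.numeric(qk <= value)
  s / length(q)
}

oracle_pw <- function(w, q, pi0, qj) {
  cw <- 0
  for (wk in w) cw <- cw + as.numeric(wk <= qj)
  cq <- 0
  for (qk in q) cq <- cq + as.numeric(qk <= qj)
  f_g <- length(w) / length(q)
  val <- (cw - pi0 * f_g * cq) / ((1 - pi0) * length(w))
  min(1, max(0, val))
}

oracle_f1 <- function(w, q, pi0, T) {
  if (pi0 >= 1 - 1e-12) {
    return(0)
  }
  s <- 0
  for (qj in q) {
    if (qj > T) {
      r <- oracle_pw(w, q, pi0, qj) / oracle_py(q, qj)
      s <- s + min(1, max(0, r))
    }
  }
  (1 - pi0) * (length(w) / length(q)) * s
}

oracle_fdr <- function(w, q, pi0, T) {
  n_above <- 0
  for (wi in w) n_above <- n_above + as.numeric(wi > T)
  if (n_above == 0) {
    return(NA_real_)
  }
  (oracle_f0(w, q, pi0, T) + oracle_f1(w, q, pi0, T)) / n_above
}

# Brute-force FDP from labels.
oracle_fdp <- function(scores, labels, T) {
  v <- 0
  r <- 0
  for (i in seq_along(scores)) {
    if (scores[i] > T) {
      r <- r + 1
      if (labels[i] != "correct") v <- v + 1
    }
  }
  if (r == 0) 0 else v / r
}

# Random small estimation instance for property tests.
random_instance <- function(max_n = 30) {
  n_w <- sample(1:max_n, 1)
  n_q <- sample(1:max_n, 1)
  list(
    w = round(stats::rnorm(n_w, 1, 2), 2),   # rounding induces ties
    q = round(stats::rnorm(n_q, 0, 2), 2),
    pi0 = sample(c(0, stats::runif(1), 1), 1),
    T = round(stats::rnorm(1, 0.5, 2), 2)
  )
}
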