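# Independent oracles: plain matrix algebra and explicit loops only, no calls
# into the package's estimation path.

# weighted least squares by normal equations; X a matrix, w a weight vector
oracle_wls <- function(X, y, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  cov_unscaled <- solve(XtW %*% X)
  list(beta = drop(beta), se_unscaled = sqrt(diag(cov_unscaled)))
}

# brute-force cumulative-weight walk for the weighted median
oracle_weighted_median <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  s <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    s[j] <- 100 * (acc + wn[j] / 2)
    acc <- acc + wn[j]
  }
  if (s[1] >= 50) return(r[1])
  if (s[length(s)] <= 50) return(r[length(s)])
  j <- max(which(s <= 50))
  r[j] + (r[j + 1] - r[j]) * (50 - s[j]) / (s[j + 1] - s[j])
}

# direct summation of Q contributions
oracle_q <- function(bx, by, sy, theta) {
  q <- 0
  for (j in seq_along(bx)) {
    q <- q + (bx[j]^2 / sy[j]^2) * (by[j] / bx[j] - theta)^2
  }
  q
}

# a fixed deterministic toy instrument table (oriented, heterogeneous weights)
toy_instruments <- function(J = 20, seed = 101, theta = 0.25) {
  withr::with_seed(seed, {
    bx <- runif(J, 0.02, 0.08)
    sy <- runif(J, 0.002, 0.01)
    by <- theta * bx + rnorm(J, 0, sy)
    tibble::tibble(
      variant_id = sprintf("t%02d", seq_len(J)),
      beta_x = bx, se_x = runif(J, 0.002, 0.005),
      beta_y = by, se_y = sy
    )
  })
}

# simulate and return oriented instruments in one step
sim_instruments <- function(seed, ..., outcome_stream = 0L) {
  sim <- simulate_two_sample(sim_config(seed = seed, flip_fraction = 0, ...),
                             outcome_stream = outcome_stream)
  orient_to_exposure(harmonize(sim$exposure, sim$outcome))
}

# canonical single-variant association row
assoc_row <- function(id, ea, oa, beta, se = 0.01, eaf = 0.3,
                      pvalue = 1e-10, n = 1e5) {
  tibble::tibble(variant_id = id, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}
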