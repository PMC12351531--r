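# Independent numerical oracles (quadrature, brute-force grids) and shared
# fixtures for the test suite.

# quadrature moments of Beta(f | mu+1, la+1)
quad_mean <- function(mu, la) {
  stats::integrate(function(f) f * stats::dbeta(f, mu + 1, la + 1),
                   0, 1, rel.tol = 1e-12)$value
}

quad_var <- function(mu, la) {
  m <- quad_mean(mu, la)
  stats::integrate(function(f) (f - m)^2 * stats::dbeta(f, mu + 1, la + 1),
                   0, 1, rel.tol = 1e-12)$value
}

# quadrature KL divergence between two beta beliefs
quad_kl <- function(p, q) {
  stats::integrate(function(f) {
    lp <- stats::dbeta(f, p[1] + 1, p[2] + 1, log = TRUE)
    lq <- stats::dbeta(f, q[1] + 1, q[2] + 1, log = TRUE)
    exp(lp) * (lp - lq)
  }, 0, 1, rel.tol = 1e-10)$value
}

# mixture expectations of ln f and ln(1 - f) by quadrature
quad_mix_suffstats <- function(weights, comps) {
  dens <- function(f) {
    out <- 0
    for (i in seq_along(weights))
      out <- out + weights[i] * stats::dbeta(f, comps[[i]][1] + 1, comps[[i]][2] + 1)
    out
  }
  c(
    stats::integrate(function(f) log(f) * dens(f), 0, 1, rel.tol = 1e-10)$value,
    stats::integrate(function(f) log(1 - f) * dens(f), 0, 1, rel.tol = 1e-10)$value
  )
}

# brute-force grid minimizer of KL(mixture || Beta(mu+1, la+1)). Up to an
# additive constant (the mixture entropy) the KL equals
#   -(mu * T1 + la * T2 - log B(mu+1, la+1))
# with T1 = E_mix[ln f], T2 = E_mix[ln(1-f)] computed by quadrature.
brute_compress <- function(weights, comps, grid = seq(0, 30, by = 0.25)) {
  ss <- quad_mix_suffstats(weights, comps)
  best <- c(NA, NA)
  best_val <- Inf
  for (mu in grid) for (la in grid) {
    val <- -(mu * ss[1] + la * ss[2] - lbeta(mu + 1, la + 1))
    if (val < best_val) {
      best_val <- val
      best <- c(mu, la)
    }
  }
  best
}

standard_roster <- function() {
  agent_roster(c("black", "cyan", "red"), c(0.97, 0.80, 0.14))
}

special_roster <- function(strategy) {
  agent_roster(c("black", "cyan", "red"), c(0.97, 0.80, 0),
               c("ordinary", "ordinary", strategy))
}

# batches are expensive; share them between test files
.rg_test_cache <- new.env(parent = emptyenv())

cached_batch <- function(strategy, n_runs = 200, seed0 = 1) {
  key <- paste(strategy, n_runs, seed0, sep = "_")
  if (is.null(.rg_test_cache[[key]])) {
    .rg_test_cache[[key]] <- run_learning_batch(strategy, n_runs = n_runs,
                                                seed0 = seed0)
  }
  .rg_test_cache[[key]]
}
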