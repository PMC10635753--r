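chain3 <- function() {
  list(cd = count_data(c("a", "b", "c"), c(1, 2, 3), c(2, 2, 2)),
       w = spatial_weights(c("a", "b", "c"), list(2L, c(1L, 3L), 2L)))
}

test_that("MCMC schedule bookkeeping", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iter, 500000L)
  expect_equal(cfg$thin, 20L)
  expect_equal(cfg$burn_in_fraction, 0.6)
  expect_equal(cfg$n_chains, 1L)
  expect_equal(cfg$n_keep, 10000L)
  # a schedule keeping fewer than 100 draws is rejected before sampling
  expect_error(mcmc_config(n_iter = 1000, thin = 20, burn_in_fraction = 0.9),
               "at least 100")
})

test_that("log posterior matches direct arithmetic at the null state", {
  f <- chain3()
  O <- f$cd$observed; E <- f$cd$expected
  st <- bym_state(alpha = 0, u = rep(0, 3), v = rep(0, 3),
                  tau_u = 1.5, tau_v = 2.5)
  got <- bym_log_posterior(st, f$cd, f$w)
  # independent evaluation, term by term (rank of a 3-chain ICAR = 2)
  pois <- sum(O * log(E) - E - lgamma(O + 1))
  icar <- 0.5 * 2 * (log(1.5) - log(2 * pi))
  vterm <- 3 * (-0.5 * log(2 * pi) + 0.5 * log(2.5))
  hyp <- dgamma(1.5, 0.5, rate = 5e-4, log = TRUE) +
    dgamma(2.5, 0.5, rate = 5e-4, log = TRUE)
  expect_equal(got, pois + icar + vterm + hyp, tolerance = 1e-12)
})

test_that("ICAR kernel contributes -(tau_u/2)(2c)^2 for one linked pair", {
  cd <- count_data(c("a", "b"), c(4, 4), c(4, 4))
  w <- spatial_weights(c("a", "b"), list(2L, 1L))
  tau_u <- 3; cval <- 0.7
  base <- bym_state(0, c(0, 0), c(0, 0), tau_u, 1)
  tilt <- bym_state(0, c(cval, -cval), c(0, 0), tau_u, 1)
  # difference = Poisson-likelihood change + structured-kernel change
  dpois_diff <- sum(dpois(cd$observed, cd$expected * exp(c(cval, -cval)),
                          log = TRUE)) -
    sum(dpois(cd$observed, cd$expected, log = TRUE))
  expect_equal(bym_log_posterior(tilt, cd, w) - bym_log_posterior(base, cd, w),
               dpois_diff - (tau_u / 2) * (2 * cval)^2, tolerance = 1e-12)
})

test_that("sum-to-zero recentering leaves relative risks unchanged", {
  shift <- 0.9
  a <- bym_state(0.2, c(0.3, -0.1, -0.2) + shift, c(0, 0.1, -0.1), 1, 1)
  b <- bym_state(0.2 + shift, c(0.3, -0.1, -0.2), c(0, 0.1, -0.1), 1, 1)
  expect_equal(sum(a$u), 0, tolerance = 1e-12)
  expect_equal(a$alpha + a$u + a$v, b$alpha + b$u + b$v, tolerance = 1e-12)
})

test_that("islands block the BYM stage unless explicitly allowed", {
  cd <- count_data(c("a", "b", "c"), c(1, 2, 3), c(2, 2, 2))
  w <- spatial_weights(c("a", "b", "c"), list(2L, 1L, integer(0)))
  st <- bym_state(0, rep(0, 3), rep(0, 3), 1, 1)
  expect_error(bym_log_posterior(st, cd, w), "apply_manual_links")
  expect_error(fit_bym(cd, w, mcmc_config(n_iter = 2000, thin = 1,
                                          burn_in_fraction = 0.5)),
               "island")
  expect_silent(got <- bym_log_posterior(st, cd, w, allow_islands = TRUE))
  expect_true(is.finite(got))
})

test_that("conjugate precision draws follow the analytic Gamma", {
  set.seed(101)
  v <- rnorm(16, 0, 0.5)
  a <- 0.5; b <- 5e-4
  draws <- replicate(10000, draw_tau_v_cpp(v, a, b))
  analytic_mean <- (a + 8) / (b + sum(v^2) / 2)
  expect_lt(abs(mean(draws) / analytic_mean - 1), 0.02)

  # structured precision: rank-aware shape, pairwise-difference rate
  f <- chain3()
  u <- c(0.4, -0.1, -0.3)
  arr <- bymap:::adjacency_arrays(f$w)
  draws_u <- replicate(10000, draw_tau_u_cpp(u, arr$adj, arr$adj_start,
                                             arr$island, a, b, arr$icar_rank))
  quad <- (u[1] - u[2])^2 + (u[2] - u[3])^2
  expect_lt(abs(mean(draws_u) / ((a + 1) / (b + quad / 2)) - 1), 0.02)
})

test_that("a Gibbs sweep is deterministic under a fixed seed", {
  f <- chain3()
  st <- bym_state(0.1, c(0.2, -0.1, -0.1), c(0.05, 0, -0.05), 1, 1)
  s1 <- gibbs_sweep(st, f$cd, f$w, seed = 42)
  s2 <- gibbs_sweep(st, f$cd, f$w, seed = 42)
  expect_identical(s1, s2)
  expect_equal(sum(s1$u), 0, tolerance = 1e-9)
  expect_gt(s1$tau_u, 0)
})

test_that("huge structured precision pulls u toward neighbor means", {
  lat <- make_lattice(4, 4)
  w <- build_rook_adjacency(lat)
  cd <- count_data(lat$area_id, rep(50L, 16), rep(50, 16))
  set.seed(5)
  u0 <- rnorm(16, 0, 1)
  st <- bym_state(0, u0, rep(0, 16), tau_u = 1e6, tau_v = 1)
  dev_max <- function(s) {
    max(abs(vapply(seq_len(16), function(i) {
      s$u[i] - mean(s$u[w$neighbours[[i]]])
    }, numeric(1))))
  }
  d0 <- dev_max(st)
  out <- gibbs_sweep(st, cd, w, n_sweeps = 200, fix_tau = TRUE, seed = 6,
                     steps = list(alpha = 0.05, u = rep(0.05, 16),
                                  v = rep(0.05, 16)))
  expect_lt(dev_max(out), d0 / 5)
})

test_that("fitting is deterministic and smooths toward the field", {
  lat <- make_lattice(4, 4)
  w <- build_rook_adjacency(lat)
  set.seed(9)
  O <- rpois(16, 50)
  cd <- count_data(lat$area_id, O, rep(50, 16))
  cfg <- mcmc_config(n_iter = 6000, thin = 2, burn_in_fraction = 0.5, seed = 3)
  f1 <- fit_bym(cd, w, cfg)
  f2 <- fit_bym(cd, w, cfg)
  expect_identical(f1$draws$theta, f2$draws$theta)   # bit-identical kept draws
  expect_equal(nrow(f1$draws$theta), cfg$n_keep)
  # smoothing: posterior medians vary less than raw ratios
  expect_lte(var(f1$summary$median_rr), var(f1$summary$raw_ratio))
  # credible interval brackets the median
  expect_true(all(f1$summary$ci_low <= f1$summary$median_rr &
                    f1$summary$median_rr <= f1$summary$ci_high))
})

test_that("a flat-truth lattice yields near-1 medians and no significance", {
  lat <- make_lattice(4, 4)
  w <- build_rook_adjacency(lat)
  O <- simulate_counts(rep(50, 16), rep(1, 16), seed = 21)
  cd <- count_data(lat$area_id, O, rep(50, 16))
  fit <- fit_bym(cd, w, mcmc_config(n_iter = 20000, thin = 4,
                                    burn_in_fraction = 0.5, seed = 22))
  expect_true(all(abs(fit$summary$median_rr - 1) < 0.1))
  expect_true(all(fit$summary$significance == "none"))
})

test_that("an extreme raw ratio is shrunk by the smoothing prior", {
  lat <- make_lattice(4, 4)
  w <- build_rook_adjacency(lat)
  O <- rep(50L, 16); E <- rep(50, 16)
  O[6] <- 3L; E[6] <- 0.5    # raw ratio 6 on a tiny expected count
  cd <- count_data(lat$area_id, O, E)
  fit <- fit_bym(cd, w, mcmc_config(n_iter = 20000, thin = 4,
                                    burn_in_fraction = 0.5, seed = 8))
  expect_lt(fit$summary$median_rr[6], 6)
})

test_that("significance follows the credible-interval rule", {
  expect_equal(classify_significance(2.14, 3.15), "high")
  expect_equal(classify_significance(1.04, 1.59), "high")
  expect_equal(classify_significance(0.80, 1.20), "none")
  expect_equal(classify_significance(0.62, 0.95), "low")
  expect_equal(classify_significance(c(2.14, 0.8), c(3.15, 1.2)),
               c("high", "none"))
})

test_that("risk bands split at the state average and at double it", {
  expect_equal(risk_band(2.61), "above_100pct")
  expect_equal(risk_band(1.29), "above_average_within_100pct")
  expect_equal(risk_band(1.00), "at_or_below_average")
  expect_equal(risk_band(2.00), "above_average_within_100pct")
  expect_equal(risk_band(c(0.5, 1.5, 3)),
               c("at_or_below_average", "above_average_within_100pct",
                 "above_100pct"))
  expect_error(risk_band(0))
})
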