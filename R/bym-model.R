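#' MCMC schedule configuration
#'
#' Defaults follow the single-chain schedule customary in registry-based
#' disease mapping: 500,000 iterations with the first 60% discarded as
#' burn-in and every 20th post-burn-in draw kept, yielding exactly 10,000
#' retained samples. The kept-sample count
#' `floor(n_iter * (1 - burn_in_fraction) / thin)` must be at least 100.
#'
#' @param n_iter total MCMC iterations.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param burn_in_fraction fraction of iterations discarded as burn-in.
#' @param n_chains number of independent chains (default 1).
#' @param seed RNG seed.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 500000L, thin = 20L, burn_in_fraction = 0.6,
                        n_chains = 1L, seed = 1L) {
  stopifnot(n_iter >= 1, thin >= 1, n_chains >= 1,
            burn_in_fraction > 0, burn_in_fraction < 1)
  n_burn <- round(n_iter * burn_in_fraction)
  n_keep <- floor((n_iter - n_burn) / thin)
  if (n_keep < 100) {
    stop("configuration keeps only ", n_keep,
         " samples; at least 100 required (raise n_iter or lower thin)")
  }
  structure(list(n_iter = as.integer(n_iter), thin = as.integer(thin),
                 burn_in_fraction = burn_in_fraction,
                 n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Hyperprior settings for the BYM precisions
#'
#' Both precisions get Gamma(shape, rate) priors; the conventional
#' disease-mapping default Gamma(0.5, 0.0005) is vague on the standard
#' deviation scale.
#'
#' @param shape_u,rate_u Gamma prior for the structured precision tau_u.
#' @param shape_v,rate_v Gamma prior for the unstructured precision tau_v.
#' @return list of hyperprior parameters.
#' @export
bym_hyperpriors <- function(shape_u = 0.5, rate_u = 0.0005,
                            shape_v = 0.5, rate_v = 0.0005) {
  stopifnot(shape_u > 0, rate_u > 0, shape_v > 0, rate_v > 0)
  list(shape_u = shape_u, rate_u = rate_u, shape_v = shape_v, rate_v = rate_v)
}

#' BYM parameter state
#'
#' Bundles one point of the model's parameter space: log baseline relative
#' risk `alpha`, sum-to-zero spatially structured effects `u`, unstructured
#' effects `v` and the two precisions. The per-area relative risk is
#' `theta_i = exp(alpha + u_i + v_i)`.
#'
#' @param alpha log baseline relative risk.
#' @param u spatially structured effects (recentered to sum to zero; the
#'   mean is absorbed into `alpha`).
#' @param v unstructured effects.
#' @param tau_u,tau_v positive precisions.
#' @return object of class `bym_state`.
#' @export
bym_state <- function(alpha, u, v, tau_u, tau_v) {
  stopifnot(length(u) == length(v), tau_u > 0, tau_v > 0,
            is.finite(alpha), all(is.finite(u)), all(is.finite(v)))
  m <- mean(u)
  structure(list(alpha = alpha + m, u = u - m, v = v,
                 tau_u = tau_u, tau_v = tau_v),
            class = "bym_state")
}

# Flatten a binary weights object into CSR-style arrays for the C++ core.
# Islands get deg_prior 1 (proper N(0, 1/tau_u) fallback) when allowed.
adjacency_arrays <- function(w, allow_islands = FALSE) {
  if (w$style != "binary") stop("BYM model requires binary contiguity weights")
  n <- length(w$area_id)
  if (length(w$islands) > 0 && !allow_islands) {
    stop("weights contain island area(s) with no neighbor: ",
         paste(w$area_id[w$islands], collapse = ", "),
         ". Connect them with apply_manual_links(), or set",
         " allow_islands = TRUE to give islands an independent normal prior.")
  }
  deg <- lengths(w$neighbours)
  island <- deg == 0L
  comp <- graph_components(w)
  rank <- n - max(comp) + sum(island)
  list(
    adj = as.integer(unlist(w$neighbours, use.names = FALSE) - 1L),
    adj_start = as.integer(c(0L, cumsum(deg))),
    deg_prior = as.numeric(ifelse(island, 1, deg)),
    island = island,
    icar_rank = as.integer(rank)
  )
}

#' Log unnormalized posterior density of the BYM model
#'
#' Poisson likelihood O_i ~ Poisson(E_i exp(alpha + u_i + v_i)); intrinsic
#' CAR kernel -(tau_u/2) * sum over neighbor pairs of (u_i - u_j)^2 for the
#' structured effects (with the normalizing power tau_u^(rank/2)); iid
#' N(0, 1/tau_v) for the unstructured effects; flat prior on alpha; Gamma
#' hyperpriors on both precisions.
#'
#' @param state a [bym_state()].
#' @param counts a [count_data()] object.
#' @param weights binary symmetric [spatial_weights()].
#' @param hyper hyperpriors from [bym_hyperpriors()].
#' @param allow_islands if `TRUE`, islands are given an independent
#'   N(0, 1/tau_u) structured-effect prior instead of aborting.
#' @return log of the unnormalized joint density (finite for finite states).
#' @export
bym_log_posterior <- function(state, counts, weights,
                              hyper = bym_hyperpriors(),
                              allow_islands = FALSE) {
  stopifnot(inherits(state, "bym_state"), inherits(counts, "count_data"),
            inherits(weights, "spatial_weights"))
  arr <- adjacency_arrays(weights, allow_islands)
  n <- length(counts$area_id)
  stopifnot(length(state$u) == n)
  eta <- state$alpha + state$u + state$v
  loglik <- sum(stats::dpois(counts$observed, counts$expected * exp(eta),
                             log = TRUE))
  quad <- 0
  for (i in seq_len(n)) {
    if (arr$island[i]) {
      quad <- quad + state$u[i]^2
    } else {
      nb <- weights$neighbours[[i]]
      nb <- nb[nb > i]
      if (length(nb)) quad <- quad + sum((state$u[i] - state$u[nb])^2)
    }
  }
  log_icar <- 0.5 * arr$icar_rank * (log(state$tau_u) - log(2 * pi)) -
    0.5 * state$tau_u * quad
  log_v <- sum(stats::dnorm(state$v, 0, 1 / sqrt(state$tau_v), log = TRUE))
  log_hyper <- stats::dgamma(state$tau_u, hyper$shape_u, rate = hyper$rate_u,
                             log = TRUE) +
    stats::dgamma(state$tau_v, hyper$shape_v, rate = hyper$rate_v, log = TRUE)
  loglik + log_icar + log_v + log_hyper
}

#' One (or more) Metropolis-within-Gibbs sweeps
#'
#' A full sweep updates, in order: every structured effect u_i (random-walk
#' Metropolis against its ICAR full conditional, whose prior mean is the
#' neighbor average and prior variance 1/(tau_u * m_i)); the sum-to-zero
#' recentering of u with alpha absorbing the mean; every unstructured
#' effect v_i; alpha; then the two precisions by their conjugate Gamma full
#' conditionals. Deterministic given the RNG state (`set.seed()` before
#' calling, or pass `seed`).
#'
#' @inheritParams bym_log_posterior
#' @param n_sweeps number of consecutive sweeps to run.
#' @param steps optional list of proposal standard deviations
#'   (`alpha` scalar, `u` and `v` vectors); default 0.1 everywhere.
#' @param fix_tau if `TRUE`, the precisions stay at their values in
#'   `state`.
#' @param seed optional seed applied before sweeping.
#' @return the updated [bym_state()].
#' @export
gibbs_sweep <- function(state, counts, weights, hyper = bym_hyperpriors(),
                        n_sweeps = 1L, steps = NULL, fix_tau = FALSE,
                        allow_islands = FALSE, seed = NULL) {
  stopifnot(inherits(state, "bym_state"), inherits(counts, "count_data"))
  arr <- adjacency_arrays(weights, allow_islands)
  n <- length(counts$area_id)
  if (is.null(steps)) steps <- list(alpha = 0.1, u = rep(0.1, n), v = rep(0.1, n))
  if (!is.null(seed)) set.seed(seed)
  res <- bym_run_cpp(
    as.numeric(counts$observed), counts$expected,
    arr$adj, arr$adj_start, arr$deg_prior, arr$island,
    n_iter = as.integer(n_sweeps), n_burn = as.integer(n_sweeps),
    thin = 1L, n_keep = 0L,
    a_u = hyper$shape_u, b_u = hyper$rate_u,
    a_v = hyper$shape_v, b_v = hyper$rate_v,
    fix_tau = fix_tau, icar_rank = arr$icar_rank,
    alpha0 = state$alpha, u0 = state$u, v0 = state$v,
    tau_u0 = state$tau_u, tau_v0 = state$tau_v,
    step0_u = steps$u, step0_v = steps$v, step0_alpha = steps$alpha,
    adapt = FALSE)
  fs <- res$final_state
  bym_state(fs$alpha, fs$u, fs$v, fs$tau_u, fs$tau_v)
}

#' Fit the BYM model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler under the given schedule,
#' discards burn-in, thins, and summarizes the kept relative-risk draws per
#' area by the posterior median and the equal-tailed 95% credible interval
#' (2.5th / 97.5th percentiles). Significance and risk-band classification
#' follow [classify_significance()] and [risk_band()]. Proposal step sizes
#' adapt toward 30-50% acceptance during burn-in and are frozen afterwards.
#'
#' @param counts a [count_data()] object.
#' @param weights binary symmetric [spatial_weights()] aligned with
#'   `counts` (no unresolved islands unless `allow_islands`).
#' @param config an [mcmc_config()].
#' @param hyper hyperpriors from [bym_hyperpriors()].
#' @param fix_tau optional list `list(tau_u =, tau_v =)` holding both
#'   precisions fixed (used for validation against exact posteriors).
#' @param allow_islands give island areas an independent N(0, 1/tau_u)
#'   structured prior instead of aborting; intended only as a fallback,
#'   the auditable route is [apply_manual_links()].
#' @param monitor_theta number of randomly chosen per-area risks added to
#'   the convergence report alongside alpha, tau_u and tau_v.
#' @return object of class `bym_fit`: list with `draws` (kept `theta`
#'   matrix, `alpha`, `tau_u`, `tau_v`, `chain`), `summary` (per-area data
#'   frame), `diagnostics` (Geweke report, acceptance rates) and `config`.
#' @export
fit_bym <- function(counts, weights, config = mcmc_config(),
                    hyper = bym_hyperpriors(), fix_tau = NULL,
                    allow_islands = FALSE, monitor_theta = 3L) {
  stopifnot(inherits(counts, "count_data"), inherits(config, "mcmc_config"))
  if (!identical(counts$area_id, weights$area_id)) {
    stop("counts and weights must list the same areas in the same order")
  }
  arr <- adjacency_arrays(weights, allow_islands)
  n <- length(counts$area_id)
  fixed <- !is.null(fix_tau)
  tau_u0 <- if (fixed) fix_tau$tau_u else 1
  tau_v0 <- if (fixed) fix_tau$tau_v else 1
  alpha0 <- log(sum(counts$observed) / sum(counts$expected))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- bym_run_cpp(
      as.numeric(counts$observed), counts$expected,
      arr$adj, arr$adj_start, arr$deg_prior, arr$island,
      n_iter = config$n_iter, n_burn = config$n_burn,
      thin = config$thin, n_keep = config$n_keep,
      a_u = hyper$shape_u, b_u = hyper$rate_u,
      a_v = hyper$shape_v, b_v = hyper$rate_v,
      fix_tau = fixed, icar_rank = arr$icar_rank,
      alpha0 = alpha0, u0 = rep(0, n), v0 = rep(0, n),
      tau_u0 = tau_u0, tau_v0 = tau_v0,
      step0_u = rep(0.1, n), step0_v = rep(0.1, n), step0_alpha = 0.1,
      adapt = TRUE)
  }

  draws <- list(
    theta = do.call(rbind, lapply(chains, `[[`, "theta")),
    alpha = unlist(lapply(chains, `[[`, "alpha")),
    tau_u = unlist(lapply(chains, `[[`, "tau_u")),
    tau_v = unlist(lapply(chains, `[[`, "tau_v")),
    chain = rep(seq_len(config$n_chains), each = config$n_keep)
  )
  colnames(draws$theta) <- counts$area_id

  med <- apply(draws$theta, 2, stats::median)
  ci <- apply(draws$theta, 2, stats::quantile, probs = c(0.025, 0.975))
  summary_df <- data.frame(
    area_id = counts$area_id,
    observed = counts$observed,
    expected = counts$expected,
    raw_ratio = counts$observed / counts$expected,
    median_rr = unname(med),
    ci_low = unname(ci[1, ]),
    ci_high = unname(ci[2, ]),
    significance = classify_significance(ci[1, ], ci[2, ]),
    risk_band = risk_band(med),
    stringsAsFactors = FALSE
  )

  # convergence report on chain 1, mirroring a single-chain workflow
  th1 <- chains[[1]]
  mon_idx <- sort(sample.int(n, min(monitor_theta, n)))
  mon <- cbind(alpha = th1$alpha, tau_u = th1$tau_u, tau_v = th1$tau_v,
               th1$theta[, mon_idx, drop = FALSE])
  colnames(mon)[-(1:3)] <- paste0("theta[", counts$area_id[mon_idx], "]")
  if (fixed) mon <- mon[, !(colnames(mon) %in% c("tau_u", "tau_v")), drop = FALSE]
  gz <- vapply(seq_len(ncol(mon)), function(j) {
    tryCatch(geweke_diagnostic(mon[, j]), error = function(e) NA_real_)
  }, numeric(1))
  diagnostics <- list(
    geweke = data.frame(parameter = colnames(mon), z = gz,
                        converged = abs(gz) < 1.96,
                        stringsAsFactors = FALSE),
    acceptance = th1$acceptance,
    monitored_areas = counts$area_id[mon_idx]
  )

  structure(list(draws = draws, summary = summary_df,
                 diagnostics = diagnostics, config = config,
                 hyper = hyper, fix_tau = fix_tau),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM fit:", nrow(x$summary), "areas,",
      length(x$draws$alpha), "kept draws",
      sprintf("(%d chain%s)\n", x$config$n_chains,
              if (x$config$n_chains > 1) "s" else ""))
  cat("  significance: high =", sum(x$summary$significance == "high"),
      ", low =", sum(x$summary$significance == "low"), "\n")
  cat("  acceptance: alpha =", sprintf("%.2f", x$diagnostics$acceptance$alpha),
      ", u =", sprintf("%.2f", x$diagnostics$acceptance$u),
      ", v =", sprintf("%.2f", x$diagnostics$acceptance$v), "\n")
  bad <- x$diagnostics$geweke$parameter[!x$diagnostics$geweke$converged]
  if (length(bad)) cat("  Geweke |z| >= 1.96 for:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Credible-interval significance classification
#'
#' An area is significantly high-risk when the lower limit of its 95%
#' credible interval exceeds 1 (the state average), significantly low-risk
#' when the upper limit is below 1, otherwise not significant.
#'
#' @param ci_low,ci_high credible-interval limits.
#' @return character vector: `"high"`, `"low"` or `"none"`.
#' @export
classify_significance <- function(ci_low, ci_high) {
  ifelse(ci_low > 1, "high", ifelse(ci_high < 1, "low", "none"))
}

#' Risk-band classification of smoothed relative risks
#'
#' Bands used for choropleth fills: at or below the state average
#' (median RR <= 1), between 1% and 100% above average (1 < RR <= 2), and
#' more than 100% above average (RR > 2).
#'
#' @param median_rr positive median relative risks.
#' @return character vector of band labels.
#' @export
risk_band <- function(median_rr) {
  stopifnot(all(median_rr > 0))
  ifelse(median_rr <= 1, "at_or_below_average",
         ifelse(median_rr <= 2, "above_average_within_100pct", "above_100pct"))
}

#' Write a per-area posterior summary as CSV
#'
#' @param fit a [fit_bym()] result (or its `summary` data frame).
#' @param path output path.
#' @param seed,config_hash optional provenance fields recorded as comment
#'   header lines.
#' @export
write_bym_summary <- function(fit, path, seed = NULL, config_hash = NULL) {
  df <- if (inherits(fit, "bym_fit")) fit$summary else fit
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config_hash)) writeLines(paste0("# config: ", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
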