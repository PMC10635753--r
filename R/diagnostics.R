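#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac_first` of a chain with the mean of
#' the last `frac_last` by a two-sample z-score whose denominator uses each
#' segment's spectral density at frequency zero (a Bartlett-windowed
#' autocovariance estimate), so autocorrelation within segments is
#' accounted for. |z| < 1.96 is the conventional "no evidence against
#' convergence" gate.
#'
#' @param chain numeric vector of kept draws of one scalar (length >= 100).
#' @param frac_first fraction of the chain forming the early window.
#' @param frac_last fraction forming the late window.
#' @return the z-score (a single number).
#' @export
geweke_diagnostic <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  chain <- as.numeric(chain)
  if (length(chain) < 100) {
    stop("chain too short for the Geweke diagnostic (need >= 100, got ",
         length(chain), ")")
  }
  if (stats::var(chain) == 0) stop("constant chain: zero variance")
  n <- length(chain)
  first <- chain[seq_len(floor(frac_first * n))]
  last <- chain[seq.int(n - floor(frac_last * n) + 1L, n)]
  v1 <- spectrum0_bartlett(first) / length(first)
  v2 <- spectrum0_bartlett(last) / length(last)
  (mean(first) - mean(last)) / sqrt(v1 + v2)
}

# Spectral density of a series at frequency zero via a Bartlett
# (triangular) autocovariance window of width ~ sqrt(length): the sum of
# down-weighted autocovariances out to lag K. Non-negative by construction
# of the window; falls back to the lag-0 autocovariance if the estimate
# degenerates.
spectrum0_bartlett <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  K <- max(1L, floor(sqrt(n)))
  ac <- stats::acf(x, lag.max = K, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  wts <- 1 - seq_len(K) / (K + 1)
  s2 <- ac[1] + 2 * sum(wts * ac[-1])
  if (s2 <= 0) ac[1] else s2
}

#' Autocorrelation of a chain
#'
#' @param chain numeric vector.
#' @param max_lag largest lag to report.
#' @return numeric vector of autocorrelations at lags `0:max_lag`
#'   (lag 0 is exactly 1).
#' @export
autocorrelation <- function(chain, max_lag = 40) {
  chain <- as.numeric(chain)
  if (stats::var(chain) == 0) stop("constant chain: autocorrelation undefined")
  a <- stats::acf(chain, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  stats::setNames(a, 0:max_lag)
}

#' Export trace, density and autocorrelation views of kept draws
#'
#' Writes a long-format CSV (`parameter, iteration, value`) plus one PNG of
#' trace, density and autocorrelation panels per monitored parameter.
#'
#' @param draws named list or data frame of kept scalar chains (e.g.
#'   `alpha`, `tau_u`, `tau_v` from a [fit_bym()] result).
#' @param path directory to write into (created if missing).
#' @param max_lag autocorrelation horizon.
#' @return invisibly, the paths written.
#' @export
trace_density_export <- function(draws, path, max_lag = 40) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  draws <- as.list(draws)
  draws <- draws[vapply(draws, is.numeric, logical(1))]
  long <- do.call(rbind, lapply(names(draws), function(p) {
    data.frame(parameter = p, iteration = seq_along(draws[[p]]),
               value = as.numeric(draws[[p]]), stringsAsFactors = FALSE)
  }))
  csv <- file.path(path, "kept_draws.csv")
  utils::write.csv(long, csv, row.names = FALSE)
  pngs <- character(0)
  for (p in names(draws)) {
    x <- as.numeric(draws[[p]])
    f <- file.path(path, paste0("diag_", gsub("[^A-Za-z0-9_.-]", "_", p), ".png"))
    grDevices::png(f, width = 900, height = 320)
    op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
    graphics::plot(x, type = "l", xlab = "kept iteration", ylab = p,
                   main = paste("trace:", p))
    graphics::plot(stats::density(x), main = paste("density:", p))
    if (stats::var(x) > 0) {
      a <- autocorrelation(x, max_lag)
      graphics::plot(as.integer(names(a)), a, type = "h", xlab = "lag",
                     ylab = "acf", main = paste("autocorrelation:", p))
      graphics::abline(h = 0)
    }
    graphics::par(op)
    grDevices::dev.off()
    pngs <- c(pngs, f)
  }
  invisible(c(csv, pngs))
}
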