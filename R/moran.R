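#' Global Moran's I
#'
#' I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the deviations
#' from the mean and S0 the total weight. With row-standardized weights the
#' spatial lag is the neighbor mean and S0 equals the number of non-island
#' rows. Expectation under no spatial autocorrelation is -1/(n-1).
#'
#' @param values per-area numeric vector (e.g. median smoothed SIR).
#' @param weights a row-standardized [spatial_weights()] object.
#' @return Moran's I (single number).
#' @export
global_moran <- function(values, weights) {
  mp <- moran_prep(values, weights)
  (mp$n / mp$S0) * sum(mp$z * mp$lag) / sum(mp$z^2)
}

moran_prep <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (weights$style != "row_standardized") {
    stop("Moran statistics require row-standardized weights; see row_standardize()")
  }
  n <- length(values)
  if (n != length(weights$area_id)) stop("values and weights length mismatch")
  if (n < 3) stop("need at least 3 areas")
  if (stats::var(values) == 0) stop("values have zero variance")
  z <- values - mean(values)
  lag <- spatial_lag(z, weights)
  S0 <- sum(unlist(weights$weights, use.names = FALSE))
  list(n = n, z = z, lag = lag, S0 = S0)
}

#' Spatial lag of a vector
#'
#' @param x per-area numeric vector.
#' @param weights a [spatial_weights()] object.
#' @return per-area weighted sum of neighbor values (0 for islands).
#' @export
spatial_lag <- function(x, weights) {
  vapply(seq_along(x), function(i) {
    nb <- weights$neighbours[[i]]
    if (length(nb) == 0) 0 else sum(weights$weights[[i]] * x[nb])
  }, numeric(1))
}

#' Monte-Carlo permutation test for global Moran's I
#'
#' Values are randomly relabeled across areas; the pseudo p-value is
#' (number of permuted statistics at least as extreme + 1) / (n_perm + 1),
#' one-sided toward the observed deviation from the expectation -1/(n-1).
#'
#' @inheritParams global_moran
#' @param n_perm number of random permutations (default 99,999, giving a
#'   minimum attainable p of 1e-5).
#' @param seed RNG seed (results are reproducible given the seed).
#' @param keep_permutations retain the permuted statistics in the result.
#' @return object of class `moran_test` with elements `I`, `expected_I`,
#'   `p_perm`, `n_perm`, `seed` and optionally `permuted_Is`.
#' @export
moran_permutation_test <- function(values, weights, n_perm = 99999L,
                                   seed = NULL, keep_permutations = FALSE) {
  stopifnot(n_perm >= 1)
  mp <- moran_prep(values, weights)
  obs <- (mp$n / mp$S0) * sum(mp$z * mp$lag) / sum(mp$z^2)
  if (!is.null(seed)) set.seed(seed)
  W <- weights_matrix(weights)
  denom <- sum(mp$z^2)
  scale <- mp$n / mp$S0
  perm_I <- numeric(n_perm)
  chunk <- 5000L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    ZP <- vapply(seq_len(m), function(k) mp$z[sample.int(mp$n)],
                 numeric(mp$n))
    perm_I[done + seq_len(m)] <- scale * colSums(ZP * (W %*% ZP)) / denom
    done <- done + m
  }
  e_I <- -1 / (mp$n - 1)
  p <- if (obs >= e_I) {
    (sum(perm_I >= obs) + 1) / (n_perm + 1)
  } else {
    (sum(perm_I <= obs) + 1) / (n_perm + 1)
  }
  structure(list(I = obs, expected_I = e_I, p_perm = p,
                 n_perm = as.integer(n_perm), seed = seed,
                 permuted_Is = if (keep_permutations) perm_I),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("global Moran's I = %.4f (E[I] = %.4f), pseudo p = %.5g [%d permutations]\n",
              x$I, x$expected_I, x$p_perm, x$n_perm))
  invisible(x)
}

#' Local Moran statistics (LISA)
#'
#' I_i = (z_i / m2) * lag_i with m2 = sum(z^2) / n. Quadrants follow the
#' signs of the deviation and its spatial lag: HH (high value, high
#' neighbors), LL, LH (low among highs - a spatial outlier), HL. Exact
#' zeros are treated as positive, a measure-zero tie rule. The identity
#' mean(I_i) = I holds for fully connected row-standardized weights.
#'
#' @inheritParams global_moran
#' @return data frame with `z`, `lag`, `I_local` and `quadrant` per area.
#' @export
local_moran <- function(values, weights) {
  mp <- moran_prep(values, weights)
  m2 <- sum(mp$z^2) / mp$n
  I_i <- (mp$z / m2) * mp$lag
  quad <- ifelse(mp$z >= 0,
                 ifelse(mp$lag >= 0, "HH", "HL"),
                 ifelse(mp$lag >= 0, "LH", "LL"))
  data.frame(area_id = weights$area_id, value = values, z = mp$z,
             lag = mp$lag, I_local = I_i, quadrant = quad,
             stringsAsFactors = FALSE)
}

#' LISA cluster/outlier classification with conditional permutation
#'
#' Per-area significance by conditional randomization: area i's value is
#' held fixed while the remaining values are permuted among the other
#' areas, the local statistic recomputed each time, and a one-sided pseudo
#' p-value taken toward the sign of the observed statistic. Significant
#' areas keep their quadrant as the cluster label (high_high / low_low
#' clusters, low_high / high_low spatial outliers); the rest are
#' not_significant. Islands have a zero lag, an undefined local statistic,
#' and are always not_significant. One RNG stream drives all areas in
#' fixed order, so results are reproducible given the seed.
#'
#' @inheritParams global_moran
#' @param n_perm conditional permutations per area.
#' @param alpha significance level on the pseudo p-values (default 0.05,
#'   uncorrected across areas).
#' @param seed RNG seed.
#' @return object of class `lisa_result`: a data frame with per-area
#'   `value, z, lag, I_local, p_local, quadrant, label`, plus attributes
#'   `alpha`, `n_perm`, `seed`.
#' @export
lisa_significance <- function(values, weights, n_perm = 99999L, alpha = 0.05,
                              seed = NULL) {
  stopifnot(n_perm >= 1, alpha >= 0, alpha <= 1)
  lm <- local_moran(values, weights)
  mp <- moran_prep(values, weights)
  m2 <- sum(mp$z^2) / mp$n
  n <- mp$n
  if (!is.null(seed)) set.seed(seed)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- weights$neighbours[[i]]
    k <- length(nb)
    if (k == 0) next
    wts <- weights$weights[[i]]
    zi <- mp$z[i]
    others <- mp$z[-i]
    obs <- lm$I_local[i]
    perm_stat <- vapply(seq_len(n_perm), function(r) {
      (zi / m2) * sum(wts * others[sample.int(n - 1, k)])
    }, numeric(1))
    p[i] <- if (obs >= 0) {
      (sum(perm_stat >= obs) + 1) / (n_perm + 1)
    } else {
      (sum(perm_stat <= obs) + 1) / (n_perm + 1)
    }
  }
  label_map <- c(HH = "high_high", LL = "low_low", LH = "low_high",
                 HL = "high_low")
  label <- ifelse(!is.na(p) & p <= alpha, label_map[lm$quadrant],
                  "not_significant")
  out <- cbind(lm, p_local = p, label = unname(label))
  out$label <- as.character(out$label)
  structure(out, alpha = alpha, n_perm = as.integer(n_perm), seed = seed,
            class = c("lisa_result", "data.frame"))
}

#' @export
print.lisa_result <- function(x, ...) {
  cat("LISA:", nrow(x), "areas,", sum(x$label != "not_significant"),
      "significant at alpha =", attr(x, "alpha"),
      "(", attr(x, "n_perm"), "conditional permutations )\n")
  tab <- table(x$label)
  for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write global/local Moran results as text files
#'
#' @param x a `moran_test` or `lisa_result` object.
#' @param path output file path.
#' @export
write_moran <- function(x, path) {
  if (inherits(x, "moran_test")) {
    df <- data.frame(I = x$I, expected_I = x$expected_I, p_perm = x$p_perm,
                     n_perm = x$n_perm,
                     seed = if (is.null(x$seed)) NA else x$seed)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "lisa_result")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    stop("unsupported object")
  }
  invisible(path)
}
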