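# Shared fixtures and independent oracles. Everything here is built in code
# at test time; oracles deliberately share no code path with the package
# functions they check.

# nx x ny lattice of unit squares as an area_set (built directly, not via
# simulate_geography, so geography tests do not depend on the generator).
make_lattice <- function(nx, ny, population = 1000L) {
  ids <- character(0)
  geom <- list()
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      ids <- c(ids, sprintf("c%02d_%02d", i, j))
      geom[[length(geom) + 1]] <-
        rbind(c(i - 1, j - 1), c(i, j - 1), c(i, j), c(i - 1, j), c(i - 1, j - 1))
    }
  }
  area_set(ids, geom, population_15plus = rep(population, nx * ny))
}

# Naive double-loop Moran's I on a dense weight matrix.
naive_global_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  }
  (n / sum(W)) * num / sum(z^2)
}

# Naive local Moran I_i with m2 = sum(z^2)/n.
naive_local_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) s <- s + W[i, j] * z[j]
    (z[i] / m2) * s
  }, numeric(1))
}

# Naive queen contiguity: shared snapped boundary vertex (point contact
# counts). Used only for the rook-subset-of-queen property.
naive_queen_pairs <- function(areas, snap = 1e-9) {
  n <- length(areas$area_id)
  verts <- lapply(areas$geometry, function(g) {
    pts <- do.call(rbind, lapply(g, function(poly) do.call(rbind, poly)))
    unique(paste(round(pts[, 1] / snap), round(pts[, 2] / snap)))
  })
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(verts[[i]], verts[[j]])) > 0) {
        out[i, j] <- out[j, i] <- TRUE
      }
    }
  }
  out
}

# Deterministic quadrature of the exact BYM posterior (fixed precisions,
# flat intercept) on a small graph; returns per-area posterior medians of
# theta. Marginalizes alpha, u, v into eta = alpha + u + v: flat along the
# constant direction, Gaussian (ICAR pseudo-inverse + 1/tau_v) in the
# sum-to-zero complement. Only feasible for n = 3.
quadrature_theta_medians <- function(O, E, L, tau_u, tau_v,
                                     lo = -5, hi = 2.5, step = 0.035) {
  n <- length(O)
  stopifnot(n == 3)
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > 1e-10
  Lp <- eig$vectors[, pos] %*% diag(1 / eig$values[pos]) %*%
    t(eig$vectors[, pos])
  B <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n]
  C <- t(B) %*% (Lp / tau_u) %*% B + diag(n - 1) / tau_v
  M <- B %*% solve(C) %*% t(B)
  g <- seq(lo, hi, by = step)
  ng <- length(g)
  A1 <- array(rep(g, times = ng * ng), c(ng, ng, ng))
  A2 <- array(rep(rep(g, each = ng), times = ng), c(ng, ng, ng))
  A3 <- array(rep(g, each = ng * ng), c(ng, ng, ng))
  lp <- O[1] * A1 - E[1] * exp(A1) + O[2] * A2 - E[2] * exp(A2) +
    O[3] * A3 - E[3] * exp(A3) -
    0.5 * (M[1, 1] * A1^2 + M[2, 2] * A2^2 + M[3, 3] * A3^2) -
    (M[1, 2] * A1 * A2 + M[1, 3] * A1 * A3 + M[2, 3] * A2 * A3)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  med <- function(marg) {
    cs <- cumsum(marg)
    g[which(cs >= 0.5)[1]]
  }
  exp(c(med(apply(p, 1, sum)), med(apply(p, 2, sum)), med(apply(p, 3, sum))))
}

# Registry data frame with given column vectors recycled to n rows.
make_registry <- function(n, age = 60, sex = "male", subsite = "gingiva",
                          area_id = "A", vital_status = "alive",
                          survival_months = 0, grade = NULL) {
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = rep_len(age, n), sex = rep_len(sex, n),
    subsite = rep_len(subsite, n), area_id = rep_len(area_id, n),
    vital_status = rep_len(vital_status, n),
    survival_months = rep_len(survival_months, n),
    stringsAsFactors = FALSE)
  if (!is.null(grade)) df$grade <- rep_len(grade, n)
  df
}

# Expand printed category margins into a synthetic patient table whose
# marginal counts match exactly (categories assigned independently).
expand_table_margins <- function() {
  n <- 9885
  rep_counts <- function(values, counts) rep(values, counts)
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = rep_counts(c(30, 50, 70), c(283, 4036, 5566)),
    sex = rep_counts(c("female", "male"), c(2815, 7070)),
    subsite = rep_counts(c("gingiva", "tongue base", "unknown primary"),
                         c(5151, 4578, 156)),
    area_id = "A",
    grade = rep_counts(c("well", "moderate", "poor", "undiff", "unknown"),
                       c(1140, 4888, 2359, 33, 1465)),
    vital_status = rep_counts(c("alive", "dead"), c(4026, 5859)),
    survival_months = rep_counts(c(12, 12, 48, 120),
                                 c(4026, 3482, 617, 1760)),
    stringsAsFactors = FALSE)
}
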