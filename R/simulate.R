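#' Simulation specification
#'
#' Defines the synthetic study region: an nx x ny lattice of unit-square
#' areas (plus optionally some detached island cells), the fraction of
#' areas with no resident population, the population scale, and the true
#' parameters of the log-relative-risk surface used for recovery studies
#' (baseline `alpha_true`, ICAR marginal scale `sigma_u`, unstructured
#' noise `sigma_v`).
#'
#' @param nx,ny lattice dimensions (`nx * ny >= 4`).
#' @param n_islands number of detached cells with no contiguous neighbor.
#' @param zero_pop_fraction fraction of areas assigned zero population.
#' @param base_population mean 15+ population per populated area (actual
#'   populations jittered +/-20%).
#' @param alpha_true true log baseline relative risk.
#' @param sigma_u,sigma_v true structured / unstructured effect scales.
#' @param seed RNG seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(nx = 10L, ny = 10L, n_islands = 0L,
                            zero_pop_fraction = 0, base_population = 5000L,
                            alpha_true = 0, sigma_u = 0.5, sigma_v = 0.1,
                            seed = 1L) {
  stopifnot(nx * ny >= 4, n_islands >= 0, zero_pop_fraction >= 0,
            zero_pop_fraction < 1, base_population > 0,
            sigma_u >= 0, sigma_v >= 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 n_islands = as.integer(n_islands),
                 zero_pop_fraction = zero_pop_fraction,
                 base_population = as.integer(base_population),
                 alpha_true = alpha_true, sigma_u = sigma_u,
                 sigma_v = sigma_v, seed = as.integer(seed)),
            class = "simulation_spec")
}

unit_square <- function(x0, y0) {
  rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1), c(x0, y0))
}

#' Simulate a lattice geography
#'
#' Builds an nx x ny lattice of unit squares plus `n_islands` detached
#' squares offset below the lattice (so rook adjacency finds them
#' neighborless, emulating offshore localities). `zero_pop_fraction` of all
#' areas (a deterministic count, seeded choice) get population 0; the rest
#' get `base_population` with +/-20% uniform jitter.
#'
#' @param spec a [simulation_spec()].
#' @param path optional path to also write the geography as GeoJSON.
#' @return an [area_set()].
#' @export
simulate_geography <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  ids <- character(0)
  geom <- list()
  for (j in seq_len(spec$ny)) {
    for (i in seq_len(spec$nx)) {
      ids <- c(ids, sprintf("A%03d", (j - 1) * spec$nx + i))
      geom[[length(geom) + 1]] <- unit_square(i - 1, j - 1)
    }
  }
  if (spec$n_islands > 0) {
    for (k in seq_len(spec$n_islands)) {
      ids <- c(ids, sprintf("I%02d", k))
      geom[[length(geom) + 1]] <- unit_square(2 * (k - 1), -3)
    }
  }
  n <- length(ids)
  pop <- round(spec$base_population * stats::runif(n, 0.8, 1.2))
  n_zero <- round(spec$zero_pop_fraction * n)
  if (n_zero > 0) pop[sample.int(n, n_zero)] <- 0L
  areas <- area_set(ids, geom, population_15plus = pop)
  if (!is.null(path)) write_geojson_areas(areas, path)
  areas
}

#' Exact draw from the intrinsic CAR (ICAR) distribution
#'
#' Samples the spatially structured field u on a connected graph from the
#' sum-to-zero ICAR distribution with covariance sigma_u^2 times the
#' Moore-Penrose pseudo-inverse of the graph Laplacian D - W, via
#' eigendecomposition. This is an exact, MCMC-free construction, so the
#' generator shares no code path with the fitting sampler.
#'
#' @param weights binary [spatial_weights()] on a single connected
#'   component (no islands).
#' @param sigma_u marginal scale; `0` returns the zero field.
#' @param seed RNG seed.
#' @return numeric vector u with `sum(u) == 0` (to 1e-10).
#' @export
simulate_icar_field <- function(weights, sigma_u, seed = NULL) {
  stopifnot(inherits(weights, "spatial_weights"), sigma_u >= 0)
  n <- length(weights$area_id)
  comp <- graph_components(weights)
  if (max(comp) > 1) {
    stop("ICAR field requires a connected graph; found ", max(comp),
         " components (link islands first)")
  }
  if (sigma_u == 0) return(rep(0, n))
  W <- weights_matrix(weights)
  L <- diag(rowSums(W)) - W
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  if (!is.null(seed)) set.seed(seed)
  zdraw <- stats::rnorm(sum(pos)) / sqrt(eig$values[pos])
  u <- sigma_u * as.numeric(eig$vectors[, pos, drop = FALSE] %*% zdraw)
  u - mean(u)
}

#' Poisson observation layer
#'
#' @param expected per-area expected counts E_i.
#' @param theta_true per-area true relative risks.
#' @param seed RNG seed.
#' @return integer vector O_i ~ Poisson(E_i * theta_i).
#' @export
simulate_counts <- function(expected, theta_true, seed = NULL) {
  stopifnot(length(expected) == length(theta_true), all(expected > 0),
            all(theta_true >= 0))
  if (!is.null(seed)) set.seed(seed)
  stats::rpois(length(expected), expected * theta_true)
}

#' Default registry marginal distributions
#'
#' Category probabilities emulating a large oral/oropharyngeal cancer
#' registry cohort: 71.5% male; age bands <40 / 40-64 / >=65 at
#' 2.9% / 40.8% / 56.3% (with a small mass below 15 years to exercise the
#' age exclusion); tumor site 52.1% oral cavity, 46.3% oropharynx, 1.6%
#' unspecified; 59.3% dead at follow-up; survival months for the deceased
#' geometric with rate chosen so roughly 60% of deaths fall within 36
#' months, truncated at 478 months.
#'
#' @return list of marginal parameters consumed by [simulate_registry()].
#' @export
default_registry_marginals <- function() {
  list(
    p_male = 0.715,
    age_bands = c("<40" = 0.029, "40-64" = 0.408, ">=65" = 0.563),
    p_under15 = 2 / 9887,
    site = c(oral_cavity = 0.521, oropharynx = 0.463, not_specified = 0.016),
    grade = c("well_differentiated" = 0.115, "moderately_differentiated" = 0.494,
              "poorly_differentiated" = 0.239, "undifferentiated" = 0.003,
              "unknown" = 0.149),
    p_dead = 0.593,
    survival_geom_prob = 0.024,
    survival_max = 478L
  )
}

#' Simulate patient-level registry records
#'
#' Draws independent records with the configured marginal structure: sex,
#' age band (uniform age within band; ages 15-17 are skipped, matching
#' adult oral-cancer registries), anatomical subsite label within the
#' drawn site class, grade, vital status, survival months (geometric,
#' truncated), and an area assigned proportional to population at risk.
#' Survival is generated independently of area: any spatial mortality
#' signal belongs in the relative-risk surface, not the patient layer.
#'
#' @param n_patients number of records.
#' @param areas an [area_set()] supplying area codes and populations.
#' @param marginals list from [default_registry_marginals()].
#' @param seed RNG seed.
#' @param path optional CSV path to also write the records.
#' @return registry data frame (possibly zero rows).
#' @export
simulate_registry <- function(n_patients, areas,
                              marginals = default_registry_marginals(),
                              seed = 1L, path = NULL) {
  stopifnot(inherits(areas, "area_set"), n_patients >= 0)
  set.seed(seed)
  m <- marginals
  empty <- data.frame(patient_id = character(0), age = integer(0),
                      sex = character(0), subsite = character(0),
                      area_id = character(0), grade = character(0),
                      vital_status = character(0),
                      survival_months = integer(0), stringsAsFactors = FALSE)
  if (n_patients == 0) {
    if (!is.null(path)) utils::write.csv(empty, path, row.names = FALSE)
    return(empty)
  }
  n <- n_patients
  sex <- ifelse(stats::runif(n) < m$p_male, "male", "female")
  under15 <- stats::runif(n) < m$p_under15
  band <- sample(names(m$age_bands), n, replace = TRUE, prob = m$age_bands)
  age <- integer(n)
  age[band == "<40"] <- sample(18:39, sum(band == "<40"), replace = TRUE)
  age[band == "40-64"] <- sample(40:64, sum(band == "40-64"), replace = TRUE)
  age[band == ">=65"] <- sample(65:105, sum(band == ">=65"), replace = TRUE)
  age[under15] <- sample(0:14, sum(under15), replace = TRUE)
  dict <- default_subsite_dictionary()
  site_class <- sample(names(m$site), n, replace = TRUE, prob = m$site)
  subsite <- character(n)
  for (cl in c("oral_cavity", "oropharynx")) {
    sel <- site_class == cl
    labs <- names(dict)[dict == cl]
    subsite[sel] <- sample(labs, sum(sel), replace = TRUE)
  }
  subsite[site_class == "not_specified"] <- "unknown primary"
  grade <- sample(names(m$grade), n, replace = TRUE, prob = m$grade)
  dead <- stats::runif(n) < m$p_dead
  surv <- integer(n)
  surv[dead] <- pmin(stats::rgeom(sum(dead), m$survival_geom_prob),
                     m$survival_max)
  surv[!dead] <- sample.int(m$survival_max, sum(!dead), replace = TRUE)
  pop <- areas$population_15plus
  if (sum(pop) == 0) stop("all areas have zero population; no one at risk")
  area_id <- sample(areas$area_id, n, replace = TRUE, prob = pop / sum(pop))
  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, subsite = subsite, area_id = area_id,
    grade = grade,
    vital_status = ifelse(dead, "dead", "alive"),
    survival_months = surv, stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Emit a complete demo dataset
#'
#' Writes a geography (GeoJSON), a population-at-risk table (CSV) and a
#' patient-level registry (CSV) generated from one [simulation_spec()],
#' ready to be fed back through the pipeline.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param n_patients registry size.
#' @return named character vector of the files written.
#' @export
emit_demo_dataset <- function(spec, dir, n_patients = 2000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  geo <- file.path(dir, "geography.geojson")
  popf <- file.path(dir, "population.csv")
  regf <- file.path(dir, "registry.csv")
  areas <- simulate_geography(spec, path = geo)
  utils::write.csv(
    data.frame(area_id = areas$area_id,
               population_15plus = areas$population_15plus),
    popf, row.names = FALSE)
  simulate_registry(n_patients, areas, seed = spec$seed + 1L, path = regf)
  c(geography = geo, population = popf, registry = regf)
}
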