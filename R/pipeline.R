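#' Run the full disease-mapping pipeline
#'
#' Chains every stage on registry-style inputs: geography + population +
#' patient records -> rook adjacency (with optional manual island links)
#' -> per-area observed counts for the chosen outcome stratum -> internally
#' standardized expected counts -> BYM smoothing -> significance and
#' risk-band classification -> global Moran permutation test and LISA
#' clusters on the median smoothed ratios. All outputs are written under
#' `out_dir` with the seed and a configuration hash recorded.
#'
#' @param areas an [area_set()] (or path to a GeoJSON file).
#' @param population named per-area 15+ population vector (or path to a
#'   CSV with `area_id, population_15plus`); defaults to the populations
#'   stored on `areas`.
#' @param registry registry data frame (or CSV path).
#' @param stratum outcome stratum for [aggregate_counts()].
#' @param config an [mcmc_config()].
#' @param manual_links optional island repair links for
#'   [apply_manual_links()].
#' @param allow_islands passed to [fit_bym()].
#' @param n_perm permutations for the Moran and LISA tests.
#' @param alpha LISA significance level.
#' @param out_dir optional output directory; when given, CSV/GeoJSON/PNG
#'   artifacts are written there.
#' @param min_age inclusion age threshold.
#' @return list with `areas`, `weights`, `cohort`, `counts`, `fit`,
#'   `moran`, `lisa` and `files` (paths written).
#' @export
run_pipeline <- function(areas, registry, population = NULL,
                         stratum = "incidence", config = mcmc_config(),
                         manual_links = NULL, allow_islands = FALSE,
                         n_perm = 999L, alpha = 0.05, out_dir = NULL,
                         min_age = 15) {
  if (is.character(areas)) areas <- read_geojson_areas(areas)
  if (is.character(registry)) registry <- read_registry(registry)
  if (is.character(population)) population <- read_population(population)
  if (!is.null(population)) {
    idx <- match(areas$area_id, names(population))
    if (anyNA(idx)) {
      stop("population table lacks area(s): ",
           paste(areas$area_id[is.na(idx)], collapse = ", "))
    }
    areas$population_15plus <- as.integer(population[idx])
  }

  weights <- build_rook_adjacency(areas)
  if (!is.null(manual_links)) weights <- apply_manual_links(weights, manual_links)

  filtered <- apply_age_exclusion(registry, min_age = min_age)
  cohort <- cohort_summary(filtered$included)
  observed <- aggregate_counts(filtered$included, areas, stratum = stratum)
  counts <- compute_expected(observed, areas$population_15plus,
                             area_id = areas$area_id)

  fit <- fit_bym(counts, weights, config = config,
                 allow_islands = allow_islands)

  wstd <- row_standardize(weights)
  med <- fit$summary$median_rr
  moran <- moran_permutation_test(med, wstd, n_perm = n_perm,
                                  seed = config$seed)
  lisa <- lisa_significance(med, wstd, n_perm = n_perm, alpha = alpha,
                            seed = config$seed)

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    ch <- config_hash(unclass(config))
    f <- function(name) file.path(out_dir, name)
    write_weights_gal(weights, f("adjacency.gal"))
    write_cohort_summary(cohort, f("cohort_summary.csv"))
    write_count_data(counts, f("counts.csv"))
    write_bym_summary(fit, f("bym_summary.csv"), seed = config$seed,
                      config_hash = ch)
    write_moran(moran, f("moran_global.csv"))
    write_moran(lisa, f("lisa.csv"))
    map_join(areas, fit$summary, f("map.geojson"))
    choropleth(areas, fit$summary, f("map.png"), lisa = lisa)
    trace_density_export(list(alpha = fit$draws$alpha,
                              tau_u = fit$draws$tau_u,
                              tau_v = fit$draws$tau_v),
                         f("diagnostics"))
    files <- c(adjacency = f("adjacency.gal"), cohort = f("cohort_summary.csv"),
               counts = f("counts.csv"), bym = f("bym_summary.csv"),
               moran = f("moran_global.csv"), lisa = f("lisa.csv"),
               map_geojson = f("map.geojson"), map_png = f("map.png"))
  }
  list(areas = areas, weights = weights, cohort = cohort, counts = counts,
       fit = fit, moran = moran, lisa = lisa, files = files)
}

#' Join a posterior summary onto the geography and write GeoJSON
#'
#' Each feature gains `median_rr, ci_low, ci_high, significance, risk_band`
#' properties; reading the file back recovers every column.
#'
#' @param areas an [area_set()].
#' @param summary per-area summary data frame from [fit_bym()].
#' @param path output GeoJSON path.
#' @export
map_join <- function(areas, summary, path) {
  stopifnot(inherits(areas, "area_set"))
  idx <- match(areas$area_id, summary$area_id)
  if (anyNA(idx)) stop("summary lacks area(s): ",
                       paste(areas$area_id[is.na(idx)], collapse = ", "))
  cols <- c("median_rr", "ci_low", "ci_high", "significance", "risk_band")
  write_geojson_areas(areas, path, extra_properties = summary[idx, cols])
}

#' Choropleth of smoothed relative risks
#'
#' Categorical fill by the three risk bands (at/below average, 1-100%
#' above, >100% above the state average), with significant LISA cluster
#' labels optionally hatched on top.
#'
#' @param areas an [area_set()].
#' @param summary per-area summary data frame with `risk_band`.
#' @param path PNG output path.
#' @param lisa optional [lisa_significance()] result drawn as an overlay.
#' @return `path`, invisibly.
#' @export
choropleth <- function(areas, summary, path, lisa = NULL) {
  idx <- match(areas$area_id, summary$area_id)
  band <- summary$risk_band[idx]
  fill <- c(at_or_below_average = "#d7e8f7",
            above_average_within_100pct = "#fdae61",
            above_100pct = "#d7191c")[band]
  grDevices::png(path, width = 800, height = 800)
  op <- graphics::par(mar = c(1, 1, 3, 1))
  xs <- unlist(lapply(areas$geometry, function(g) lapply(g, function(p) p[[1]][, 1])))
  ys <- unlist(lapply(areas$geometry, function(g) lapply(g, function(p) p[[1]][, 2])))
  graphics::plot(range(xs), range(ys), type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "median smoothed relative risk")
  for (i in seq_along(areas$area_id)) {
    for (poly in areas$geometry[[i]]) {
      ring <- poly[[1]]
      graphics::polygon(ring[, 1], ring[, 2], col = fill[i], border = "grey30")
    }
  }
  if (!is.null(lisa)) {
    sig <- which(lisa$label != "not_significant")
    for (i in sig) {
      for (poly in areas$geometry[[i]]) {
        ring <- poly[[1]]
        graphics::polygon(ring[, 1], ring[, 2], density = 12,
                          col = "black", border = NA)
      }
    }
  }
  graphics::legend("topright",
                   legend = c("at/below average", "1-100% above",
                              ">100% above",
                              if (!is.null(lisa)) "significant LISA"),
                   fill = c("#d7e8f7", "#fdae61", "#d7191c",
                            if (!is.null(lisa)) "black"),
                   bty = "n")
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
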