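#' Construct a set of areal units
#'
#' An `area_set` is the package's representation of the spatial units of a
#' study (e.g. local-government areas or suburbs): an identifier, a display
#' name, a resolution level, a planar polygon geometry and the population at
#' risk (persons aged 15 and over) for each unit. Geometry is stored as a
#' list with one element per area; each element is a list of polygons, and
#' each polygon a list of rings (closed n x 2 coordinate matrices, exterior
#' ring first).
#'
#' @param area_id character vector of unique area codes.
#' @param geometry list of polygon geometries, one per area (see Details).
#' @param name optional character vector of display names; defaults to
#'   `area_id`.
#' @param level `"coarse"` (LGA-like) or `"fine"` (suburb-like).
#' @param population_15plus non-negative integer vector of persons aged >= 15
#'   per area. Zero is allowed: unpopulated localities are retained and later
#'   flagged during standardization.
#' @return an object of class `area_set`.
#' @seealso [read_geojson_areas()], [build_rook_adjacency()]
#' @export
area_set <- function(area_id, geometry, name = area_id,
                     level = c("coarse", "fine"),
                     population_15plus = rep(0L, length(area_id))) {
  level <- match.arg(level)
  area_id <- as.character(area_id)
  if (anyDuplicated(area_id)) {
    dup <- unique(area_id[duplicated(area_id)])
    stop("duplicate area_id: ", paste(dup, collapse = ", "))
  }
  n <- length(area_id)
  if (length(geometry) != n) stop("geometry must have one element per area")
  if (length(name) != n) stop("name must have one element per area")
  if (length(population_15plus) != n) {
    stop("population_15plus must have one element per area")
  }
  if (any(is.na(population_15plus)) || any(population_15plus < 0)) {
    stop("population_15plus must be non-negative")
  }
  geometry <- lapply(seq_len(n), function(i) {
    g <- normalize_geometry(geometry[[i]])
    if (length(g) == 0) stop("invalid or empty geometry for area ", area_id[i])
    g
  })
  structure(
    list(area_id = area_id, name = as.character(name), level = level,
         geometry = geometry,
         population_15plus = as.integer(round(population_15plus))),
    class = "area_set"
  )
}

# Coerce a geometry element to list-of-polygons / list-of-rings / matrix.
# Accepts a bare matrix (one ring), a list of matrices (one polygon), or the
# full nested form. Rings are closed (first row repeated last) on output.
normalize_geometry <- function(g) {
  if (is.matrix(g)) g <- list(list(g))
  if (is.list(g) && length(g) > 0 && is.matrix(g[[1]])) g <- list(g)
  if (!is.list(g)) return(list())
  lapply(g, function(poly) {
    lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2) stop("rings must be n x 2 coordinate matrices")
      if (nrow(ring) < 3) stop("ring with fewer than 3 vertices")
      if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      storage.mode(ring) <- "double"
      unname(ring)
    })
  })
}

#' @export
print.area_set <- function(x, ...) {
  cat("area_set:", length(x$area_id), "areas, level =", x$level, "\n")
  cat("  population 15+:", sum(x$population_15plus),
      "(", sum(x$population_15plus == 0), "areas with zero population )\n")
  invisible(x)
}

#' @export
length.area_set <- function(x) length(x$area_id)

#' Read areal units from a GeoJSON FeatureCollection
#'
#' One feature per area; Polygon and MultiPolygon geometries are supported.
#' The area identifier is taken from a configurable property key.
#'
#' @param path path to a GeoJSON file.
#' @param id_property name of the feature property holding the area code.
#' @param name_property optional property for the display name.
#' @param population_property optional property for the 15+ population
#'   (missing values default to 0).
#' @param level resolution label stored on the result.
#' @return an [area_set()].
#' @export
read_geojson_areas <- function(path, id_property = "area_id",
                               name_property = "name",
                               population_property = "population_15plus",
                               level = c("coarse", "fine")) {
  level <- match.arg(level)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  feats <- gj$features
  if (length(feats) == 0) stop("FeatureCollection has no features")
  ids <- character(length(feats))
  nms <- character(length(feats))
  pop <- integer(length(feats))
  geom <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    props <- f$properties
    if (is.null(props[[id_property]])) {
      stop("feature ", i, " lacks the '", id_property, "' property")
    }
    ids[i] <- as.character(props[[id_property]])
    nms[i] <- as.character(props[[name_property]] %||% ids[i])
    pop[i] <- as.integer(props[[population_property]] %||% 0L)
    geom[[i]] <- geojson_to_rings(f$geometry, where = ids[i])
  }
  area_set(ids, geom, name = nms, level = level, population_15plus = pop)
}

geojson_to_rings <- function(geometry, where = "?") {
  if (is.null(geometry$type)) stop("feature '", where, "' has no geometry")
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  switch(geometry$type,
    Polygon = list(lapply(geometry$coordinates, ring_mat)),
    MultiPolygon = lapply(geometry$coordinates, function(poly) {
      lapply(poly, ring_mat)
    }),
    stop("unsupported geometry type '", geometry$type, "' for area ", where)
  )
}

#' Write areal units (plus optional per-area properties) as GeoJSON
#'
#' @param areas an [area_set()].
#' @param path output file path.
#' @param extra_properties optional data frame of additional per-area
#'   properties (one row per area, in area order) to attach to each feature,
#'   e.g. a posterior summary.
#' @return `path`, invisibly.
#' @export
write_geojson_areas <- function(areas, path, extra_properties = NULL) {
  stopifnot(inherits(areas, "area_set"))
  n <- length(areas$area_id)
  if (!is.null(extra_properties) && nrow(extra_properties) != n) {
    stop("extra_properties must have one row per area")
  }
  feats <- lapply(seq_len(n), function(i) {
    props <- list(area_id = areas$area_id[i], name = areas$name[i],
                  population_15plus = areas$population_15plus[i])
    if (!is.null(extra_properties)) {
      for (cn in names(extra_properties)) {
        val <- extra_properties[[cn]][i]
        props[[cn]] <- if (is.factor(val)) as.character(val) else val
      }
    }
    polys <- lapply(areas$geometry[[i]], function(poly) {
      lapply(poly, function(ring) {
        lapply(seq_len(nrow(ring)), function(r) as.numeric(ring[r, ]))
      })
    })
    if (length(polys) == 1) {
      geom <- list(type = "Polygon", coordinates = polys[[1]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = polys)
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
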