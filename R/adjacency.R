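#' Spatial weights objects
#'
#' A `spatial_weights` object stores the neighbor structure of a set of
#' areas: per-area neighbor index lists with non-negative weights, either
#' binary (contiguity) or row-standardized. It records which areas are
#' islands (no neighbors) and which links were added manually, so the
#' repair of disconnected units stays auditable.
#'
#' @param area_id character vector of area codes.
#' @param neighbours list of integer vectors (1-based indices into
#'   `area_id`), one per area.
#' @param weights list of numeric vectors aligned with `neighbours`; if
#'   `NULL`, binary weights of 1 are used.
#' @param style `"binary"` or `"row_standardized"`.
#' @param manual_links two-column character matrix of manually added links.
#' @return an object of class `spatial_weights`.
#' @export
spatial_weights <- function(area_id, neighbours, weights = NULL,
                            style = c("binary", "row_standardized"),
                            manual_links = NULL) {
  style <- match.arg(style)
  area_id <- as.character(area_id)
  n <- length(area_id)
  if (length(neighbours) != n) stop("one neighbour vector per area required")
  neighbours <- lapply(neighbours, function(x) sort(as.integer(x)))
  for (i in seq_len(n)) {
    nb <- neighbours[[i]]
    if (any(nb == i)) stop("area ", area_id[i], " listed as its own neighbor")
    if (any(nb < 1 | nb > n)) stop("neighbor index out of range for ", area_id[i])
  }
  if (is.null(weights)) {
    weights <- lapply(neighbours, function(x) rep(1, length(x)))
  }
  if (is.null(manual_links)) {
    manual_links <- matrix(character(0), ncol = 2)
  }
  w <- structure(
    list(area_id = area_id, neighbours = neighbours, weights = weights,
         style = style,
         islands = which(lengths(neighbours) == 0L),
         manual_links = manual_links),
    class = "spatial_weights"
  )
  check_symmetry(w)
  w
}

check_symmetry <- function(w) {
  for (i in seq_along(w$neighbours)) {
    for (j in w$neighbours[[i]]) {
      if (!(i %in% w$neighbours[[j]])) {
        stop("asymmetric adjacency: ", w$area_id[i], " ~ ", w$area_id[j],
             " but not the reverse")
      }
    }
  }
  invisible(w)
}

#' @export
print.spatial_weights <- function(x, ...) {
  nl <- sum(lengths(x$neighbours))
  cat("spatial_weights:", length(x$area_id), "areas,", nl %/% 2, "links,",
      "style =", x$style, "\n")
  cat("  islands:", length(x$islands),
      if (nrow(x$manual_links)) paste0("; manual links: ", nrow(x$manual_links)),
      "\n")
  invisible(x)
}

#' Dense weight matrix
#'
#' @param w a [spatial_weights()] object.
#' @return an n x n numeric matrix W with `W[i, j]` the weight of j as a
#'   neighbor of i (zero rows for islands).
#' @export
weights_matrix <- function(w) {
  n <- length(w$area_id)
  W <- matrix(0, n, n, dimnames = list(w$area_id, w$area_id))
  for (i in seq_len(n)) W[i, w$neighbours[[i]]] <- w$weights[[i]]
  W
}

#' Rook contiguity from polygon geometry
#'
#' Two areas are rook neighbors iff their boundaries share a linear segment
#' of strictly positive length; contact at isolated corner points does not
#' create a link. Coordinates are snapped to a regular grid before
#' comparison so that sub-tolerance slivers in digitized boundaries do not
#' break contiguity. Shared borders need not be digitized with matching
#' vertices: overlap is detected on collinear segment pairs.
#'
#' Areas with no neighbor are reported as islands and are never linked
#' automatically; use [apply_manual_links()] to connect them, mirroring the
#' manual repair step used in registry studies.
#'
#' @param areas an [area_set()].
#' @param snap snapping grid size in coordinate units (default `1e-9`).
#' @return a binary [spatial_weights()] object.
#' @export
build_rook_adjacency <- function(areas, snap = 1e-9) {
  stopifnot(inherits(areas, "area_set"))
  n <- length(areas$area_id)
  segs <- lapply(areas$geometry, area_segments, snap = snap)
  for (i in seq_len(n)) {
    if (nrow(segs[[i]]) == 0) stop("invalid geometry for area ", areas$area_id[i])
  }
  boxes <- t(vapply(segs, function(s) {
    c(min(s[, 1], s[, 3]), max(s[, 1], s[, 3]),
      min(s[, 2], s[, 4]), max(s[, 2], s[, 4]))
  }, numeric(4)))
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  tol <- snap
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (boxes[i, 1] > boxes[j, 2] + tol || boxes[j, 1] > boxes[i, 2] + tol ||
          boxes[i, 3] > boxes[j, 4] + tol || boxes[j, 3] > boxes[i, 4] + tol) next
      if (shares_segment(segs[[i]], segs[[j]], tol)) {
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  spatial_weights(areas$area_id, nb, style = "binary")
}

# All boundary edges of an area as a matrix (x1, y1, x2, y2), snapped.
area_segments <- function(geom, snap) {
  out <- list()
  for (poly in geom) {
    for (ring in poly) {
      r <- round(ring / snap) * snap
      a <- r[-nrow(r), , drop = FALSE]
      b <- r[-1, , drop = FALSE]
      keep <- a[, 1] != b[, 1] | a[, 2] != b[, 2]
      if (any(keep)) out[[length(out) + 1]] <- cbind(a[keep, , drop = FALSE],
                                                     b[keep, , drop = FALSE])
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 4))
  do.call(rbind, out)
}

# TRUE iff any segment of A is collinear with a segment of B and the two
# overlap over a length > tol (corner-point contact therefore fails).
shares_segment <- function(A, B, tol) {
  for (k in seq_len(nrow(A))) {
    p <- A[k, 1:2]; q <- A[k, 3:4]
    d <- q - p
    len <- sqrt(sum(d^2))
    u <- d / len
    for (m in seq_len(nrow(B))) {
      r <- B[m, 1:2]; s <- B[m, 3:4]
      # both endpoints of B-segment must lie on the A-segment's line
      if (abs((r[1] - p[1]) * u[2] - (r[2] - p[2]) * u[1]) > tol) next
      if (abs((s[1] - p[1]) * u[2] - (s[2] - p[2]) * u[1]) > tol) next
      tr <- sum((r - p) * u)
      ts <- sum((s - p) * u)
      lo <- max(0, min(tr, ts))
      hi <- min(len, max(tr, ts))
      if (hi - lo > tol) return(TRUE)
    }
  }
  FALSE
}

#' Manually link areas (island repair)
#'
#' Adds symmetric binary links between the given pairs, the way isolated
#' units (offshore islands, detached localities) are connected to their
#' nearest mainland neighbor before spatial modeling. Links already present
#' leave the structure unchanged; every applied pair is recorded in
#' `manual_links` for provenance.
#'
#' @param w a binary [spatial_weights()] object.
#' @param links list of length-2 character vectors of area ids, or a
#'   two-column matrix.
#' @return the updated [spatial_weights()] object.
#' @export
apply_manual_links <- function(w, links) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "binary") stop("manual links must be applied to binary weights")
  if (is.matrix(links)) links <- lapply(seq_len(nrow(links)), function(i) links[i, ])
  if (length(links) && !is.list(links)) links <- list(links)
  nb <- w$neighbours
  ml <- w$manual_links
  for (lk in links) {
    a <- as.character(lk[1]); b <- as.character(lk[2])
    ia <- match(a, w$area_id); ib <- match(b, w$area_id)
    if (is.na(ia)) stop("unknown area_id in manual link: ", a)
    if (is.na(ib)) stop("unknown area_id in manual link: ", b)
    if (ia == ib) stop("cannot link area ", a, " to itself")
    recorded <- nrow(ml) > 0 &&
      any((ml[, 1] == a & ml[, 2] == b) | (ml[, 1] == b & ml[, 2] == a))
    if (!recorded) ml <- rbind(ml, c(a, b))
    if (!(ib %in% nb[[ia]])) nb[[ia]] <- sort(c(nb[[ia]], ib))
    if (!(ia %in% nb[[ib]])) nb[[ib]] <- sort(c(nb[[ib]], ia))
  }
  spatial_weights(w$area_id, nb, style = "binary", manual_links = ml)
}

#' Row-standardize binary weights
#'
#' Divides each non-island row by its neighbor count so rows sum to 1, the
#' scaling under which Moran statistics use the mean of neighbors as the
#' spatial lag. Island rows stay all-zero.
#'
#' @param w a binary [spatial_weights()] object.
#' @return a row-standardized [spatial_weights()] object.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style == "row_standardized") {
    stop("weights are already row-standardized")
  }
  wts <- lapply(w$neighbours, function(nb) {
    if (length(nb) == 0) numeric(0) else rep(1 / length(nb), length(nb))
  })
  spatial_weights(w$area_id, w$neighbours, weights = wts,
                  style = "row_standardized", manual_links = w$manual_links)
}

#' Read / write GAL contiguity files
#'
#' The GAL dialect used here: first line is the area count `n`; then, for
#' each area, a line `id k` followed by a line of `k` space-separated
#' neighbor ids. Round-tripping a weights object through a GAL file
#' reproduces its neighbor sets exactly (weights are contiguity-binary).
#'
#' @param path file path.
#' @return for `read_weights_gal`, a binary [spatial_weights()] object.
#' @export
read_weights_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GAL file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("malformed GAL header at line 1: '", lines[1], "'")
  ids <- character(n)
  raw_nb <- vector("list", n)
  ln <- 1
  for (i in seq_len(n)) {
    ln <- ln + 1
    if (ln > length(lines)) stop("GAL file truncated at line ", ln)
    head <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(head) != 2) stop("malformed GAL area header at line ", ln)
    ids[i] <- head[1]
    k <- suppressWarnings(as.integer(head[2]))
    if (is.na(k) || k < 0) stop("malformed neighbor count at line ", ln)
    if (k == 0) {
      raw_nb[[i]] <- character(0)
    } else {
      ln <- ln + 1
      if (ln > length(lines)) stop("GAL file truncated at line ", ln)
      nbids <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(nbids) != k) {
        stop("expected ", k, " neighbor ids at line ", ln, ", found ",
             length(nbids))
      }
      raw_nb[[i]] <- nbids
    }
  }
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- match(raw_nb[[i]], ids)
    if (anyNA(idx)) {
      stop("GAL file references unknown id '",
           raw_nb[[i]][which(is.na(idx))[1]], "' for area ", ids[i])
    }
    nb[[i]] <- idx
  }
  spatial_weights(ids, nb, style = "binary")
}

#' @param w a binary [spatial_weights()] object.
#' @rdname read_weights_gal
#' @export
write_weights_gal <- function(w, path) {
  stopifnot(inherits(w, "spatial_weights"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(w$area_id)), con)
  for (i in seq_along(w$area_id)) {
    nb <- w$neighbours[[i]]
    writeLines(paste(w$area_id[i], length(nb)), con)
    if (length(nb) > 0) writeLines(paste(w$area_id[nb], collapse = " "), con)
  }
  invisible(path)
}

# Connected components of the adjacency graph (islands are singleton
# components). Used for the ICAR rank and to validate exact ICAR sampling.
graph_components <- function(w) {
  n <- length(w$area_id)
  comp <- integer(n)
  cur <- 0
  for (start in seq_len(n)) {
    if (comp[start] != 0) next
    cur <- cur + 1
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in w$neighbours[[i]]) {
        if (comp[j] == 0) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}
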