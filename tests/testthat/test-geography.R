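test_that("rook adjacency on rectangular lattices matches the grid graph", {
  a22 <- make_lattice(2, 2)
  w22 <- build_rook_adjacency(a22)
  expect_equal(lengths(w22$neighbours), rep(2L, 4))
  # diagonal cells are not neighbors
  expect_false(4L %in% w22$neighbours[[1]])

  a33 <- make_lattice(3, 3)
  w33 <- build_rook_adjacency(a33)
  deg <- lengths(w33$neighbours)
  expect_equal(deg[5], 4L)                       # center
  expect_equal(deg[c(1, 3, 7, 9)], rep(2L, 4))   # corners
  expect_equal(length(w33$islands), 0L)

  # total link count on an nx x ny lattice: nx*(ny-1) + ny*(nx-1), doubled
  # in the symmetric structure
  for (dims in list(c(2, 2), c(3, 3), c(4, 6))) {
    w <- build_rook_adjacency(make_lattice(dims[1], dims[2]))
    expect_equal(sum(lengths(w$neighbours)),
                 2 * (dims[1] * (dims[2] - 1) + dims[2] * (dims[1] - 1)))
  }
})

test_that("corner-point contact does not create a rook link", {
  # two unit squares touching only at (1, 1)
  a <- area_set(c("a", "b"),
                list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)),
                     rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2), c(1, 1))))
  w <- build_rook_adjacency(a)
  expect_equal(lengths(w$neighbours), c(0L, 0L))
  expect_equal(sort(w$islands), c(1L, 2L))
})

test_that("shared borders are detected even with mismatched vertices", {
  # b's left edge spans a's right edge but is digitized with an extra
  # midpoint and extends further north
  a <- area_set(c("a", "b"),
                list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)),
                     rbind(c(1, 0), c(2, 0), c(2, 2), c(1, 2),
                           c(1, 0.5), c(1, 0))))
  w <- build_rook_adjacency(a)
  expect_equal(w$neighbours[[1]], 2L)
  expect_equal(w$neighbours[[2]], 1L)
})

test_that("adjacency is symmetric and rook links are a subset of queen links", {
  set.seed(31)
  areas <- simulate_geography(simulation_spec(nx = 5, ny = 4, n_islands = 2,
                                              seed = 8))
  w <- build_rook_adjacency(areas)
  for (i in seq_along(w$neighbours)) {
    for (j in w$neighbours[[i]]) expect_true(i %in% w$neighbours[[j]])
  }
  queen <- naive_queen_pairs(areas)
  for (i in seq_along(w$neighbours)) {
    expect_true(all(queen[i, w$neighbours[[i]]]))
  }
})

test_that("duplicate ids and degenerate geometry are rejected", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_error(area_set(c("a", "a"), list(sq, sq)), "duplicate area_id: a")
  expect_error(area_set("a", list(rbind(c(0, 0), c(1, 1)))), "fewer than 3")
})

test_that("manual links repair islands symmetrically and idempotently", {
  areas <- simulate_geography(simulation_spec(nx = 3, ny = 3, n_islands = 1,
                                              seed = 2))
  w <- build_rook_adjacency(areas)
  isl <- w$area_id[w$islands]
  expect_equal(isl, "I01")

  w2 <- apply_manual_links(w, list(c("I01", "A001")))
  expect_equal(w2$area_id[w2$neighbours[[match("I01", w2$area_id)]]], "A001")
  expect_true("I01" %in% w2$area_id[w2$neighbours[[match("A001", w2$area_id)]]])
  expect_equal(length(w2$islands), 0L)
  expect_equal(nrow(w2$manual_links), 1L)

  # re-applying the same link (either orientation) changes nothing
  w3 <- apply_manual_links(w2, list(c("A001", "I01")))
  expect_identical(w3$neighbours, w2$neighbours)
  expect_equal(nrow(w3$manual_links), 1L)

  expect_error(apply_manual_links(w, list(c("I01", "I01"))), "itself")
  expect_error(apply_manual_links(w, list(c("I01", "nope"))), "unknown area_id")
})

test_that("row standardization scales rows to 1 and leaves islands zero", {
  areas <- simulate_geography(simulation_spec(nx = 3, ny = 3, n_islands = 1,
                                              seed = 2))
  w <- build_rook_adjacency(areas)
  ws <- row_standardize(w)
  expect_equal(ws$style, "row_standardized")
  rs <- vapply(ws$weights, sum, numeric(1))
  expect_equal(rs[1:9], rep(1, 9), tolerance = 1e-12)
  expect_equal(rs[10], 0)
  center <- 5L
  expect_equal(ws$weights[[center]], rep(0.25, 4))
  expect_error(row_standardize(ws), "already row-standardized")
})

test_that("GAL files round-trip neighbor sets exactly", {
  w <- build_rook_adjacency(make_lattice(3, 3))
  f <- withr::local_tempfile(fileext = ".gal")
  write_weights_gal(w, f)
  w2 <- read_weights_gal(f)
  expect_identical(w2$area_id, w$area_id)
  expect_identical(w2$neighbours, w$neighbours)

  # islands round-trip too
  areas <- simulate_geography(simulation_spec(nx = 3, ny = 3, n_islands = 2,
                                              seed = 5))
  wi <- build_rook_adjacency(areas)
  write_weights_gal(wi, f)
  expect_identical(read_weights_gal(f)$islands, wi$islands)
})

test_that("malformed GAL input is reported with its line", {
  f <- withr::local_tempfile(fileext = ".gal")
  writeLines(character(0), f)
  expect_error(read_weights_gal(f), "empty GAL file")
  writeLines(c("2", "a 1", "zzz", "b 1", "a"), f)
  expect_error(read_weights_gal(f), "unknown id 'zzz'")
  writeLines(c("notanumber"), f)
  expect_error(read_weights_gal(f), "line 1")
  writeLines(c("2", "a 1"), f)
  expect_error(read_weights_gal(f), "truncated")
})

test_that("GeoJSON round-trips areas and attached summary columns", {
  areas <- simulate_geography(simulation_spec(nx = 3, ny = 2, seed = 4))
  f <- withr::local_tempfile(fileext = ".geojson")
  extra <- data.frame(median_rr = seq(0.5, by = 0.25, length.out = 6),
                      significance = rep(c("none", "high"), 3))
  write_geojson_areas(areas, f, extra_properties = extra)
  back <- read_geojson_areas(f)
  expect_identical(back$area_id, areas$area_id)
  expect_identical(back$population_15plus, areas$population_15plus)
  expect_identical(back$geometry, areas$geometry)
  gj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_equal(length(gj$features), 6L)
  got <- vapply(gj$features, function(ft) ft$properties$median_rr, numeric(1))
  expect_equal(got, extra$median_rr)
})
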