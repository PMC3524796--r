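test_that("a ring arc around a follicle is detected as circumferential", {
  tr <- ring_trace(n = 20, r = 25, span = 320, z = 50)
  m <- one_follicle_map(diameter = 50)
  e <- detect_terminal_endings(tr, m)
  circ <- e[e$kind == "circumferential", ]
  expect_equal(nrow(circ), 1)
  expect_equal(circ$follicle_id, 1L)
  expect_equal(circ$arc_fraction, 320 / 360, tolerance = 0.02)
})

test_that("a cluster of short vertical twigs is detected as lanceolate", {
  tr <- twig_trace(k = 5, r = 17, z = 50)
  m <- one_follicle_map(diameter = 30)
  e <- detect_terminal_endings(tr, m)
  expect_equal(as.character(e$kind), "lanceolate")
  expect_equal(e$follicle_id, 1L)
  expect_equal(e$n_nodes, 10L)  # 5 bases + 5 leaves
  # fewer than min_twigs vertical segments never form a palisade
  tr2 <- twig_trace(k = 2)
  e2 <- detect_terminal_endings(tr2, one_follicle_map(diameter = 30))
  expect_false(any(e2$kind == "lanceolate"))
})

test_that("terminals far from every follicle are free endings", {
  tr <- path_trace(cbind(c(200, 230, 260), c(200, 200, 200), c(120, 30, 30)))
  e <- detect_terminal_endings(tr, one_follicle_map(diameter = 30))
  expect_equal(as.character(e$kind), "free")
  expect_true(is.na(e$follicle_id))
})

test_that("thickened terminal segments are detected from the radius profile", {
  # terminal 60 um at 3x the arbor median radius
  nd <- node_df(1:8, x = c(0, 0, 0, 0, 0, 0, 0, 0),
                y = c(0, 30, 60, 90, 120, 140, 160, 180),
                z = 20, parent_id = c(-1, 1:7),
                radius = c(rep(0.5, 5), rep(1.5, 3)))
  tr <- arbor_trace(nd)
  m <- one_follicle_map(diameter = 30)
  e <- detect_terminal_endings(tr, m)
  expect_true("thick" %in% e$kind)
  expect_true(all(is.na(e$follicle_id[e$kind == "thick"])))
  # all-zero radii with detection forced is an explicit error
  nd$radius <- 0
  expect_error(
    detect_terminal_endings(arbor_trace(nd), m,
                            ending_params(detect_thick = TRUE)),
    "radii are zero")
})

test_that("follicle assignment is nearest-in-range with a fixed tie-break", {
  extra <- data.frame(follicle_id = 2L, cx = 60, cy = 0, diameter = 30,
                      guard = FALSE, tilt_x = 1, tilt_y = 0)
  m <- one_follicle_map(diameter = 30, extra = extra)
  e <- empty_set <- detect_terminal_endings(twig_trace(k = 4, r = 10), m)
  e$centroid_x <- 10; e$centroid_y <- 0
  e2 <- assign_endings_to_follicles(e, m, attach_radius = 40)
  expect_equal(e2$follicle_id, 1L)            # 10 um away, in range
  e$centroid_x <- 30                           # equidistant from both
  expect_equal(assign_endings_to_follicles(e, m, 40)$follicle_id, 1L)
  e$centroid_x <- 300                          # out of range everywhere
  expect_true(is.na(assign_endings_to_follicles(e, m, 40)$follicle_id))
  # idempotent and order-independent
  once <- assign_endings_to_follicles(e2, m, 40)
  expect_identical(once$follicle_id,
                   assign_endings_to_follicles(once, m, 40)$follicle_id)
})

test_that("innervation summary ties index, counts and hull area together", {
  a <- generate_arbor("HD-FALE", seed = 5)
  e <- assign_endings_to_follicles(detect_terminal_endings(a$trace,
                                                           a$follicle_map),
                                   a$follicle_map)
  hull <- convex_hull_polygon(a$trace)
  inn <- innervation_summary(e, hull, a$follicle_map)
  expect_equal(inn$innervation_index * convex_hull_area(a$trace),
               inn$n_follicles_innervated, tolerance = 1e-12)
  expect_lte(inn$fraction_innervated, 1)
  # worked ratio: 30 follicles over 3.4e5 um^2 gives 8.82e-5 per um^2
  expect_equal(30 / 3.4e5, 8.82e-5, tolerance = 1e-3)
  # no endings: zero counts, zero fraction
  none <- e[0, ]
  attr(none, "members") <- list()
  class(none) <- c("ending_set", "data.frame")
  inn0 <- innervation_summary(none, hull, a$follicle_map)
  expect_equal(inn0$n_follicles_innervated, 0)
  expect_equal(inn0$innervation_index, 0)
})

test_that("full occupancy with in-range attachment yields fraction 1", {
  cfg <- generator_config()
  cfg$type_params[["HD-FALE"]]$occupancy <- 1
  for (s in 1:3) {
    a <- generate_arbor("HD-FALE", cfg, seed = 40 + s)
    e <- assign_endings_to_follicles(detect_terminal_endings(a$trace,
                                                             a$follicle_map),
                                     a$follicle_map)
    inn <- innervation_summary(e, a$trace, a$follicle_map)
    expect_equal(inn$fraction_innervated, 1)
  }
})

test_that("follicle density is count over area", {
  f <- data.frame(follicle_id = 1:100,
                  cx = rep(seq(50, 950, 100), 10),
                  cy = rep(seq(50, 950, 100), each = 10),
                  diameter = 20, guard = FALSE, tilt_x = 1, tilt_y = 0)
  m <- follicle_map(f, c(0, 1000, 0, 1000))
  expect_equal(follicle_density(m), 1e-4)  # 100 per mm^2
  empty <- follicle_map(f[0, ], c(0, 1000, 0, 1000))
  expect_equal(follicle_density(empty), 0)
  expect_error(follicle_density(m, c(0, 0, 0, 0)), "positive")
  # generator lattice hits the configured density within 3 SE
  d <- 1e-4
  lat <- generate_follicle_lattice(generator_config(lattice_density = d),
                                   c(0, 3200, 0, 3100), seed = 2)
  n <- nrow(lat$follicles)
  expect_lt(abs(n - d * 3200 * 3100), 3 * sqrt(d * 3200 * 3100))
})

test_that("coverage factor estimators reproduce the published arithmetic", {
  expect_equal(coverage_factor_area(2, 1), 2)
  expect_equal(coverage_factor_area(0, 5e-6), 0)
  expect_equal(coverage_factor_area(3.4e5, 5e-6), 1.7)
  # high-density lanceolate: >80% of follicles at >50% arc -> within [1, 2]
  expect_equal(coverage_factor_follicle(0.8, 0.5), 1.6)
  expect_equal(coverage_factor_follicle(0.5, 0.5), 1)
  # circumferential estimate: 57% contacted at ~20% arc -> within [2, 4]
  expect_equal(coverage_factor_follicle(0.57, 0.2), 2.85)
  expect_error(coverage_factor_follicle(0.5, 0), "positive")
})

test_that("area coverage factor matches a Monte-Carlo point-coverage oracle", {
  set.seed(77)
  # scatter generated arbors over a shared 4 x 4 mm region
  region <- c(0, 4000, 0, 4000)
  hulls <- list()
  areas <- numeric(0)
  for (s in 1:15) {
    a <- generate_arbor("HD-FALE", seed = 200 + s)
    hull <- convex_hull_polygon(a$trace)
    shift <- c(runif(1, 500, 3500), runif(1, 500, 3500))
    hull <- cbind(hull[, 1] - mean(hull[, 1]) + shift[1],
                  hull[, 2] - mean(hull[, 2]) + shift[2])
    hulls[[s]] <- hull
    areas <- c(areas, polygon_area_oracle(hull))
  }
  dens <- length(hulls) / (4000 * 4000)
  cf <- coverage_factor_area(mean(areas), dens)
  # Monte-Carlo: covering hulls per uniform point, with multiplicity
  px <- runif(10000, 0, 4000); py <- runif(10000, 0, 4000)
  hits <- rowSums(vapply(hulls, function(h)
    point_in_poly_oracle(px, py, h), numeric(10000)))
  mc <- mean(hits)
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(cf - mc), 3 * se + 1e-6)
})
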