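test_that("lattice generation hits density, guard fraction and determinism", {
  cfg <- generator_config()
  b <- c(0, 3300, 0, 3100)
  m1 <- generate_follicle_lattice(cfg, b, seed = 5)
  m2 <- generate_follicle_lattice(cfg, b, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(
    m1, generate_follicle_lattice(cfg, b, seed = 6)))
  no_guard <- generator_config(guard_fraction = 0)
  expect_false(any(generate_follicle_lattice(no_guard, b,
                                             seed = 1)$follicles$guard))
  expect_error(generate_follicle_lattice(cfg, c(0, 0, 0, 10)), "positive")
  # tilt vectors concentrate about +x within the configured scatter
  ang <- atan2(m1$follicles$tilt_y, m1$follicles$tilt_x) * 180 / pi
  expect_lt(abs(mean(ang)), 3 * sd(ang) / sqrt(length(ang)) + 1)
  expect_lt(sd(ang), 12)
})

test_that("every generated type is a valid trace that round-trips", {
  for (ty in arbor_type_labels()) {
    a <- generate_arbor(ty, seed = 61)
    expect_s3_class(a$trace, "arbor_trace")
    expect_equal(a$truth$type, ty)
    expect_true(all(a$trace$nodes$z >= 0 & a$trace$nodes$z <= 135))
    f <- withr::local_tempfile(fileext = ".swc")
    write_swc(a$trace, f)
    re <- read_swc(f)
    expect_equal(nrow(re$nodes), nrow(a$trace$nodes))
    expect_equal(re$nodes$parent_id, a$trace$nodes$parent_id)
  }
})

test_that("generated arbors land in the published per-type ranges", {
  # thick-ending arbors carry 20-80 branch points
  for (s in 1:4) {
    a <- generate_arbor("TE", seed = 400 + s)
    bp <- branch_point_count(a$trace)
    expect_gte(bp, 20); expect_lte(bp, 80)
    expect_gt(max(a$trace$nodes$radius), 0)
  }
  # bushy arbors: ~10 cm of axon and ~1e3 branch points
  a <- generate_arbor("BE", seed = 88)
  expect_gt(total_axon_length(a$trace), 6e4)
  expect_lt(total_axon_length(a$trace), 1.7e5)
  expect_gt(branch_point_count(a$trace), 500)
  expect_lt(branch_point_count(a$trace), 1700)
  dp <- depth_profile(a$trace, terminals_only = TRUE)
  expect_gt(dp$depth_mean, 4); expect_lt(dp$depth_mean, 11)
  # high-density lanceolate endings sit ~50 um below the surface
  a <- generate_arbor("HD-FALE", seed = 19)
  dp <- depth_profile(a$trace, terminals_only = TRUE)
  expect_gt(dp$depth_mean, 44); expect_lt(dp$depth_mean, 56)
})

test_that("two-tier arbors stratify with >50 vertical connectors and the
           published outer length", {
  a <- generate_arbor("LA-FE", seed = 9)
  td <- decompose_tiers(a$trace)
  expect_true(td$two_tier)
  expect_gt(td$n_vertical_connectors, 50)
  expect_gt(td$outer_length, 5e5)
  expect_lt(td$outer_length, 1e6)
  expect_lt(td$outer_depth, 20)
  expect_gt(td$inner_depth, 60)
})

test_that("surveys are deterministic and export byte-identically", {
  n <- c("HD-FALE" = 2, "TE" = 1)
  s1 <- generate_survey(n_per_type = n, seed = 33)
  s2 <- generate_survey(n_per_type = n, seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_survey(s1, d1); export_survey(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  empty <- generate_survey(n_per_type = c("BE" = 0), seed = 1)
  expect_equal(length(empty$arbors), 0)
  expect_error(generate_survey(n_per_type = 3, seed = 1), "named")
})

test_that("independent-tracing noise brackets the published differences", {
  a <- generate_arbor("BE", seed = 120)  # the published pair was a BE arbor
  # zero noise reproduces the input exactly
  p0 <- generate_trace_pair(a$trace,
                            noise = list(xy_sd_frac = 0, dropout = 0),
                            seed = 1)
  expect_identical(p0$a$nodes, a$trace$nodes)
  expect_identical(p0$b$nodes, a$trace$nodes)
  # default noise keeps both measures within 10%
  for (s in 1:5) {
    p <- generate_trace_pair(a$trace, seed = 130 + s)
    cmp <- compare_traces(p$a, p$b)
    expect_lt(cmp$length_pct_diff, 10)
    expect_lt(cmp$branch_pct_diff, 10)
  }
  # full dropout collapses the arbor and is flagged
  pd <- generate_trace_pair(a$trace,
                            noise = list(xy_sd_frac = 0, dropout = 1),
                            seed = 2)
  expect_true(isTRUE(attr(pd$a, "degenerate")) ||
                terminal_count(pd$a) < terminal_count(a$trace))
})

test_that("pipeline recovery of configured occupancy is unbiased", {
  cfg <- generator_config()
  s <- generate_survey(cfg, n_per_type = c("HD-FALE" = 40), seed = 71)
  truth <- vapply(s$arbors, function(a) length(a$truth$target_follicles),
                  numeric(1))
  tab <- run_survey(s, thresholds = NULL)
  expect_equal(tab$arbors$n_follicles_innervated, truth)
})
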