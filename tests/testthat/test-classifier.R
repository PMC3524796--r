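# hand-built metric / ending records for exercising single decision rules
fake_metrics <- function(hull_area, n_branch_points = 10,
                         two_tier = FALSE) {
  structure(list(arbor_id = "fake", axon_length = 1000,
                 n_branch_points = n_branch_points,
                 n_terminals = n_branch_points + 1,
                 hull_area = hull_area, depth_mean = 50, depth_sd = 1,
                 depth_range = c(45, 55), terminal_depth_mean = 50,
                 tier_info = list(two_tier = two_tier, outer_depth = 10,
                                  inner_depth = 70, outer_length = 1,
                                  inner_length = 1,
                                  n_vertical_connectors =
                                    if (two_tier) 60 else 0)),
            class = "arbor_metrics")
}
fake_endings <- function(kind, n, n_follicles = 0) {
  df <- data.frame(ending_id = seq_len(n), kind = kind,
                   follicle_id = if (n_follicles > 0)
                     rep_len(seq_len(n_follicles), n) else NA_integer_,
                   centroid_x = 0, centroid_y = 0, depth = 50,
                   arc_fraction = 0.5, n_nodes = 5L)
  structure(df, members = rep(list(1L), n),
            class = c("ending_set", "data.frame"))
}

test_that("single decision rules reproduce the type definitions", {
  th <- classifier_thresholds()
  # lanceolate endings on an isolated follicle
  expect_equal(classify_arbor(fake_metrics(2000),
                              fake_endings("lanceolate", 6, 1), th)$label,
               "I-FALE")
  # circumferential on one follicle
  expect_equal(classify_arbor(fake_metrics(2000),
                              fake_endings("circumferential", 2, 1),
                              th)$label, "I-FACE")
  # circumferential, 4 follicles, small territory
  expect_equal(classify_arbor(fake_metrics(1.2e5),
                              fake_endings("circumferential", 4, 4),
                              th)$label, "SA-FACE")
  # circumferential, 197 follicles, 2e6 um^2 territory
  expect_equal(classify_arbor(fake_metrics(2e6),
                              fake_endings("circumferential", 197, 197),
                              th)$label, "LA-FACE")
  # free endings, single tier, 1000 branch points in 5e5 um^2
  expect_equal(classify_arbor(fake_metrics(5e5, n_branch_points = 1000),
                              fake_endings("free", 900), th)$label, "BE")
  # free endings in two tiers
  expect_equal(classify_arbor(fake_metrics(8e6, 2000, two_tier = TRUE),
                              fake_endings("free", 1500), th)$label,
               "LA-FE")
  # merkel declaration wins over everything
  expect_equal(classify_arbor(fake_metrics(1000),
                              fake_endings("merkel", 1, 1), th)$label,
               "MCA")
  # dominant thick endings
  expect_equal(classify_arbor(fake_metrics(1e5, 40),
                              fake_endings("thick", 50), th)$label, "TE")
  # high- vs low-density lanceolate via the (log area, log index) split
  hd <- classify_arbor(fake_metrics(3.4e5),
                       fake_endings("lanceolate", 30, 30), th)
  expect_equal(hd$label, "HD-FALE")
  ld <- classify_arbor(fake_metrics(1.6e6),
                       fake_endings("lanceolate", 12, 12), th)
  expect_equal(ld$label, "LD-FALE")
  # every label arrives with a non-empty auditable rule trace
  expect_gt(length(hd$rule_trace), 0)
  expect_match(hd$rule_trace[1], "HD-FALE")
})

test_that("balanced mixtures of specialized kinds are rejected", {
  mix <- fake_endings(rep(c("lanceolate", "circumferential"), each = 10),
                      20, 10)
  out <- classify_arbor(fake_metrics(1e5), mix, classifier_thresholds())
  expect_equal(out$label, "unclassifiable")
  expect_match(out$rule_trace[1], "purity")
})

test_that("survey classification is deterministic and order-invariant", {
  s <- generate_survey(n_per_type = c("HD-FALE" = 3, "SA-FACE" = 3,
                                      "TE" = 2), seed = 17)
  tab <- run_survey(s)
  expect_true(all(tab$arbors$label == tab$arbors$true_label))
  tab2 <- run_survey(s)
  expect_identical(tab$arbors, tab2$arbors)
  # reversing arbor order permutes rows but not labels
  s_rev <- s
  s_rev$arbors <- rev(s_rev$arbors)
  tab3 <- run_survey(s_rev)
  m <- match(tab$arbors$arbor_id, tab3$arbors$arbor_id)
  expect_equal(tab3$arbors$label[m], tab$arbors$label)
})

test_that("confusion diagnostics appear when ground truth is available", {
  s <- generate_survey(n_per_type = c("HD-FALE" = 2), seed = 23)
  tab <- run_survey(s)
  conf <- attr(tab, "confusion")
  expect_false(is.null(conf))
  expect_equal(dim(conf), c(1, 1))
  expect_equal(attr(tab, "agreement"), 1)
})
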