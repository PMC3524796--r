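test_that("axon length matches hand calculations and the edge-loop oracle", {
  expect_equal(total_axon_length(path_trace(cbind(c(0, 0), c(0, 3),
                                                  c(0, 4)))), 5)
  expect_equal(total_axon_length(y_tree()), 20)  # 10 + 5 + 5
  tr <- random_tree(500, seed = 21)
  expect_equal(total_axon_length(tr), brute_axon_length(tr),
               tolerance = 1e-9)
  single <- arbor_trace(node_df(1, 0, 0, 0, -1))
  expect_error(total_axon_length(single), "single-node")
})

test_that("branch points count nodes with >= 2 children, once each", {
  path <- path_trace(cbind(seq(0, 90, 10), 0, 0))
  expect_equal(branch_point_count(path), 0)
  # full binary tree with 4 terminals has 3 branch points
  bin <- arbor_trace(node_df(1:7, c(0, -2, 2, -3, -1, 1, 3),
                             c(0, 1, 1, 2, 2, 2, 2), 0,
                             c(-1, 1, 1, 2, 2, 3, 3)))
  expect_equal(branch_point_count(bin), 3)
  expect_equal(terminal_count(bin), 4)
  for (s in 1:5) {
    tr <- random_tree(300, seed = s)
    expect_equal(branch_point_count(tr), brute_branch_points(tr))
    expect_lte(branch_point_count(tr), terminal_count(tr) - 1)
  }
})

test_that("convex-hull area agrees with the brute-force hull oracle", {
  sq <- arbor_trace(node_df(1:4, c(0, 1, 1, 0), c(0, 0, 1, 1), 0,
                            c(-1, 1, 2, 3)))
  expect_equal(convex_hull_area(sq), 1)
  col <- arbor_trace(node_df(1:3, c(0, 1, 2), c(0, 1, 2), 0, c(-1, 1, 2)))
  expect_warning(a <- convex_hull_area(col), "collinear|non-collinear")
  expect_equal(a, 0)
  for (s in 1:4) {
    set.seed(100 + s)
    xy <- cbind(runif(200, 0, 50), runif(200, 0, 50))
    expect_equal(convex_hull_area(xy), brute_hull_area(xy),
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under re-indexing and rigid XY motion", {
  tr <- random_tree(150, seed = 8)
  th <- 0.7
  rot <- tr
  rot$nodes$x <- cos(th) * tr$nodes$x - sin(th) * tr$nodes$y + 12
  rot$nodes$y <- sin(th) * tr$nodes$x + cos(th) * tr$nodes$y - 40
  expect_equal(total_axon_length(rot), total_axon_length(tr))
  expect_equal(branch_point_count(rot), branch_point_count(tr))
  expect_equal(convex_hull_area(rot), convex_hull_area(tr),
               tolerance = 1e-9)
  # re-indexing: relabel node ids by a permutation
  set.seed(1); perm <- sample(150)
  re <- tr$nodes
  re$node_id <- perm[re$node_id]
  re$parent_id <- ifelse(re$parent_id == -1, -1, perm[pmax(re$parent_id, 1)])
  re <- arbor_trace(re)
  expect_equal(total_axon_length(re), total_axon_length(tr))
  expect_equal(branch_point_count(re), branch_point_count(tr))
})

test_that("hull area dominates the hull area of any subtree", {
  tr <- random_tree(200, seed = 31)
  # subtree rooted at the first child of the root
  nd <- tr$nodes
  keep <- rep(FALSE, nrow(nd))
  root_child <- which(nd$parent_id == 1)[1]
  keep[root_child] <- TRUE
  repeat {
    add <- !keep & nd$parent_id %in% nd$node_id[keep]
    if (!any(add)) break
    keep[add] <- TRUE
  }
  sub <- nd[keep, ]
  sub$parent_id[sub$node_id == nd$node_id[root_child]] <- -1
  sub <- arbor_trace(sub)
  expect_gte(convex_hull_area(tr),
             suppressWarnings(convex_hull_area(sub)))
})

test_that("depth profiles summarize node and terminal depths", {
  flat <- path_trace(cbind(0:5, 0, 50))
  dp <- depth_profile(flat)
  expect_equal(dp$depth_mean, 50)
  expect_equal(dp$depth_sd, 0)
  two <- path_trace(cbind(0:9, 0, rep(c(10, 70), each = 5)))
  expect_equal(depth_profile(two)$depth_mean, 40)
})

test_that("tier decomposition splits stratified arbors and counts connectors", {
  flat <- random_tree(100, seed = 2)
  flat$nodes$z <- runif(100, 20, 25)  # all within 5 um
  flat <- arbor_trace(flat$nodes)
  td <- decompose_tiers(flat)
  expect_false(td$two_tier)
  expect_equal(td$n_vertical_connectors, 0)

  # outer backbone at z = 10 with exactly 3 straight vertical drops to
  # inner junction nodes at z = 70, each bearing two inner leaves
  mk <- function(zoff = 0) {
    nd <- node_df(
      1:14,
      x = c(0, 100, 200, 300, 100, 200, 300,
            90, 110, 190, 210, 290, 310, 350),
      y = c(0, 0, 0, 0, 0, 0, 0, 10, 10, 10, 10, 10, 10, 0),
      z = c(10, 10, 10, 10, 70, 70, 70,
            70, 70, 70, 70, 70, 70, 10) + zoff,
      parent_id = c(-1, 1, 2, 3, 2, 3, 4, 5, 5, 6, 6, 7, 7, 4))
    arbor_trace(nd)
  }
  tr <- mk()
  td <- decompose_tiers(tr, min_gap = 30)
  expect_true(td$two_tier)
  expect_equal(td$n_vertical_connectors, 3)
  expect_equal(td$outer_depth, 10)
  expect_equal(td$inner_depth, 70)
  # uniform z offset shifts tier depths by exactly that offset
  td2 <- decompose_tiers(mk(15), min_gap = 30)
  expect_equal(td2$outer_depth, 25)
  expect_equal(td2$inner_depth, 85)
  expect_equal(td2$n_vertical_connectors, 3)
})

test_that("percent difference uses the larger denominator and is symmetric", {
  expect_equal(percent_difference(85020, 86908), 2.17)
  expect_equal(percent_difference(1011, 1071), 5.60)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(86908, 85020),
               percent_difference(85020, 86908))
  set.seed(6)
  a <- runif(50, 0.1, 100); b <- runif(50, 0.1, 100)
  pd <- percent_difference(a, b)
  expect_true(all(pd >= 0 & pd < 100))
  expect_error(percent_difference(-1, 2), "positive")
})
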