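# Programmatic fixtures: toy traces and follicle maps built in code.

node_df <- function(node_id, x, y, z, parent_id, radius = 0) {
  data.frame(node_id = node_id, x = x, y = y, z = z, radius = radius,
             parent_id = parent_id)
}

# unbranched path through the given coordinate matrix (rows = nodes)
path_trace <- function(coords, arbor_id = "path") {
  n <- nrow(coords)
  arbor_trace(node_df(seq_len(n), coords[, 1], coords[, 2], coords[, 3],
                      c(-1, seq_len(n - 1))), arbor_id = arbor_id)
}

# Y-shaped tree: trunk (0,0,0)->(0,0,10), two children at (+-5, 0, 10)
y_tree <- function() {
  arbor_trace(node_df(1:4, c(0, 0, 5, -5), c(0, 0, 0, 0), c(0, 10, 10, 10),
                      c(-1, 1, 2, 2)), arbor_id = "Y")
}

# random valid tree with n nodes: each node's parent drawn among earlier ones
random_tree <- function(n, scale = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parent <- c(-1, sample_parents(n))
  arbor_trace(node_df(seq_len(n), stats::runif(n, 0, scale),
                      stats::runif(n, 0, scale), stats::runif(n, 0, 50),
                      parent), arbor_id = "random")
}

sample_parents <- function(n) {
  vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
}

# single follicle at the origin plus an optional neighbor
one_follicle_map <- function(diameter = 30, tilt = c(1, 0), extra = NULL) {
  f <- data.frame(follicle_id = 1L, cx = 0, cy = 0, diameter = diameter,
                  guard = FALSE, tilt_x = tilt[1], tilt_y = tilt[2])
  if (!is.null(extra)) f <- rbind(f, extra)
  follicle_map(f, c(-500, 500, -500, 500))
}

# hub-and-spokes ring fixture: `n` leaves on a circle of radius r around the
# origin spanning `span` degrees, all children of a central hub at depth z
ring_trace <- function(n = 20, r = 25, span = 320, z = 50) {
  th <- seq(0, span, length.out = n) * pi / 180
  arbor_trace(node_df(
    1:(n + 2),
    c(0, 0, r * cos(th)), c(0, 0, r * sin(th)), c(120, z, rep(z, n)),
    c(-1, 1, rep(2, n))), arbor_id = "ring")
}

# lanceolate fixture: k vertical twigs around the origin follicle
twig_trace <- function(k = 5, r = 17, z = 50) {
  th <- seq(0, 300, length.out = k) * pi / 180
  ids <- seq_len(2 + 2 * k)
  bx <- r * cos(th); by <- r * sin(th)
  arbor_trace(node_df(
    ids,
    c(0, 0, as.vector(rbind(bx, bx))),
    c(0, 0, as.vector(rbind(by, by))),
    c(120, z - 6, rep(c(z - 6, z + 7), k)),
    c(-1, 1, as.vector(rbind(2, 2 + 2 * seq_len(k) - 1)))),
    arbor_id = "twigs")
}
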