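# Independent oracles, kept deliberately naive: they re-derive quantities by
# brute force and are never shared with the implementation.

# O(n^3) convex-hull area: a directed pair (i, j) is a hull edge iff every
# other point lies on or to the left of the line i -> j; the hull polygon is
# assembled by following edges, and its area taken by the shoelace formula.
brute_hull_area <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- TRUE
    strictly_left <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cr <- (xy[j, 1] - xy[i, 1]) * (xy[k, 2] - xy[i, 2]) -
            (xy[j, 2] - xy[i, 2]) * (xy[k, 1] - xy[i, 1])
      if (cr < -1e-9) { ok <- FALSE; break }
      if (cr > 1e-9) strictly_left <- TRUE
    }
    if (ok && strictly_left) edges[[length(edges) + 1L]] <- c(i, j)
  }
  if (!length(edges)) return(0)
  em <- do.call(rbind, edges)
  # follow the edge cycle
  v <- em[1, 1]
  poly <- v
  repeat {
    nxt <- em[em[, 1] == v, 2]
    nxt <- nxt[!nxt %in% poly]
    if (!length(nxt)) break
    v <- nxt[1]
    poly <- c(poly, v)
  }
  p <- xy[poly, , drop = FALSE]
  m <- nrow(p)
  j <- c(m, seq_len(m - 1L))
  abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
}

# per-edge cable length by an explicit loop with per-node parent lookup
brute_axon_length <- function(trace) {
  nd <- trace$nodes
  total <- 0
  for (i in seq_len(nrow(nd))) {
    if (nd$parent_id[i] == -1) next
    p <- which(nd$node_id == nd$parent_id[i])
    total <- total + sqrt((nd$x[i] - nd$x[p])^2 + (nd$y[i] - nd$y[p])^2 +
                            (nd$z[i] - nd$z[p])^2)
  }
  total
}

brute_branch_points <- function(trace) {
  nd <- trace$nodes
  sum(vapply(nd$node_id, function(id) sum(nd$parent_id == id) >= 2,
             logical(1)))
}

# direct resultant-vector circular statistics via complex sums
brute_circular <- function(angles_deg) {
  zsum <- sum(exp(1i * angles_deg * pi / 180))
  R <- Mod(zsum) / length(angles_deg)
  mu <- (Arg(zsum) * 180 / pi) %% 360
  list(mean = mu, sd = sqrt(-2 * log(R)) * 180 / pi, R = R)
}

# von Mises sampler (Best & Fisher rejection scheme), degrees
rvm_deg <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1L
      out[i] <- (mu_deg + sign(u[3] - 0.5) * acos(f) * 180 / pi) %% 360
    }
  }
  out
}

# shoelace area, written independently of the package internals
polygon_area_oracle <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

# even-odd ray casting point-in-polygon test (vectorized over points)
point_in_poly_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  as.numeric(inside)
}
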