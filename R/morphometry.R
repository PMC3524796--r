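# Per-arbor continuous morphometrics: cable length, branch points, convex
# hull receptive-field area, depth statistics, and two-tier decomposition of
# stratified arbors.

# --- internal tree helpers -------------------------------------------------

# index of each node's parent row (NA for root)
parent_index <- function(nodes) {
  idx <- match(nodes$parent_id, nodes$node_id)
  idx[nodes$parent_id == -1] <- NA_integer_
  idx
}

# number of children per node row
child_counts <- function(nodes) {
  pidx <- parent_index(nodes)
  tabulate(pidx[!is.na(pidx)], nbins = nrow(nodes))
}

# 3-D length of every parent-child segment (0 for root row)
segment_lengths <- function(nodes) {
  pidx <- parent_index(nodes)
  len <- numeric(nrow(nodes))
  ok <- !is.na(pidx)
  len[ok] <- sqrt((nodes$x[ok] - nodes$x[pidx[ok]])^2 +
                  (nodes$y[ok] - nodes$y[pidx[ok]])^2 +
                  (nodes$z[ok] - nodes$z[pidx[ok]])^2)
  len
}

# Decompose the tree into maximal unbranched paths. Junctions are the root,
# branch points (>= 2 children) and leaves. Each path is reported leaf-to-root
# orientation-free as the vector of node rows from one junction to the next,
# including both junction endpoints.
tree_paths <- function(nodes) {
  pidx <- parent_index(nodes)
  nch <- child_counts(nodes)
  junction <- nch >= 2 | is.na(pidx) | nch == 0
  paths <- vector("list", sum(nch == 0) + sum(nch >= 2) + 1L)
  k <- 0L
  # walk up from every non-root junction to the junction above it
  for (i in which(junction & !is.na(pidx))) {
    rows <- i
    j <- pidx[i]
    while (!junction[j]) {
      rows <- c(rows, j)
      j <- pidx[j]
    }
    k <- k + 1L
    paths[[k]] <- c(rows, j)
  }
  paths[seq_len(k)]
}

# Terminal branches: the maximal unbranched path ending at each leaf, ordered
# leaf first; the final element is the supporting junction node.
terminal_branches <- function(nodes) {
  nch <- child_counts(nodes)
  paths <- tree_paths(nodes)
  paths[vapply(paths, function(p) nch[p[1]] == 0L, logical(1))]
}

# --- exported metrics ------------------------------------------------------

#' Total axon length of a trace
#'
#' Sum of the 3-D Euclidean lengths of all parent-child segments, in
#' micrometers.
#'
#' @param trace An [arbor_trace()] with at least 2 nodes.
#' @return Length in micrometers.
#' @export
total_axon_length <- function(trace) {
  stopifnot(inherits(trace, "arbor_trace"))
  if (nrow(trace$nodes) < 2)
    stop("axon length is undefined for a single-node trace", call. = FALSE)
  sum(segment_lengths(trace$nodes))
}

#' Branch point count
#'
#' Number of nodes with two or more children. A node with k children counts
#' once, not k - 1 times; a root with >= 2 children counts.
#'
#' @param trace An [arbor_trace()].
#' @return Integer count.
#' @export
branch_point_count <- function(trace) {
  stopifnot(inherits(trace, "arbor_trace"))
  sum(child_counts(trace$nodes) >= 2L)
}

#' Terminal (leaf) count
#'
#' @param trace An [arbor_trace()].
#' @return Number of nodes with no children.
#' @export
terminal_count <- function(trace) {
  stopifnot(inherits(trace, "arbor_trace"))
  sum(child_counts(trace$nodes) == 0L)
}

#' Convex-hull arbor area
#'
#' Area of the 2-D convex hull of the XY projections of all trace nodes, the
#' computational analogue of the convex polygon drawn around an isolated
#' arbor to measure its receptive territory.
#'
#' @param trace An [arbor_trace()], or a 2-column numeric matrix of XY points.
#' @return Area in square micrometers; 0 (with a warning) when fewer than 3
#'   distinct non-collinear points exist.
#' @export
convex_hull_area <- function(trace) {
  polygon_area(convex_hull_polygon(trace))
}

#' @rdname convex_hull_area
#' @return `convex_hull_polygon`: the hull vertices as a 2-column matrix in
#'   counterclockwise order (0 rows for degenerate input).
#' @export
convex_hull_polygon <- function(trace) {
  xy <- if (inherits(trace, "arbor_trace")) {
    cbind(trace$nodes$x, trace$nodes$y)
  } else as.matrix(trace)
  xy <- unique(xy)
  degenerate <- function() {
    warning("fewer than 3 non-collinear points: hull area is 0")
    matrix(numeric(0), ncol = 2)
  }
  if (nrow(xy) < 3) return(degenerate())
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(degenerate())
  poly <- xy[h, , drop = FALSE]
  if (polygon_area(poly) <= 0) return(degenerate())
  poly[rev(seq_len(nrow(poly))), , drop = FALSE]  # chull is clockwise
}

#' Depth profile of a trace
#'
#' Summary statistics of node depths (z, micrometers below the surface),
#' computed over all nodes or restricted to terminal nodes -- the relevant
#' summary when reporting the lamination depth of sensory endings.
#'
#' @param trace An [arbor_trace()] in original-thickness (Z-corrected)
#'   coordinates.
#' @param terminals_only If `TRUE`, use only terminal (leaf) nodes.
#' @return List with `depth_mean`, `depth_sd`, `depth_range` (min, max) and
#'   `n` (nodes used).
#' @export
depth_profile <- function(trace, terminals_only = FALSE) {
  stopifnot(inherits(trace, "arbor_trace"))
  z <- trace$nodes$z
  if (terminals_only) z <- z[child_counts(trace$nodes) == 0L]
  list(depth_mean = mean(z),
       depth_sd = if (length(z) > 1) stats::sd(z) else 0,
       depth_range = range(z),
       n = length(z))
}

#' Two-tier depth decomposition of a stratified arbor
#'
#' The largest free-ending arbors ramify in two narrowly stratified tiers --
#' an outer arbor near the surface and an inner arbor deeper in the dermis --
#' joined by many near-vertical connector branches. This operation partitions
#' terminal nodes into at most two depth tiers by the largest gap in their z
#' values, declares two tiers only when that gap is at least `min_gap`, and
#' counts vertical connectors: maximal unbranched paths whose endpoints lie
#' in different tiers and whose endpoint depth difference exceeds
#' `vertical_frac` times the path length.
#'
#' @param trace An [arbor_trace()].
#' @param min_gap Minimum inter-tier gap in terminal depths, micrometers
#'   (default 30, about the separation between an outer tier near 10 um and
#'   an inner tier near 70 um).
#' @param vertical_frac Minimum |dz| / path-length ratio for a tier-crossing
#'   path to count as a vertical connector (default 0.7).
#' @return List with `two_tier` (logical); for two-tier arbors also
#'   `outer_depth`, `inner_depth` (mean terminal depth per tier, um),
#'   `outer_length`, `inner_length` (axon length of segments lying entirely
#'   within each tier, um) and `n_vertical_connectors`.
#' @export
decompose_tiers <- function(trace, min_gap = 30, vertical_frac = 0.7) {
  stopifnot(inherits(trace, "arbor_trace"), min_gap > 0)
  nd <- trace$nodes
  zt <- sort(nd$z[child_counts(nd) == 0L])
  single <- list(two_tier = FALSE,
                 outer_depth = mean(zt), inner_depth = mean(zt),
                 outer_length = if (nrow(nd) > 1) total_axon_length(trace) else 0,
                 inner_length = 0, n_vertical_connectors = 0L)
  if (length(zt) < 2) return(single)
  gaps <- diff(zt)
  g <- which.max(gaps)
  if (gaps[g] < min_gap) return(single)
  z_split <- (zt[g] + zt[g + 1]) / 2
  outer <- zt[zt < z_split]; inner <- zt[zt > z_split]
  # per-tier axon length: segments whose endpoints both lie in the tier
  pidx <- parent_index(nd)
  len <- segment_lengths(nd)
  ok <- !is.na(pidx)
  zn <- nd$z; zp <- zn[pidx]
  in_outer <- ok & zn < z_split & zp < z_split
  in_inner <- ok & zn > z_split & zp > z_split
  # vertical connectors over the path decomposition
  paths <- tree_paths(nd)
  n_conn <- 0L
  for (p in paths) {
    zends <- zn[c(p[1], p[length(p)])]
    if ((zends[1] - z_split) * (zends[2] - z_split) >= 0) next
    plen <- sum(len[p[-length(p)]])
    if (plen > 0 && abs(diff(zends)) > vertical_frac * plen)
      n_conn <- n_conn + 1L
  }
  list(two_tier = TRUE,
       outer_depth = mean(outer), inner_depth = mean(inner),
       outer_length = sum(len[in_outer]), inner_length = sum(len[in_inner]),
       n_vertical_connectors = n_conn)
}

#' Percent difference between two positive measurements
#'
#' |a - b| / max(a, b) * 100, rounded to 2 decimals -- the convention used to
#' compare independent tracings of the same arbor (larger value as the
#' denominator).
#'
#' @param a,b Positive numbers.
#' @return Percent difference in `[0, 100)`, 2 decimal places.
#' @examples
#' percent_difference(85020, 86908) # 2.17
#' percent_difference(1011, 1071)   # 5.60
#' @export
percent_difference <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(a <= 0) || any(b <= 0))
    stop("percent_difference requires positive inputs", call. = FALSE)
  round(abs(a - b) / pmax(a, b) * 100, 2)
}

#' All continuous metrics for one arbor
#'
#' Convenience wrapper computing the full parametric record for a trace:
#' axon length, branch points, terminals, convex-hull area, depth statistics
#' (all-node and terminal-restricted) and the tier decomposition.
#'
#' @param trace An [arbor_trace()] with at least 2 nodes.
#' @param min_gap,vertical_frac Passed to [decompose_tiers()].
#' @return An object of class `arbor_metrics` (a named list).
#' @export
arbor_metrics <- function(trace, min_gap = 30, vertical_frac = 0.7) {
  stopifnot(inherits(trace, "arbor_trace"))
  dp <- depth_profile(trace)
  dpt <- depth_profile(trace, terminals_only = TRUE)
  tiers <- decompose_tiers(trace, min_gap = min_gap,
                           vertical_frac = vertical_frac)
  structure(list(
    arbor_id = trace$arbor_id,
    axon_length = total_axon_length(trace),
    n_branch_points = branch_point_count(trace),
    n_terminals = terminal_count(trace),
    hull_area = suppressWarnings(convex_hull_area(trace)),
    depth_mean = dp$depth_mean, depth_sd = dp$depth_sd,
    depth_range = dp$depth_range,
    terminal_depth_mean = dpt$depth_mean,
    tier_info = tiers
  ), class = "arbor_metrics")
}

#' @export
print.arbor_metrics <- function(x, ...) {
  cat("<arbor_metrics> ", x$arbor_id, "\n",
      "  axon length   : ", format(round(x$axon_length, 1), big.mark = ","),
      " um\n",
      "  branch points : ", x$n_branch_points, "\n",
      "  terminals     : ", x$n_terminals, "\n",
      "  hull area     : ", format(signif(x$hull_area, 4), big.mark = ","),
      " um^2\n",
      "  depth (mean)  : ", round(x$depth_mean, 1), " um (terminals ",
      round(x$terminal_depth_mean, 1), " um)\n", sep = "")
  if (isTRUE(x$tier_info$two_tier))
    cat("  two tiers at ", round(x$tier_info$outer_depth, 1), " / ",
        round(x$tier_info$inner_depth, 1), " um, ",
        x$tier_info$n_vertical_connectors, " vertical connectors\n",
        sep = "")
  invisible(x)
}
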