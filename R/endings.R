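# Terminal ending detection, follicle assignment, and innervation statistics.
#
# Cutaneous afferents terminate in a small set of specialized structures:
# lanceolate endings (short vertical palisade elements parallel to the hair
# shaft), circumferential endings (fibers encircling a follicle), thick
# endings (club-like swellings of the final 50-100 um of a branch), Merkel
# cell contacts, and unspecialized free endings. Detection here is purely
# geometric, operating on the terminal branches of a trace against a
# follicle map.

#' Detection parameters for terminal endings
#'
#' @param attach_radius Maximum centroid-to-follicle-center distance for an
#'   ending to be attached to a follicle, micrometers (default 40, about one
#'   guard-follicle diameter).
#' @param ring_tol Radial tolerance around diameter/2 for circumferential
#'   (ring) node membership, micrometers.
#' @param min_ring_span Minimum angular span (degrees) distinguishing a ring
#'   arc from an incidental pass-by.
#' @param min_ring_nodes Minimum in-band nodes for a ring.
#' @param min_twigs Minimum vertical twig count for a lanceolate cluster.
#' @param twig_max_len Maximum final-segment length of a lanceolate twig, um.
#' @param vertical_frac Minimum |dz|/length for a twig segment to count as
#'   vertical.
#' @param thick_ratio Terminal mean radius must exceed `thick_ratio` times
#'   the arbor median radius for a thick ending.
#' @param thick_window Terminal path length over which the thick-ending
#'   radius is averaged, micrometers.
#' @param detect_thick `NA` (default) enables thick detection when any node
#'   radius is positive; `TRUE` forces it (error if radii are all zero);
#'   `FALSE` disables it.
#' @return A named list of parameters.
#' @export
ending_params <- function(attach_radius = 40, ring_tol = 8,
                          min_ring_span = 60, min_ring_nodes = 5,
                          min_twigs = 3, twig_max_len = 30,
                          vertical_frac = 0.7, thick_ratio = 2,
                          thick_window = 50, detect_thick = NA) {
  stopifnot(attach_radius > 0, ring_tol > 0, min_ring_span > 0,
            thick_ratio > 0, thick_window > 0)
  as.list(environment())
}

new_ending_set <- function(df, members) {
  rownames(df) <- NULL
  structure(df, members = members, class = c("ending_set", "data.frame"))
}

empty_ending_set <- function() {
  new_ending_set(data.frame(ending_id = integer(0), kind = character(0),
                            follicle_id = integer(0), centroid_x = numeric(0),
                            centroid_y = numeric(0), depth = numeric(0),
                            arc_fraction = numeric(0), n_nodes = integer(0)),
                 list())
}

#' Detect terminal ending specializations
#'
#' Labels the terminal branches of a trace by geometric rules against a
#' follicle map:
#' \itemize{
#'   \item \emph{thick}: the final `thick_window` micrometers of a branch
#'     have mean radius at least `thick_ratio` times the arbor median radius
#'     (requires radii; skipped when all radii are 0 unless forced).
#'   \item \emph{lanceolate}: a cluster of at least `min_twigs` short,
#'     predominantly vertical final segments whose leaves lie within
#'     `attach_radius` of a follicle center.
#'   \item \emph{circumferential}: nodes of terminal branches lying in the
#'     radial band diameter/2 +/- `ring_tol` around a follicle center and
#'     spanning at least `min_ring_span` degrees of its circumference;
#'     `arc_fraction` is the covered span over 360 degrees.
#'   \item \emph{merkel}: declared through the trace metadata field
#'     `ending_type = "merkel"` (Merkel contacts have no geometric signature
#'     at tracing scale); the whole terminal set forms one merkel ending.
#'   \item \emph{free}: every remaining terminal branch.
#' }
#'
#' @param trace An [arbor_trace()].
#' @param follicle_map A [follicle_map()] covering the arbor territory.
#' @param params See [ending_params()].
#' @return An `ending_set`: a data frame with one row per ending
#'   (`ending_id`, `kind`, `follicle_id`, `centroid_x`, `centroid_y`,
#'   `depth`, `arc_fraction`, `n_nodes`) carrying the member node ids in
#'   `attr(, "members")`.
#' @export
detect_terminal_endings <- function(trace, follicle_map,
                                    params = ending_params()) {
  stopifnot(inherits(trace, "arbor_trace"),
            inherits(follicle_map, "follicle_map"))
  nd <- trace$nodes
  branches <- terminal_branches(nd)
  if (!length(branches)) return(empty_ending_set())
  fol <- follicle_map$follicles

  rows <- list(); members <- list()
  add <- function(kind, node_rows, follicle_id, arc_fraction) {
    k <- length(rows) + 1L
    rows[[k]] <<- data.frame(
      ending_id = k, kind = kind,
      follicle_id = if (is.na(follicle_id)) NA_integer_ else
        as.integer(follicle_id),
      centroid_x = mean(nd$x[node_rows]), centroid_y = mean(nd$y[node_rows]),
      depth = mean(nd$z[node_rows]), arc_fraction = arc_fraction,
      n_nodes = length(node_rows))
    members[[k]] <<- nd$node_id[node_rows]
  }

  # declared Merkel arbor: one ending spanning all terminal branches
  if (identical(trace$metadata$ending_type, "merkel")) {
    leaf_rows <- vapply(branches, `[`, integer(1), 1L)
    arc <- NA_real_
    fid <- NA_integer_
    if (nrow(fol)) {
      cx <- mean(nd$x[leaf_rows]); cy <- mean(nd$y[leaf_rows])
      d2 <- (fol$cx - cx)^2 + (fol$cy - cy)^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= params$attach_radius + fol$diameter[j] / 2) {
        fid <- fol$follicle_id[j]
        arc <- angular_span(rad2deg(atan2(nd$y[leaf_rows] - fol$cy[j],
                                          nd$x[leaf_rows] - fol$cx[j]))) / 360
      }
    }
    add("merkel", unique(unlist(lapply(branches, function(p) p[-length(p)]))),
        fid, arc)
    df <- do.call(rbind, rows)
    return(new_ending_set(df, members))
  }

  consumed <- rep(FALSE, length(branches))
  leaf_rows <- vapply(branches, `[`, integer(1), 1L)
  leaf_parent <- vapply(branches, `[`, integer(1), 2L)
  seg_dx <- nd$x[leaf_rows] - nd$x[leaf_parent]
  seg_dy <- nd$y[leaf_rows] - nd$y[leaf_parent]
  seg_dz <- nd$z[leaf_rows] - nd$z[leaf_parent]
  seg_len <- sqrt(seg_dx^2 + seg_dy^2 + seg_dz^2)
  is_twig <- seg_len > 0 & seg_len <= params$twig_max_len &
    abs(seg_dz) >= params$vertical_frac * seg_len

  # thick endings from the radius profile of each terminal branch
  do_thick <- if (is.na(params$detect_thick)) any(nd$radius > 0) else
    isTRUE(params$detect_thick)
  if (isTRUE(params$detect_thick) && !any(nd$radius > 0))
    stop("thick-ending detection requested but all radii are zero",
         call. = FALSE)
  if (do_thick) {
    med_r <- stats::median(nd$radius)
    if (med_r <= 0) med_r <- stats::median(nd$radius[nd$radius > 0])
    len <- segment_lengths(nd)
    for (b in seq_along(branches)) {
      p <- branches[[b]]
      pp <- p[-length(p)]  # exclude the supporting junction
      cum <- cumsum(len[pp])
      take <- pp[c(TRUE, utils::head(cum, -1) < params$thick_window)]
      if (mean(nd$radius[take]) >= params$thick_ratio * med_r) {
        add("thick", p[-length(p)], NA_integer_, NA_real_)
        consumed[b] <- TRUE
      }
    }
  }

  # follicle-associated endings, follicles in id order (deterministic).
  # Branch nodes are flattened once so the per-follicle work is vectorized.
  if (nrow(fol)) {
    bn_branch <- rep.int(seq_along(branches),
                         lengths(branches) - 1L)
    bn_rows <- unlist(lapply(branches, function(p) p[-length(p)]))
    bn_pos <- unlist(lapply(lengths(branches) - 1L, seq_len))
    bx <- nd$x[bn_rows]; by <- nd$y[bn_rows]
    lx <- nd$x[leaf_rows]; ly <- nd$y[leaf_rows]
    ord <- order(fol$follicle_id)
    for (j in ord) {
      cx <- fol$cx[j]; cy <- fol$cy[j]; r <- fol$diameter[j] / 2
      # lanceolate: vertical twig leaves within the attachment radius
      near <- abs(lx - cx) <= params$attach_radius &
        abs(ly - cy) <= params$attach_radius
      tw <- which(!consumed & is_twig & near)
      if (length(tw)) {
        d_leaf <- sqrt((lx[tw] - cx)^2 + (ly[tw] - cy)^2)
        tw <- tw[d_leaf <= params$attach_radius]
      }
      if (length(tw) >= params$min_twigs) {
        lr <- leaf_rows[tw]
        mem <- unique(unlist(lapply(branches[tw],
                                    function(p) p[-length(p)])))
        arc <- angular_span(rad2deg(atan2(nd$y[lr] - cy, nd$x[lr] - cx))) / 360
        add("lanceolate", mem, fol$follicle_id[j], max(arc, 1e-3))
        consumed[tw] <- TRUE
        next
      }
      # circumferential: a ring arc must reach the band at its leaf end --
      # only the contiguous run of in-band nodes starting at the leaf of an
      # unconsumed non-twig branch contributes, which rejects branches that
      # merely pass through the band.
      rmax <- r + params$ring_tol
      sel <- which(!consumed[bn_branch] & !is_twig[bn_branch] &
                     abs(bx - cx) <= rmax & abs(by - cy) <= rmax)
      if (length(sel) < params$min_ring_nodes) next
      dr <- sqrt((bx[sel] - cx)^2 + (by[sel] - cy)^2)
      sel <- sel[abs(dr - r) <= params$ring_tol]
      if (length(sel) < params$min_ring_nodes) next
      band_rows <- integer(0); band_br <- integer(0)
      for (b in unique(bn_branch[sel])) {
        pos <- sort(bn_pos[sel[bn_branch[sel] == b]])
        k <- match(FALSE, pos == seq_along(pos), nomatch = length(pos) + 1L) - 1L
        if (k >= 1L) {
          band_rows <- c(band_rows, branches[[b]][seq_len(k)])
          band_br <- c(band_br, b)
        }
      }
      if (length(band_rows) < params$min_ring_nodes) next
      span <- angular_span(rad2deg(atan2(nd$y[band_rows] - cy,
                                         nd$x[band_rows] - cx)))
      if (span < params$min_ring_span) next
      add("circumferential", band_rows, fol$follicle_id[j], span / 360)
      consumed[band_br] <- TRUE
    }
  }

  # everything else is a free ending, one per remaining terminal branch
  for (b in which(!consumed)) {
    p <- branches[[b]]
    add("free", p[-length(p)], NA_integer_, NA_real_)
  }

  if (!length(rows)) return(empty_ending_set())
  new_ending_set(do.call(rbind, rows), members)
}

#' Assign endings to their nearest follicle
#'
#' Each follicle-associated ending (lanceolate, circumferential, merkel) is
#' assigned to the nearest follicle whose center lies within `attach_radius`
#' of the ending centroid; equidistant candidates resolve to the lower
#' follicle id. Endings with no follicle in range keep `follicle_id = NA`.
#' The operation is idempotent.
#'
#' @param endings An `ending_set` from [detect_terminal_endings()].
#' @param follicle_map A [follicle_map()].
#' @param attach_radius Attachment radius, micrometers.
#' @return The updated `ending_set`.
#' @export
assign_endings_to_follicles <- function(endings, follicle_map,
                                        attach_radius = 40) {
  stopifnot(inherits(endings, "ending_set"),
            inherits(follicle_map, "follicle_map"), attach_radius > 0)
  fol <- follicle_map$follicles
  if (!nrow(endings) || !nrow(fol)) return(endings)
  ord <- order(fol$follicle_id)
  fol <- fol[ord, ]
  idx <- which(endings$kind %in% c("lanceolate", "circumferential", "merkel"))
  for (i in idx) {
    d <- sqrt((fol$cx - endings$centroid_x[i])^2 +
              (fol$cy - endings$centroid_y[i])^2)
    j <- which(d <= attach_radius)
    if (!length(j)) { endings$follicle_id[i] <- NA_integer_; next }
    j <- j[order(d[j], fol$follicle_id[j])][1]
    endings$follicle_id[i] <- as.integer(fol$follicle_id[j])
  }
  endings
}

#' Innervation summary for one arbor
#'
#' Counts the distinct follicles carrying a follicle-associated ending and
#' derives the innervation statistics: the innervation index (innervated
#' follicles per square micrometer of arbor hull area) and the fraction of
#' follicles innervated among those whose centers fall inside the arbor's
#' convex hull (boundary counts as inside).
#'
#' @param endings An `ending_set` with follicle assignments.
#' @param hull Hull polygon (2-column matrix from [convex_hull_polygon()]) or
#'   an [arbor_trace()] from which it is computed.
#' @param follicle_map A [follicle_map()].
#' @return List with `n_follicles_innervated`, `n_follicles_in_hull`,
#'   `innervation_index`, `fraction_innervated` (NA, with attribute
#'   `"flag"`, when no follicle center lies in the hull) and
#'   `mean_arc_fraction`.
#' @export
innervation_summary <- function(endings, hull, follicle_map) {
  stopifnot(inherits(endings, "ending_set"),
            inherits(follicle_map, "follicle_map"))
  if (inherits(hull, "arbor_trace")) hull <- convex_hull_polygon(hull)
  hull_area <- polygon_area(hull)
  if (hull_area <= 0)
    stop("innervation summary requires a positive hull area", call. = FALSE)
  fa <- endings$kind %in% c("lanceolate", "circumferential", "merkel") &
    !is.na(endings$follicle_id)
  innervated <- unique(endings$follicle_id[fa])
  fol <- follicle_map$follicles
  in_hull <- if (nrow(fol))
    sum(in_convex_hull(fol$cx, fol$cy, hull)) else 0L
  frac <- if (in_hull > 0) {
    min(length(innervated) / in_hull, 1)
  } else if (length(innervated) == 0) 0 else
    structure(NA_real_, flag = "no follicles inside hull")
  list(n_follicles_innervated = length(innervated),
       n_follicles_in_hull = as.integer(in_hull),
       innervation_index = length(innervated) / hull_area,
       fraction_innervated = frac,
       mean_arc_fraction = if (any(fa)) mean(endings$arc_fraction[fa],
                                             na.rm = TRUE) else NA_real_)
}

#' Coverage factor estimators
#'
#' `coverage_factor_area` is the area-based estimator: the mean territory
#' covered by arbors of a type multiplied by the number of such arbors per
#' unit skin area -- the expected number of same-type arbors overlying a
#' random skin point.
#'
#' @param mean_arbor_area Mean arbor hull area, square micrometers (>= 0).
#' @param arbor_density Arbors of the type per square micrometer (>= 0).
#' @return Dimensionless coverage factor.
#' @export
coverage_factor_area <- function(mean_arbor_area, arbor_density) {
  stopifnot(mean_arbor_area >= 0, arbor_density >= 0)
  mean_arbor_area * arbor_density
}

#' @rdname coverage_factor_area
#' @details `coverage_factor_follicle` is the follicle-occupancy estimator:
#'   under the assumption that each follicle's circumference is fully and
#'   uniformly occupied by endings of the type, a type contacting a fraction
#'   `g` of follicles while individual endings occupy a mean fraction `f` of
#'   the circumference implies `g / f` arbors sharing each follicle.
#' @param g Fraction of follicles contacted by the type, in `[0, 1]`.
#' @param f Mean arc fraction occupied per ending, in `(0, 1]`.
#' @export
coverage_factor_follicle <- function(g, f) {
  stopifnot(g >= 0, g <= 1, f <= 1)
  if (f <= 0) stop("mean arc fraction must be positive", call. = FALSE)
  g / f
}
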