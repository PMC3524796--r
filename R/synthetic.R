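# Synthetic follicle lattices and arbors of all ten morphologic types, with
# per-type parameters matching the published per-type statistics, plus an
# independent-tracing noise model. Every generated object satisfies the
# arbor_trace / follicle_map invariants and is fully deterministic under
# (config, seed).

#' Per-type generator parameters
#'
#' One entry per morphologic type. Territory sizes, depths, branch and
#' length ranges, occupancy fractions and ending geometry follow the
#' published per-type descriptions; distribution families (log-normal areas
#' and lengths, uniform diameters, binomial occupancy) are modeling choices.
#' Two LA-FACE constants (territory diameter and occupancy range) were fixed
#' by a one-off calibration of the full generate-and-measure loop at a fixed
#' seed so that the measured survey means sit at the published values; they
#' are frozen here.
#'
#' @return Named list of per-type parameter lists.
#' @export
default_type_params <- function() {
  list(
    "HD-FALE" = list(kind = "lanceolate",
                     area_mean = 3.4e5, area_sd = 3.2e5,
                     area_clip = c(1e5, 2.5e6),
                     occupancy = 0.9, depth = 50, guard_depth = 40,
                     twig_range = c(4, 7), c_arc_deg = 200, c_kappa = 8,
                     step = 40),
    "LD-FALE" = list(kind = "lanceolate",
                     diameter_range = c(1000, 2000),
                     occupancy = 0.08, min_targets = 2,
                     depth = 50, guard_depth = 40,
                     twig_range = c(4, 7), c_arc_deg = 200, c_kappa = 8,
                     step = 50),
    "I-FALE"  = list(kind = "lanceolate", single = TRUE, prefer_guard = TRUE,
                     depth = 40, twig_range = c(6, 9), c_arc_deg = 280,
                     c_kappa = 8, step = 40),
    "I-FACE"  = list(kind = "circumferential", single = TRUE,
                     prefer_guard = TRUE, depth = 40,
                     arc_range = c(0.5, 1), step = 40),
    "SA-FACE" = list(kind = "circumferential",
                     n_base = 2, n_binom = 4, n_p = 0.45,
                     diameter_range = c(300, 500), depth = 50,
                     arc_range = c(0.4, 1), step = 40),
    "LA-FACE" = list(kind = "circumferential",
                     diameter_range = c(1670, 2540),
                     occupancy_range = c(0.36, 0.76),
                     depth = 50, guard_depth = 40,
                     arc_range = c(0.4, 1), step = 50),
    "BE"      = list(kind = "free",
                     diameter_range = c(500, 1000),
                     depth_range = c(5, 10),
                     length_meanlog = log(9.5e4), length_sdlog = 0.22,
                     length_clip = c(6e4, 1.6e5),
                     len_per_branch = 100, step = 25),
    "TE"      = list(kind = "free", thick = TRUE,
                     diameter_range = c(300, 500), depth_range = c(17, 23),
                     bp_range = c(25, 75), len_per_bp = c(150, 200),
                     thick_len = c(50, 100), thick_radius = 1.6,
                     base_radius = 0.5, step = 25),
    "LA-FE"   = list(kind = "free", two_tier = TRUE,
                     outer_diameter = 4000, inner_diameter = 3000,
                     outer_depth_range = c(7, 13),
                     inner_depth_range = c(67, 73),
                     outer_length_range = c(5.5e5, 9.5e5),
                     inner_length_range = c(1.0e5, 1.5e5),
                     connector_range = c(55, 80),
                     outer_len_per_branch = 250,
                     inner_len_per_branch = 400, step = 60),
    "MCA"     = list(kind = "merkel", single = TRUE, prefer_guard = FALSE,
                     depth = 25, twig_range = c(8, 14),
                     arc_range = c(0.5, 0.75), step = 40)
  )
}

#' Generator configuration
#'
#' @param lattice_density Follicles per square micrometer (default 1e-4,
#'   derived so that a high-density lanceolate arbor occupying ~90% of the
#'   follicles in a mean ~3.4e5 um^2 territory innervates ~30 of them).
#' @param guard_fraction Fraction of follicles that are large-diameter guard
#'   hairs.
#' @param lattice_jitter Uniform positional jitter of lattice sites,
#'   micrometers.
#' @param tilt_sd_deg Angular SD of follicle tilt about the
#'   anterior-posterior (+x) axis, degrees (under 10 on wild-type back skin).
#' @param type_params Per-type parameter table, see [default_type_params()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(lattice_density = 1e-4, guard_fraction = 0.04,
                             lattice_jitter = 18, tilt_sd_deg = 8,
                             type_params = default_type_params()) {
  stopifnot(lattice_density > 0, guard_fraction >= 0, guard_fraction <= 1,
            lattice_jitter >= 0, tilt_sd_deg >= 0)
  structure(list(lattice_density = lattice_density,
                 guard_fraction = guard_fraction,
                 lattice_jitter = lattice_jitter,
                 tilt_sd_deg = tilt_sd_deg,
                 type_params = type_params),
            class = "generator_config")
}

#' Generate a jittered hair-follicle lattice
#'
#' Square lattice at the configured density with uniform positional jitter,
#' a sparse fraction of large-diameter guard follicles, and tilt vectors
#' scattered about the +x (anterior-to-posterior) axis.
#'
#' @param config A [generator_config()].
#' @param bounds `c(xmin, xmax, ymin, ymax)` in micrometers.
#' @param seed Optional integer seed (local to this call).
#' @param id_offset First follicle id minus one.
#' @return A [follicle_map()].
#' @export
generate_follicle_lattice <- function(config = generator_config(), bounds,
                                      seed = NULL, id_offset = 0L) {
  stopifnot(inherits(config, "generator_config"), length(bounds) == 4L)
  if ((bounds[2] - bounds[1]) * (bounds[4] - bounds[3]) <= 0)
    stop("bounds area must be positive", call. = FALSE)
  with_seed(seed, {
    s <- 1 / sqrt(config$lattice_density)
    gx <- seq(bounds[1] + s / 2, bounds[2], by = s)
    gy <- seq(bounds[3] + s / 2, bounds[4], by = s)
    cx <- rep(gx, times = length(gy))
    cy <- rep(gy, each = length(gx))
    n <- length(cx)
    j <- config$lattice_jitter
    cx <- pmin(pmax(cx + stats::runif(n, -j, j), bounds[1]), bounds[2])
    cy <- pmin(pmax(cy + stats::runif(n, -j, j), bounds[3]), bounds[4])
    guard <- stats::runif(n) < config$guard_fraction
    diameter <- ifelse(guard, stats::runif(n, 44, 56),
                       stats::runif(n, 16, 30))
    ang <- deg2rad(stats::rnorm(n, 0, config$tilt_sd_deg))
    follicle_map(data.frame(follicle_id = id_offset + seq_len(n),
                            cx = cx, cy = cy, diameter = diameter,
                            guard = guard,
                            tilt_x = cos(ang), tilt_y = sin(ang)),
                 bounds)
  })
}

# --- internal node store and growth primitives -----------------------------

node_store <- function(capacity = 1024L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$x <- env$y <- env$z <- env$r <- numeric(capacity)
  env$parent <- integer(capacity)
  env
}

ns_add <- function(env, x, y, z, r, parent) {
  n <- env$n + 1L
  if (n > length(env$x)) {
    grow <- function(v) { length(v) <- 2L * length(v); v }
    env$x <- grow(env$x); env$y <- grow(env$y); env$z <- grow(env$z)
    env$r <- grow(env$r); env$parent <- grow(env$parent)
  }
  env$x[n] <- x; env$y[n] <- y; env$z[n] <- z; env$r[n] <- r
  env$parent[n] <- parent
  env$n <- n
  n
}

ns_nodes <- function(env) {
  n <- env$n
  data.frame(node_id = seq_len(n), x = env$x[seq_len(n)],
             y = env$y[seq_len(n)], z = env$z[seq_len(n)],
             radius = env$r[seq_len(n)], parent_id = env$parent[seq_len(n)])
}

# straight-ish path from node `from` to (x, y, z) in steps of ~`step` um with
# small lateral jitter; returns the id of the final node (placed exactly).
ns_path <- function(env, from, x, y, z, step, jitter = 0.15) {
  x0 <- env$x[from]; y0 <- env$y[from]; z0 <- env$z[from]
  d <- sqrt((x - x0)^2 + (y - y0)^2 + (z - z0)^2)
  nseg <- max(1L, ceiling(d / step))
  t <- seq_len(nseg) / nseg
  jx <- c(stats::rnorm(nseg - 1L, 0, jitter * step), 0)
  jy <- c(stats::rnorm(nseg - 1L, 0, jitter * step), 0)
  cur <- from
  for (i in seq_len(nseg))
    cur <- ns_add(env, x0 + (x - x0) * t[i] + jx[i],
                  y0 + (y - y0) * t[i] + jy[i],
                  z0 + (z - z0) * t[i], 0, cur)
  cur
}

# Random branching growth confined to a disk: adds ~total_len/step segments
# and exactly n_branch branch points (each branch event creates two children
# of the active tip at once). `branch_first` forces the root's first event
# to be a branch, so the root node itself becomes a junction.
ns_grow_free <- function(env, root, center, radius, z_range, total_len,
                         n_branch, step, branch_first = FALSE) {
  n_branch <- max(if (branch_first) 1L else 0L, as.integer(n_branch))
  steps_total <- max(n_branch + 1L, as.integer(round(total_len / step)) -
                       n_branch)
  branch_at <- rep(FALSE, steps_total)
  pool <- if (branch_first) 2:steps_total else seq_len(steps_total)
  extra <- n_branch - as.integer(branch_first)
  if (extra > 0)
    branch_at[sample(pool, min(extra, length(pool)))] <- TRUE
  if (branch_first) branch_at[1] <- TRUE
  tip_node <- root
  tip_dir <- stats::runif(1, 0, 2 * pi)
  n_tips <- 1L
  new_xy <- function(node, dir) {
    px <- env$x[node]; py <- env$y[node]
    dir <- dir + stats::rnorm(1, 0, 0.5)
    nx <- px + step * cos(dir); ny <- py + step * sin(dir)
    if ((nx - center[1])^2 + (ny - center[2])^2 > radius^2) {
      dir <- atan2(center[2] - py, center[1] - px) + stats::rnorm(1, 0, 0.4)
      nx <- px + step * cos(dir); ny <- py + step * sin(dir)
    }
    c(nx, ny, dir)
  }
  zr <- function() stats::runif(1, z_range[1], z_range[2])
  for (s in seq_len(steps_total)) {
    i <- sample.int(n_tips, 1L)
    if (branch_at[s]) {
      split <- stats::runif(1, pi / 4, 2 * pi / 3)
      fork <- tip_node[i]
      fork_dir <- tip_dir[i]
      for (sgn in c(-1, 1)) {
        p <- new_xy(fork, fork_dir + sgn * split / 2)
        id <- ns_add(env, p[1], p[2], zr(), 0, fork)
        if (sgn < 0) { tip_node[i] <- id; tip_dir[i] <- p[3] }
        else {
          n_tips <- n_tips + 1L
          tip_node[n_tips] <- id; tip_dir[n_tips] <- p[3]
        }
      }
    } else {
      p <- new_xy(tip_node[i], tip_dir[i])
      tip_node[i] <- ns_add(env, p[1], p[2], zr(), 0, tip_node[i])
      tip_dir[i] <- p[3]
    }
  }
  invisible(env)
}

# lanceolate C-palisade on one follicle: k vertical twigs on an arc of the
# follicle circumference whose center faces direction theta_c.
ns_lanceolate <- function(env, attach, fol_row, depth, k, arc_deg, theta_c) {
  r <- fol_row$diameter / 2
  collar <- ns_add(env,
                   fol_row$cx + (r + 6) * cos(theta_c),
                   fol_row$cy + (r + 6) * sin(theta_c),
                   depth - 9, 0, attach)
  th <- theta_c + deg2rad(seq(-arc_deg / 2, arc_deg / 2, length.out = k)) +
    stats::rnorm(k, 0, 0.03)
  # each palisade element runs parallel to the hair shaft: a ~13 um vertical
  # segment whose terminal sits at the nominal ending depth
  for (t in th) {
    bx <- fol_row$cx + (r + 2) * cos(t)
    by <- fol_row$cy + (r + 2) * sin(t)
    base <- ns_add(env, bx, by, depth - 13 + stats::runif(1, -1, 1), 0,
                   collar)
    ns_add(env, bx + stats::rnorm(1, 0, 0.4), by + stats::rnorm(1, 0, 0.4),
           depth + stats::runif(1, -1, 1), 0, base)
  }
  invisible(env)
}

# circumferential ring arc on one follicle, entered from direction theta0.
ns_ring <- function(env, attach, fol_row, depth, arc_fraction, theta0) {
  r <- fol_row$diameter / 2 + 1
  span <- arc_fraction * 360
  m <- max(6L, ceiling(span / 24) + 1L)
  th <- theta0 + deg2rad(seq(0, span, length.out = m))
  cur <- attach
  for (t in th)
    cur <- ns_add(env, fol_row$cx + r * cos(t), fol_row$cy + r * sin(t),
                  depth + stats::runif(1, -0.5, 0.5), 0, cur)
  invisible(env)
}

# backbone connecting an entry point to each target follicle in turn,
# attaching every target to the nearest already-built backbone node.
# Returns per-target attachment node ids and approach angles.
ns_backbone <- function(env, root, targets, depth, step) {
  bb_ids <- seq_len(env$n)  # entry path nodes
  att <- integer(nrow(targets)); appr <- numeric(nrow(targets))
  if (!nrow(targets)) return(list(attach = att, approach = appr))
  ord <- order((targets$cx - mean(env$x[bb_ids]))^2 +
                 (targets$cy - mean(env$y[bb_ids]))^2)
  for (i in ord) {
    d2 <- (env$x[bb_ids] - targets$cx[i])^2 +
      (env$y[bb_ids] - targets$cy[i])^2
    from <- bb_ids[which.min(d2)]
    a <- atan2(env$y[from] - targets$cy[i], env$x[from] - targets$cx[i])
    r <- targets$diameter[i] / 2
    end <- ns_path(env, from,
                   targets$cx[i] + (r + 10) * cos(a),
                   targets$cy[i] + (r + 10) * sin(a),
                   depth, step)
    new_ids <- setdiff(seq_len(env$n), c(bb_ids, att))
    bb_ids <- c(bb_ids, new_ids)
    att[i] <- end
    appr[i] <- a
  }
  list(attach = att, approach = appr, backbone = bb_ids)
}

# short branches from the backbone out to the territory rim: traced arbors
# ramify across their whole territory, so the convex hull tracks the
# territory boundary rather than the outermost follicle contact.
ns_rim_reach <- function(env, backbone, center, radius, depth, step,
                         n_targets) {
  n_rim <- max(4L, min(round(pi * 2 * radius / 170),
                       4L + 2L * n_targets, 24L))
  th <- stats::runif(1, 0, 2 * pi) +
    seq(0, 2 * pi, length.out = n_rim + 1)[-1]
  for (t in th) {
    rx <- center[1] + radius * cos(t)
    ry <- center[2] + radius * sin(t)
    d2 <- (env$x[backbone] - rx)^2 + (env$y[backbone] - ry)^2
    ns_path(env, backbone[which.min(d2)], rx, ry, depth, step)
  }
  invisible(env)
}

# --- arbor generation ------------------------------------------------------

territory_diameter <- function(tp) {
  if (!is.null(tp$area_mean)) {
    s2 <- log(1 + (tp$area_sd / tp$area_mean)^2)
    a <- stats::rlnorm(1, log(tp$area_mean) - s2 / 2, sqrt(s2))
    a <- min(max(a, tp$area_clip[1]), tp$area_clip[2])
    2 * sqrt(a / pi)
  } else if (!is.null(tp$diameter_range)) {
    stats::runif(1, tp$diameter_range[1], tp$diameter_range[2])
  } else if (!is.null(tp$outer_diameter)) {
    tp$outer_diameter
  } else 200
}

#' Generate one synthetic arbor
#'
#' Grows a rooted trace of the requested morphologic type inside a follicle
#' map: a single afferent axon enters from below (z ~ 120 um), rises to the
#' type's depth stratum, and elaborates the type's territory, branching
#' structure and terminal specializations. Follicle-targeting types place
#' lanceolate palisades or circumferential ring arcs on an
#' occupancy-determined subset of in-territory follicles; C-shaped
#' lanceolate palisades are biased to the posterior (+x) side of their
#' follicle so the opening of the C faces anterior. Thick-ending arbors get
#' enlarged radii over the final 50-100 um of each branch; large free-ending
#' arbors are built as two stratified tiers joined by >50 vertical
#' connectors.
#'
#' @param type One of [arbor_type_labels()].
#' @param config A [generator_config()].
#' @param follicle_map A [follicle_map()] covering the territory, or `NULL`
#'   to generate a fresh lattice patch sized to the territory.
#' @param seed Optional integer seed (local to this call).
#' @param arbor_id Identifier for the trace.
#' @param center Territory center `c(x, y)`; defaults to the map center.
#' @return List with `trace` (an [arbor_trace()] whose metadata carries
#'   `true_label` and, for Merkel arbors, `ending_type = "merkel"`),
#'   `follicle_map`, and `truth` (type, target follicle ids, occupancy).
#' @export
generate_arbor <- function(type, config = generator_config(),
                           follicle_map = NULL, seed = NULL,
                           arbor_id = paste0("S-", type), center = NULL) {
  stopifnot(inherits(config, "generator_config"))
  tp <- config$type_params[[type]]
  if (is.null(tp)) stop("no generator parameters for type ", type,
                        call. = FALSE)
  with_seed(seed, {
    D <- territory_diameter(tp)
    if (is.null(follicle_map)) {
      half <- D / 2 + 150
      follicle_map <- generate_follicle_lattice(
        config, c(-half, half, -half, half))
    }
    b <- follicle_map$bounds
    if (is.null(center)) center <- c((b[1] + b[2]) / 2, (b[3] + b[4]) / 2)
    fol <- follicle_map$follicles
    env <- node_store()
    truth <- list(type = type, territory_diameter = D,
                  target_follicles = integer(0), occupancy = NA_real_)

    if (tp$kind %in% c("lanceolate", "circumferential", "merkel")) {
      # choose target follicles
      if (isTRUE(tp$single)) {
        cand <- if (isTRUE(tp$prefer_guard) && any(fol$guard))
          fol[fol$guard, ] else fol
        d2 <- (cand$cx - center[1])^2 + (cand$cy - center[2])^2
        targets <- cand[which.min(d2), , drop = FALSE]
        center <- c(targets$cx[1], targets$cy[1])
      } else {
        inside <- fol[(fol$cx - center[1])^2 + (fol$cy - center[2])^2 <=
                        (D / 2)^2, , drop = FALSE]
        if (!nrow(inside))
          stop("no follicles inside the territory; enlarge the map",
               call. = FALSE)
        if (!is.null(tp$n_base)) {                       # fixed small count
          n_t <- tp$n_base + stats::rbinom(1, tp$n_binom, tp$n_p)
          n_t <- min(n_t, nrow(inside))
          d2 <- (inside$cx - center[1])^2 + (inside$cy - center[2])^2
          targets <- inside[order(d2)[seq_len(n_t)], , drop = FALSE]
        } else {                                         # occupancy fraction
          occ <- if (!is.null(tp$occupancy_range))
            stats::runif(1, tp$occupancy_range[1], tp$occupancy_range[2])
          else tp$occupancy
          truth$occupancy <- occ
          take <- stats::runif(nrow(inside)) < occ
          if (sum(take) < (tp$min_targets %||% 1))
            take[sample.int(nrow(inside),
                            min(nrow(inside), tp$min_targets %||% 1))] <- TRUE
          targets <- inside[take, , drop = FALSE]
        }
      }
      truth$target_follicles <- sort(targets$follicle_id)
      depth_of <- function(row) {
        if (isTRUE(row$guard) && !is.null(tp$guard_depth))
          tp$guard_depth else tp$depth
      }
      # entry from below, then rise to the working depth near the center
      root <- ns_add(env, center[1] + stats::runif(1, -30, 30),
                     center[2] + stats::runif(1, -30, 30), 120, 0, -1L)
      ns_path(env, root, center[1], center[2], tp$depth, tp$step)
      bb <- ns_backbone(env, root, targets, tp$depth, tp$step)
      if (!isTRUE(tp$single))
        ns_rim_reach(env, bb$backbone, center, D / 2, tp$depth, tp$step,
                     nrow(targets))
      for (i in seq_len(nrow(targets))) {
        row <- targets[i, ]
        if (tp$kind == "circumferential") {
          arc <- stats::runif(1, tp$arc_range[1], tp$arc_range[2])
          ns_ring(env, bb$attach[i], row, depth_of(row), arc,
                  bb$approach[i] + stats::runif(1, 0, 2 * pi))
        } else {
          k <- sample(seq(tp$twig_range[1], tp$twig_range[2]), 1)
          arc_deg <- tp$c_arc_deg %||% 200
          # posterior-facing C body (opening anterior): von Mises-like
          theta_c <- if (tp$kind == "merkel")
            stats::runif(1, 0, 2 * pi)
          else stats::rnorm(1, 0, 1 / sqrt(tp$c_kappa))
          if (tp$kind == "merkel") {
            arc_deg <- stats::runif(1, tp$arc_range[1], tp$arc_range[2]) * 360
            k <- sample(seq(tp$twig_range[1], tp$twig_range[2]), 1)
          }
          ns_lanceolate(env, bb$attach[i], row, depth_of(row), k, arc_deg,
                        theta_c)
        }
      }
    } else if (isTRUE(tp$two_tier)) {
      root <- ns_add(env, center[1], center[2] + stats::runif(1, -50, 50),
                     120, 0, -1L)
      inner_top <- ns_path(env, root, center[1], center[2],
                           mean(tp$inner_depth_range), tp$step)
      L_in <- stats::runif(1, tp$inner_length_range[1],
                           tp$inner_length_range[2])
      ns_grow_free(env, inner_top, center, tp$inner_diameter / 2,
                   tp$inner_depth_range, L_in,
                   round(L_in / tp$inner_len_per_branch), tp$step)
      # vertical connectors from mid-path inner nodes up to the outer tier
      nch <- tabulate(env$parent[seq_len(env$n)][env$parent[seq_len(env$n)] > 0],
                      nbins = env$n)
      cand <- which(nch == 1L & env$z[seq_len(env$n)] > 60 &
                      env$z[seq_len(env$n)] < 80)
      K <- sample(seq(tp$connector_range[1], tp$connector_range[2]), 1)
      K <- min(K, length(cand))
      picks <- sample(cand, K)
      L_out <- stats::runif(1, tp$outer_length_range[1],
                            tp$outer_length_range[2])
      for (p in picks) {
        mid <- ns_add(env, env$x[p], env$y[p], 40, 0, p)
        top <- ns_add(env, env$x[p], env$y[p],
                      stats::runif(1, tp$outer_depth_range[1],
                                   tp$outer_depth_range[2]), 0, mid)
        Lk <- L_out / K
        ns_grow_free(env, top, center, tp$outer_diameter / 2,
                     tp$outer_depth_range, Lk,
                     max(2, round(Lk / tp$outer_len_per_branch)), tp$step,
                     branch_first = TRUE)
      }
    } else {  # single-tier free-ending arbor (BE, TE)
      root <- ns_add(env, center[1] + stats::runif(1, -40, 40),
                     center[2], 120, 0, -1L)
      zr <- tp$depth_range
      start <- ns_path(env, root, center[1], center[2], mean(zr), tp$step)
      if (!is.null(tp$bp_range)) {
        B <- sample(seq(tp$bp_range[1], tp$bp_range[2]), 1)
        L <- B * stats::runif(1, tp$len_per_bp[1], tp$len_per_bp[2])
      } else {
        L <- stats::rlnorm(1, tp$length_meanlog, tp$length_sdlog)
        L <- min(max(L, tp$length_clip[1]), tp$length_clip[2])
        B <- round(L / tp$len_per_branch)
      }
      ns_grow_free(env, start, center, D / 2, zr, L, B, tp$step,
                   branch_first = TRUE)
      if (isTRUE(tp$thick)) {
        env$r[seq_len(env$n)] <- tp$base_radius
        nodes_tmp <- ns_nodes(env)
        len <- segment_lengths(nodes_tmp)
        for (p in terminal_branches(nodes_tmp)) {
          window <- stats::runif(1, tp$thick_len[1], tp$thick_len[2])
          cum <- cumsum(len[p[-length(p)]])
          take <- p[c(TRUE, cum < window)]
          take <- take[seq_len(min(length(take), length(p) - 1L))]
          env$r[take] <- tp$thick_radius
        }
      }
    }

    md <- list(true_label = type, skin_id = "synthetic")
    if (tp$kind == "merkel") md$ending_type <- "merkel"
    trace <- arbor_trace(ns_nodes(env), arbor_id = arbor_id, metadata = md)
    list(trace = trace, follicle_map = follicle_map, truth = truth)
  })
}

#' Generate a synthetic survey
#'
#' Independent arbors of each requested type, each on a fresh follicle
#' lattice patch sized to its territory. Deterministic under `seed`:
#' identical configuration and seed reproduce the survey byte-for-byte.
#'
#' @param config A [generator_config()].
#' @param n_per_type Named integer vector, e.g. `c("HD-FALE" = 300)`.
#' @param seed Integer master seed; per-arbor seeds are derived from it.
#' @return A list of class `synthetic_survey`; element `arbors` is a list of
#'   [generate_arbor()] results.
#' @export
generate_survey <- function(config = generator_config(), n_per_type,
                            seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(names(n_per_type)) || any(!nzchar(names(n_per_type))))
    stop("n_per_type must be a named vector of type counts", call. = FALSE)
  stopifnot(all(n_per_type >= 0))
  types <- rep(names(n_per_type), times = n_per_type)
  seeds <- derive_seeds(seed, length(types))
  arbors <- vector("list", length(types))
  counter <- stats::setNames(integer(length(n_per_type)), names(n_per_type))
  for (i in seq_along(types)) {
    ty <- types[i]
    counter[ty] <- counter[ty] + 1L
    arbors[[i]] <- generate_arbor(ty, config, follicle_map = NULL,
                                  seed = seeds[[i]],
                                  arbor_id = sprintf("S-%s-%03d", ty,
                                                     counter[ty]))
  }
  structure(list(arbors = arbors, config = config, seed = seed),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  types <- vapply(x$arbors, function(a) a$truth$type, character(1))
  cat("<synthetic_survey> ", length(types), " arbors\n", sep = "")
  print(table(types))
  invisible(x)
}

#' Export a synthetic survey to disk
#'
#' Writes one SWC file and one follicle-map CSV per arbor plus a
#' `ground_truth.csv` table, the on-disk form consumed by [run_survey()].
#'
#' @param survey A `synthetic_survey`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data frame listing the written trace files.
#' @export
export_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(survey$arbors, function(a) {
    id <- a$trace$arbor_id
    write_swc(a$trace, file.path(dir, paste0(id, ".swc")))
    write_follicle_map(a$follicle_map,
                       file.path(dir, paste0(id, "_follicles.csv")))
    data.frame(arbor_id = id, true_label = a$truth$type,
               swc = paste0(id, ".swc"),
               follicle_csv = paste0(id, "_follicles.csv"))
  })
  idx <- do.call(rbind, rows)
  utils::write.csv(idx, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(idx)
}

#' Simulate two independent tracings of the same arbor
#'
#' Emulates the reproducibility of independent manual tracings: each copy
#' receives Gaussian coordinate jitter (SD = `xy_sd_frac` of the mean
#' segment length) and random dropout of terminal twigs at rate `dropout`
#' (optionally, duplication of surviving twigs at rate `addition`).
#'
#' @param trace An [arbor_trace()].
#' @param noise List with `xy_sd_frac` (default 0.02), `dropout` (default
#'   0.03) and `addition` (default 0).
#' @param seed Optional integer seed (local to this call).
#' @return List with elements `a` and `b`, two independently perturbed
#'   copies. A copy left with fewer than 2 terminals is flagged with a
#'   `"degenerate"` attribute.
#' @export
generate_trace_pair <- function(trace,
                                noise = list(xy_sd_frac = 0.02,
                                             dropout = 0.03, addition = 0),
                                seed = NULL) {
  stopifnot(inherits(trace, "arbor_trace"))
  xy_sd_frac <- noise$xy_sd_frac %||% 0.02
  dropout <- noise$dropout %||% 0.03
  addition <- noise$addition %||% 0
  perturb <- function(tr) {
    nd <- tr$nodes
    if (dropout > 0) {
      drop_rows <- integer(0)
      for (p in terminal_branches(nd))
        if (stats::runif(1) < dropout)
          drop_rows <- c(drop_rows, p[-length(p)])
      if (length(drop_rows) && length(drop_rows) < nrow(nd) - 1L)
        nd <- nd[-drop_rows, , drop = FALSE]
    }
    if (xy_sd_frac > 0 && nrow(nd) > 1) {
      sd <- xy_sd_frac * mean(segment_lengths_raw(nd))
      nonroot <- nd$parent_id != -1
      n <- sum(nonroot)
      nd$x[nonroot] <- nd$x[nonroot] + stats::rnorm(n, 0, sd)
      nd$y[nonroot] <- nd$y[nonroot] + stats::rnorm(n, 0, sd)
      nd$z[nonroot] <- pmax(0, nd$z[nonroot] + stats::rnorm(n, 0, sd))
    }
    if (addition > 0) {
      for (p in terminal_branches(nd)) {
        if (stats::runif(1) < addition) {
          leaf <- p[1]
          nd <- rbind(nd, data.frame(
            node_id = max(nd$node_id) + 1L, type = 0,
            x = nd$x[leaf] + stats::rnorm(1, 0, 3),
            y = nd$y[leaf] + stats::rnorm(1, 0, 3),
            z = nd$z[leaf], radius = nd$radius[leaf],
            parent_id = nd$node_id[leaf]))
        }
      }
    }
    out <- arbor_trace(nd, arbor_id = tr$arbor_id, metadata = tr$metadata)
    if (terminal_count(out) < 2) attr(out, "degenerate") <- TRUE
    out
  }
  with_seed(seed, list(a = perturb(trace), b = perturb(trace)))
}

# segment lengths without requiring a full arbor_trace (used on partially
# pruned node tables whose columns match)
segment_lengths_raw <- function(nd) {
  len <- segment_lengths(nd)
  len[len > 0]
}
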