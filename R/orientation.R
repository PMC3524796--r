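# Orientation of C-shaped lanceolate endings relative to the follicle axis,
# and the circular statistics used to summarize them.
#
# Back-skin hair follicles tilt anterior-to-posterior (+x) with small
# scatter. A C-shaped lanceolate palisade sits eccentrically on its
# follicle; its orientation vector V_NE points from the follicle center to
# the centroid of the palisade (the body of the C), so an ending whose
# opening faces the anterior has V_NE parallel to the follicle vector V_HF
# and an angle near 0 degrees.

#' Orientation of one lanceolate ending
#'
#' @param ending One row of an `ending_set` (a data frame row) of kind
#'   `lanceolate` with an assigned follicle and at least 3 member nodes.
#' @param follicle The matching row of a follicle map's `follicles` data
#'   frame (with `cx`, `cy`, `tilt_x`, `tilt_y`).
#' @return List with `arbor_id` (NA unless supplied), `follicle_id`, `v_ne`,
#'   `v_hf` (unit 2-vectors) and `angle` in degrees, folded to `[0, 180]`.
#' @export
ending_orientation <- function(ending, follicle) {
  if (!identical(as.character(ending$kind), "lanceolate"))
    stop("orientation is defined for lanceolate endings only", call. = FALSE)
  if (is.na(ending$follicle_id))
    stop("ending has no assigned follicle", call. = FALSE)
  if (!is.null(ending$n_nodes) && ending$n_nodes < 3)
    stop("orientation requires >= 3 member nodes", call. = FALSE)
  off <- c(ending$centroid_x - follicle$cx, ending$centroid_y - follicle$cy)
  if (vec_norm(off) < 1e-9)
    stop("degenerate ending: centroid coincides with the follicle center",
         call. = FALSE)
  v_ne <- unit_vec(off)
  v_hf <- unit_vec(c(follicle$tilt_x, follicle$tilt_y))
  ang <- rad2deg(acos(pmin(1, pmax(-1, sum(v_ne * v_hf)))))
  list(follicle_id = ending$follicle_id, v_ne = v_ne, v_hf = v_hf,
       angle = ang)
}

#' Circular statistics of a set of angles
#'
#' Resultant-vector circular mean, circular standard deviation
#' (sqrt(-2 log R) converted to degrees) and mean resultant length R.
#'
#' @param angles Numeric vector of angles in degrees (any branch; values are
#'   taken modulo 360).
#' @return List with `circular_mean` (degrees in `[0, 360)`; `NA` flagged
#'   when R is numerically 0), `circular_sd` (degrees) and
#'   `resultant_length` in `[0, 1]`.
#' @export
circular_stats <- function(angles) {
  if (!length(angles)) stop("no angles supplied", call. = FALSE)
  th <- deg2rad(angles)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 1e-12) {
    return(list(circular_mean = structure(NA_real_,
                                          flag = "resultant length ~ 0"),
                circular_sd = Inf, resultant_length = 0))
  }
  mu <- rad2deg(atan2(S, C)) %% 360
  if (mu > 360 - 1e-9) mu <- 0
  list(circular_mean = mu,
       circular_sd = rad2deg(sqrt(-2 * log(min(R, 1)))),
       resultant_length = R)
}

#' Orientation records for all lanceolate endings of an arbor
#'
#' @param endings An `ending_set` with follicle assignments.
#' @param follicle_map A [follicle_map()].
#' @param arbor_id Identifier copied into each record.
#' @return Data frame with columns `arbor_id`, `follicle_id`, `angle_deg`;
#'   zero rows when the arbor has no assigned lanceolate endings.
#' @export
orientation_records <- function(endings, follicle_map, arbor_id = NA) {
  stopifnot(inherits(endings, "ending_set"),
            inherits(follicle_map, "follicle_map"))
  idx <- which(endings$kind == "lanceolate" & !is.na(endings$follicle_id) &
                 endings$n_nodes >= 3)
  out <- vector("list", length(idx))
  fol <- follicle_map$follicles
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- fol[fol$follicle_id == endings$follicle_id[i], , drop = FALSE]
    if (!nrow(f)) next
    rec <- tryCatch(ending_orientation(endings[i, ], f[1, ]),
                    error = function(e) NULL)
    if (!is.null(rec))
      out[[k]] <- data.frame(arbor_id = arbor_id,
                             follicle_id = rec$follicle_id,
                             angle_deg = rec$angle)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(arbor_id = character(0), follicle_id = integer(0),
                      angle_deg = numeric(0)))
  do.call(rbind, out)
}
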