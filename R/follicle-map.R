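# Hair-follicle map container and CSV I/O.
#
# A follicle map records, for a rectangular patch of back skin, every hair
# follicle: XY center (um), diameter (um), whether it is a large-diameter
# guard (tylotrich) hair, and the follicle tilt vector V_HF -- the unit XY
# vector of the hair axis, which on wild-type back skin points
# anterior-to-posterior (+x) with small angular scatter.

#' Construct a follicle map
#'
#' @param follicles Data frame with columns `follicle_id`, `cx`, `cy`,
#'   `diameter`, `guard`, `tilt_x`, `tilt_y`. Tilt vectors are renormalized
#'   to unit length (with a warning when they deviate by more than 1e-6).
#' @param bounds Numeric vector `c(xmin, xmax, ymin, ymax)` in micrometers;
#'   all follicle centers must lie inside.
#' @return An object of class `follicle_map` with elements `follicles` and
#'   `bounds`.
#' @export
follicle_map <- function(follicles, bounds) {
  stopifnot(is.data.frame(follicles))
  req <- c("follicle_id", "cx", "cy", "diameter", "guard", "tilt_x", "tilt_y")
  miss <- setdiff(req, names(follicles))
  if (length(miss))
    stop("follicles is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  follicles <- follicles[, req]
  stopifnot(is.numeric(bounds), length(bounds) == 4L,
            bounds[2] > bounds[1], bounds[4] > bounds[3])
  if (nrow(follicles)) {
    if (anyNA(follicles) || !all(is.finite(follicles$cx + follicles$cy)))
      stop("non-finite follicle coordinates", call. = FALSE)
    if (anyDuplicated(follicles$follicle_id))
      stop("duplicate follicle ids", call. = FALSE)
    if (anyDuplicated(follicles[c("cx", "cy")]))
      stop("duplicate follicle centers", call. = FALSE)
    if (any(follicles$diameter <= 0))
      stop("follicle diameters must be positive", call. = FALSE)
    if (any(follicles$cx < bounds[1] | follicles$cx > bounds[2] |
            follicles$cy < bounds[3] | follicles$cy > bounds[4]))
      stop("follicle centers outside the map bounds", call. = FALSE)
    nrm <- sqrt(follicles$tilt_x^2 + follicles$tilt_y^2)
    if (any(nrm == 0)) stop("zero tilt vector", call. = FALSE)
    if (any(abs(nrm - 1) > 1e-6))
      warning("tilt vectors renormalized to unit length")
    follicles$tilt_x <- follicles$tilt_x / nrm
    follicles$tilt_y <- follicles$tilt_y / nrm
    follicles$guard <- as.logical(follicles$guard)
  }
  structure(list(follicles = follicles, bounds = as.numeric(bounds)),
            class = "follicle_map")
}

#' @export
print.follicle_map <- function(x, ...) {
  b <- x$bounds
  cat("<follicle_map> ", nrow(x$follicles), " follicles (",
      sum(x$follicles$guard), " guard) in ",
      round(b[2] - b[1]), " x ", round(b[4] - b[3]), " um\n", sep = "")
  invisible(x)
}

#' Read or write a follicle map as CSV
#'
#' The CSV schema is `follicle_id,cx,cy,diameter,guard,tilt_x,tilt_y`; map
#' bounds are carried in a `# bounds: xmin xmax ymin ymax` comment on the
#' first line (when absent, the bounding box of the centers is used).
#'
#' @param path CSV file path.
#' @return `read_follicle_map`: a validated [follicle_map()].
#' @export
read_follicle_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  bounds <- NULL
  if (grepl("^#\\s*bounds:", first)) {
    bounds <- as.numeric(strsplit(trimws(sub("^#\\s*bounds:", "", first)),
                                  "\\s+")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(bounds)) {
    pad <- 1
    bounds <- c(min(df$cx) - pad, max(df$cx) + pad,
                min(df$cy) - pad, max(df$cy) + pad)
  }
  follicle_map(df, bounds)
}

#' @rdname read_follicle_map
#' @param map A [follicle_map()].
#' @export
write_follicle_map <- function(map, path) {
  stopifnot(inherits(map, "follicle_map"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# bounds: %.4f %.4f %.4f %.4f",
                     map$bounds[1], map$bounds[2],
                     map$bounds[3], map$bounds[4]), con)
  f <- map$follicles
  # fixed precision so round-trips are exact at the written precision
  for (cl in c("cx", "cy", "diameter", "tilt_x", "tilt_y"))
    f[[cl]] <- sprintf("%.6f", f[[cl]])
  utils::write.csv(f, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Follicle density over a rectangular region
#'
#' Number of follicle centers falling in `region` divided by the region area,
#' the quantity plotted as the mean-follicle-density reference line against
#' per-arbor innervation counts.
#'
#' @param map A [follicle_map()].
#' @param region Numeric `c(xmin, xmax, ymin, ymax)` in micrometers; defaults
#'   to the map bounds.
#' @return Follicles per square micrometer.
#' @export
follicle_density <- function(map, region = map$bounds) {
  stopifnot(inherits(map, "follicle_map"), length(region) == 4L)
  area <- (region[2] - region[1]) * (region[4] - region[3])
  if (!is.finite(area) || area <= 0)
    stop("region area must be positive", call. = FALSE)
  f <- map$follicles
  n <- sum(f$cx >= region[1] & f$cx <= region[2] &
           f$cy >= region[3] & f$cy <= region[4])
  n / area
}
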