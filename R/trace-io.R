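# Arbor trace container and SWC-dialect I/O.
#
# Traces are rooted trees of 3-D nodes in skin coordinates: x, y in the plane
# of the skin (micrometers, +x = anterior-to-posterior), z = depth below the
# epidermal surface (surface = 0 um). On disk they are standard 7-column SWC
# (id, type, x, y, z, radius, parent; '#' comments), the format emitted by
# common semi-automatic tracing programs.

#' Construct an arbor trace
#'
#' An `arbor_trace` is a validated rooted tree of 3-D nodes, the unit of all
#' morphometric computation in this package. Coordinates are micrometers with
#' `z` the depth below the epidermal surface (surface at 0).
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y`, `z`, `radius`,
#'   `parent_id`. `parent_id` is -1 for the root; `radius` may be 0 when
#'   unknown. An optional `type` column (SWC structure code) is preserved.
#' @param arbor_id Character identifier, e.g. `"A13-11"`.
#' @param metadata Optional named list (e.g. `skin_id`, `ending_type`,
#'   `true_label` for synthetic arbors).
#' @return An object of class `arbor_trace`: a list with elements `arbor_id`,
#'   `nodes` (data frame) and `metadata`.
#' @examples
#' nodes <- data.frame(node_id = 1:2, x = c(0, 0), y = c(0, 3), z = c(0, 4),
#'                     radius = 0, parent_id = c(-1, 1))
#' tr <- arbor_trace(nodes, arbor_id = "toy")
#' total_axon_length(tr) # 5
#' @export
arbor_trace <- function(nodes, arbor_id = "arbor", metadata = list()) {
  stopifnot(is.data.frame(nodes))
  req <- c("node_id", "x", "y", "z", "radius", "parent_id")
  miss <- setdiff(req, names(nodes))
  if (length(miss))
    stop("nodes is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"type" %in% names(nodes)) nodes$type <- 0L
  nodes <- nodes[, c("node_id", "type", "x", "y", "z", "radius", "parent_id")]
  tr <- structure(list(arbor_id = as.character(arbor_id),
                       nodes = nodes, metadata = metadata),
                  class = "arbor_trace")
  validate_arbor_trace(tr)
  tr
}

# Validates the tree invariants: unique ids, exactly one root, all parents
# resolvable, single connected component, no cycles, z >= 0.
validate_arbor_trace <- function(tr) {
  nd <- tr$nodes
  if (nrow(nd) < 1) stop("trace has no nodes", call. = FALSE)
  if (anyNA(nd[c("node_id", "x", "y", "z", "parent_id")]) ||
      !all(is.finite(as.matrix(nd[c("x", "y", "z")]))))
    stop("trace contains missing or non-finite values", call. = FALSE)
  ids <- nd$node_id
  if (any(ids != round(ids)) || any(ids < 1))
    stop("node ids must be positive integers", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate node id ", dup, " (line ",
         which(ids == dup)[2], ")", call. = FALSE)
  }
  if (any(nd$radius < 0)) stop("negative radius", call. = FALSE)
  if (any(nd$z < -1e-9))
    stop("negative z: depth below the surface must be >= 0", call. = FALSE)
  root <- which(nd$parent_id == -1)
  if (length(root) == 0) stop("no root node (parent_id -1)", call. = FALSE)
  if (length(root) > 1)
    stop("multiple roots at lines ", paste(root, collapse = ", "),
         call. = FALSE)
  pidx <- match(nd$parent_id, ids)
  bad <- which(nd$parent_id != -1 & is.na(pidx))
  if (length(bad))
    stop("dangling parent reference ", nd$parent_id[bad[1]],
         " (line ", bad[1], ")", call. = FALSE)
  # connectivity / acyclicity: follow parents to the root from every node
  depth <- rep(NA_integer_, nrow(nd))
  depth[root] <- 0L
  for (i in seq_len(nrow(nd))) {
    if (!is.na(depth[i])) next
    chain <- integer(0)
    j <- i
    while (is.na(depth[j])) {
      if (j %in% chain)
        stop("cycle detected involving node id ", ids[j], call. = FALSE)
      chain <- c(chain, j)
      j <- pidx[j]
    }
    depth[chain] <- depth[j] + rev(seq_along(chain))
  }
  invisible(tr)
}

#' @export
print.arbor_trace <- function(x, ...) {
  cat("<arbor_trace> ", x$arbor_id, ": ", nrow(x$nodes), " nodes, ",
      sum(!x$nodes$node_id %in% x$nodes$parent_id), " terminals\n", sep = "")
  if (!is.null(x$metadata$true_label))
    cat("  ground-truth label: ", x$metadata$true_label, "\n", sep = "")
  invisible(x)
}

#' @export
summary.arbor_trace <- function(object, ...) {
  m <- arbor_metrics(object)
  print(m)
  invisible(m)
}

#' Read an arbor trace from an SWC file
#'
#' Parses whitespace-delimited 7-column SWC (`id type x y z radius parent`),
#' skipping `#` comment lines, and validates the rooted-tree invariants.
#' Line numbers in error messages refer to the file, including comments.
#'
#' @param path Path to an SWC file.
#' @param arbor_id Identifier for the trace; defaults to the file base name.
#' @param metadata Optional metadata list attached to the trace.
#' @return An [arbor_trace()] with nodes in file order.
#' @export
read_swc <- function(path, arbor_id = NULL, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  dat <- raw[keep]
  if (!length(dat)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7))
    stop("line ", lineno[which(nf != 7)[1]], ": expected 7 columns, got ",
         nf[which(nf != 7)[1]], call. = FALSE)
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                               ncol = 7, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("line ", lineno[bad], ": non-numeric field", call. = FALSE)
  }
  nodes <- data.frame(node_id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent_id = m[, 7])
  if (is.null(arbor_id))
    arbor_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  # annotate parse errors with file line numbers
  tr <- tryCatch(arbor_trace(nodes, arbor_id = arbor_id, metadata = metadata),
                 error = function(e) {
                   msg <- conditionMessage(e)
                   msg <- gsub("\\(line (\\d+)\\)", "(data line \\1)", msg)
                   stop("in ", path, ": ", msg, call. = FALSE)
                 })
  tr
}

#' Write an arbor trace to an SWC file
#'
#' Emits standard 7-column SWC with a header comment. Coordinates and radii
#' are printed at fixed precision (micrometers to 1e-4), so a written trace
#' re-reads bit-identically at that precision.
#'
#' @param trace An [arbor_trace()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(trace, path) {
  stopifnot(inherits(trace, "arbor_trace"))
  nd <- trace$nodes
  if (any(nd$node_id != round(nd$node_id)) ||
      any(nd$parent_id != round(nd$parent_id)))
    stop("node and parent ids must be integers", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# arbor %s, %d nodes; columns: id type x y z radius parent",
                     trace$arbor_id, nrow(nd)), con)
  writeLines(sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                     as.integer(nd$node_id), as.integer(nd$type),
                     nd$x, nd$y, nd$z, nd$radius,
                     as.integer(nd$parent_id)), con)
  invisible(path)
}

#' Correct Z coordinates for clearing-induced shrinkage
#'
#' Solvent clearing compresses skin in Z (to roughly 92% of its original
#' thickness) while leaving X and Y essentially unchanged; depths measured in
#' cleared tissue are rescaled back to original-thickness coordinates by
#' multiplying every `z` by `z_correction` (original / cleared thickness).
#'
#' @param trace An [arbor_trace()] with z in cleared-tissue coordinates.
#' @param z_correction Ratio original thickness / cleared thickness, `>= 1`
#'   (clearing only shrinks; 1 = no correction).
#' @return The trace with all `z` multiplied by `z_correction`.
#' @examples
#' # cleared thickness ~125 um for an original ~135 um:
#' # apply_z_correction(trace, 135 / 125)
#' @export
apply_z_correction <- function(trace, z_correction) {
  stopifnot(inherits(trace, "arbor_trace"), is.numeric(z_correction),
            length(z_correction) == 1L, is.finite(z_correction))
  if (z_correction < 1)
    stop("z_correction must be >= 1 (clearing only shrinks tissue)",
         call. = FALSE)
  trace$nodes$z <- trace$nodes$z * z_correction
  trace
}

#' Read or write survey metadata
#'
#' Survey metadata records, per skin: `skin_id`, `skin_area_cm2` (dissected
#' surface area in cm^2) and `z_correction` (original / cleared thickness,
#' `>= 1`). Stored as JSON.
#'
#' @param path JSON file path.
#' @return `read_survey_metadata`: a named list with the three fields.
#' @export
read_survey_metadata <- function(path) {
  md <- jsonlite::read_json(path, simplifyVector = TRUE)
  survey_metadata(md$skin_id, md$skin_area_cm2, md$z_correction %||% 1)
}

#' @rdname read_survey_metadata
#' @param metadata A list as returned by [survey_metadata()].
#' @export
write_survey_metadata <- function(metadata, path) {
  jsonlite::write_json(metadata, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_survey_metadata
#' @param skin_id Character skin identifier.
#' @param skin_area_cm2 Skin surface area, cm^2 (> 0).
#' @param z_correction Original / cleared thickness ratio (>= 1).
#' @export
survey_metadata <- function(skin_id, skin_area_cm2, z_correction = 1) {
  stopifnot(skin_area_cm2 > 0, z_correction >= 1)
  list(skin_id = as.character(skin_id),
       skin_area_cm2 = as.numeric(skin_area_cm2),
       z_correction = as.numeric(z_correction))
}
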