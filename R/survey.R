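# End-to-end survey orchestration: load traces and follicle maps, apply the
# Z-shrinkage correction, compute metrics, detect and assign endings, derive
# innervation and orientation statistics, classify, and summarize at the
# skin level. Per-arbor failures are isolated and logged, never fatal to the
# survey.

survey_row_names <- c("arbor_id", "skin_id", "true_label", "hull_area",
                      "axon_length", "n_branch_points", "n_terminals",
                      "depth_mean", "depth_sd", "terminal_depth_mean",
                      "n_endings", "dominant_kind", "n_follicles_innervated",
                      "n_follicles_in_hull", "innervation_index",
                      "fraction_innervated", "mean_arc_fraction")

#' Run the full analysis pipeline over a set of arbors
#'
#' For each arbor: read (or take) the trace, apply the Z-shrinkage
#' correction from the survey metadata, compute the continuous metrics,
#' detect terminal endings against the follicle map, assign endings to
#' follicles, derive the innervation summary and lanceolate orientation
#' records, and classify. An arbor that fails any stage is dropped from the
#' table with its error recorded; the remaining arbors are unaffected.
#'
#' @param x Either a `synthetic_survey` from [generate_survey()], a list of
#'   `list(trace =, follicle_map =)` pairs, or a character vector of SWC
#'   paths (then `follicle_map` must be given).
#' @param follicle_map A shared [follicle_map()] when `x` is a path vector.
#' @param metadata A [survey_metadata()] record (its `z_correction` is
#'   applied to every trace) or a list of such records keyed by skin id.
#' @param ending_params See [ending_params()].
#' @param thresholds See [classifier_thresholds()]; `NULL` skips
#'   classification.
#' @return A `survey_table`: element `arbors` is the per-arbor data frame
#'   (one row per successfully processed arbor, including a `label` column
#'   when classified), element `skins` the per-skin accounting. Attributes:
#'   `metrics` and `endings` (per-arbor lists), `orientations` (data frame
#'   of lanceolate angles), `failures` (named list of error messages), and
#'   the classification attributes of [classify_survey()].
#' @export
run_survey <- function(x, follicle_map = NULL, metadata = NULL,
                       ending_params = arborscape::ending_params(),
                       thresholds = classifier_thresholds()) {
  items <- survey_items(x, follicle_map)
  if (!length(items)) stop("no input traces", call. = FALSE)
  zc <- if (!is.null(metadata) && !is.null(metadata$z_correction))
    metadata$z_correction else 1
  skin_id <- if (!is.null(metadata) && !is.null(metadata$skin_id))
    metadata$skin_id else NA_character_

  rows <- list(); metrics <- list(); endsets <- list(); orients <- list()
  failures <- list()
  for (it in items) {
    res <- tryCatch({
      tr <- if (is.character(it$trace)) read_swc(it$trace) else it$trace
      if (zc != 1) tr <- apply_z_correction(tr, zc)
      m <- arbor_metrics(tr)
      ends <- detect_terminal_endings(tr, it$follicle_map, ending_params)
      ends <- assign_endings_to_follicles(ends, it$follicle_map,
                                          ending_params$attach_radius)
      hull <- suppressWarnings(convex_hull_polygon(tr))
      inn <- if (nrow(hull) >= 3)
        innervation_summary(ends, hull, it$follicle_map)
      else list(n_follicles_innervated = 0L, n_follicles_in_hull = 0L,
                innervation_index = 0, fraction_innervated = NA_real_,
                mean_arc_fraction = NA_real_)
      ori <- orientation_records(ends, it$follicle_map, tr$arbor_id)
      dom <- if (nrow(ends)) names(which.max(table(ends$kind)))
      else NA_character_
      list(trace = tr, metrics = m, endings = ends, innervation = inn,
           orientations = ori, dominant = dom)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nm <- if (is.character(it$trace)) it$trace
      else if (inherits(it$trace, "arbor_trace")) it$trace$arbor_id
      else "arbor"
      failures[[nm]] <- conditionMessage(res)
      next
    }
    tr <- res$trace
    k <- length(rows) + 1L
    this_skin <- tr$metadata$skin_id %||% skin_id
    if (is.na(this_skin)) this_skin <- "unknown"
    rows[[k]] <- data.frame(
      arbor_id = tr$arbor_id,
      skin_id = this_skin,
      true_label = tr$metadata$true_label %||% NA_character_,
      hull_area = res$metrics$hull_area,
      axon_length = res$metrics$axon_length,
      n_branch_points = res$metrics$n_branch_points,
      n_terminals = res$metrics$n_terminals,
      depth_mean = res$metrics$depth_mean,
      depth_sd = res$metrics$depth_sd,
      terminal_depth_mean = res$metrics$terminal_depth_mean,
      n_endings = nrow(res$endings),
      dominant_kind = res$dominant,
      n_follicles_innervated = res$innervation$n_follicles_innervated,
      n_follicles_in_hull = res$innervation$n_follicles_in_hull,
      innervation_index = res$innervation$innervation_index,
      fraction_innervated = as.numeric(res$innervation$fraction_innervated),
      mean_arc_fraction = res$innervation$mean_arc_fraction)
    metrics[[k]] <- res$metrics
    endsets[[k]] <- res$endings
    orients[[k]] <- res$orientations
  }
  if (!length(rows))
    stop("no valid traces (", length(failures), " failures)", call. = FALSE)
  arbors <- do.call(rbind, rows)
  skins <- stats::aggregate(cbind(hull_area, axon_length) ~ skin_id, arbors,
                            sum)
  names(skins) <- c("skin_id", "total_arbor_area", "total_axon_length")
  skins$n_arbors <- as.integer(table(arbors$skin_id)[skins$skin_id])
  out <- structure(list(arbors = arbors, skins = skins),
                   class = "survey_table")
  attr(out, "metrics") <- metrics
  attr(out, "endings") <- endsets
  attr(out, "orientations") <- do.call(rbind, orients)
  attr(out, "failures") <- failures
  if (!is.null(thresholds)) out <- classify_survey(out, thresholds)
  out
}

# normalize run_survey inputs to a list of (trace, follicle_map) items
survey_items <- function(x, follicle_map) {
  if (inherits(x, "synthetic_survey"))
    return(lapply(x$arbors, function(a)
      list(trace = a$trace, follicle_map = a$follicle_map)))
  if (is.character(x)) {
    if (is.null(follicle_map))
      stop("follicle_map is required with trace paths", call. = FALSE)
    return(lapply(x, function(p)
      list(trace = p, follicle_map = follicle_map)))
  }
  if (is.list(x) && length(x) && inherits(x[[1]]$trace %||% x[[1]],
                                          "arbor_trace")) {
    return(lapply(x, function(it) {
      if (inherits(it, "arbor_trace"))
        list(trace = it, follicle_map = follicle_map)
      else list(trace = it$trace,
                follicle_map = it$follicle_map %||% follicle_map)
    }))
  }
  stop("unrecognized survey input", call. = FALSE)
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table> ", nrow(x$arbors), " arbors, ",
      nrow(x$skins), " skin(s)", sep = "")
  nf <- length(attr(x, "failures"))
  if (nf) cat(", ", nf, " failed", sep = "")
  cat("\n")
  if ("label" %in% names(x$arbors)) print(table(x$arbors$label))
  if (!is.null(attr(x, "agreement")))
    cat("agreement with ground truth: ",
        round(100 * attr(x, "agreement"), 1), "%\n", sep = "")
  invisible(x)
}

#' @export
plot.survey_table <- function(x, ...) {
  arb <- x$arbors
  ok <- arb$hull_area > 0 & arb$innervation_index > 0
  if (!any(ok)) {
    warning("nothing to plot: no arbors with positive area and index")
    return(invisible(x))
  }
  grp <- if ("label" %in% names(arb)) arb$label else arb$true_label
  grp <- factor(grp)
  graphics::plot(log10(arb$hull_area[ok]), log10(arb$innervation_index[ok]),
                 col = as.integer(grp[ok]), pch = 19,
                 xlab = expression(log[10] ~ "arbor area (" * mu * m^2 * ")"),
                 ylab = expression(log[10] ~ "innervation index"), ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, cex = 0.7)
  invisible(x)
}

#' Skin-level summary of a survey
#'
#' Aggregates a survey over skins: total surveyed area (mean skin area times
#' skin count, reported to 4 significant figures, cm^2), per-skin
#' occupied-area fraction (sum of arbor hull areas over the skin area; the
#' cm^2-to-um^2 conversion, 1 cm^2 = 1e8 um^2, happens only here), and
#' per-type means and SDs of the main continuous parameters.
#'
#' @param table A `survey_table`.
#' @param metadata_list List of [survey_metadata()] records, one per skin.
#' @return List with `n_skins`, `total_skin_area_cm2`, `per_skin` (data
#'   frame with `occupied_fraction`) and `per_type` (data frame of means and
#'   SDs by label).
#' @export
summarize_survey <- function(table, metadata_list) {
  stopifnot(inherits(table, "survey_table"))
  if (inherits(metadata_list, "survey_metadata") ||
      (is.list(metadata_list) && !is.null(metadata_list$skin_id)))
    metadata_list <- list(metadata_list)
  if (!length(metadata_list)) stop("at least one skin required",
                                   call. = FALSE)
  areas <- vapply(metadata_list, function(m) m$skin_area_cm2, numeric(1))
  ids <- vapply(metadata_list, function(m) m$skin_id, character(1))
  total <- signif(mean(areas) * length(areas), 4)
  per_skin <- data.frame(skin_id = ids, skin_area_cm2 = areas,
                         occupied_fraction = 0)
  for (i in seq_len(nrow(per_skin))) {
    j <- table$skins$skin_id == per_skin$skin_id[i]
    if (any(j))
      per_skin$occupied_fraction[i] <-
        sum(table$skins$total_arbor_area[j]) /
        (per_skin$skin_area_cm2[i] * 1e8)
  }
  arb <- table$arbors
  grp <- if ("label" %in% names(arb)) arb$label else arb$true_label
  per_type <- NULL
  if (!is.null(grp) && nrow(arb)) {
    agg <- function(f, suffix) {
      a <- stats::aggregate(
        arb[c("hull_area", "axon_length", "n_branch_points",
              "n_follicles_innervated", "fraction_innervated")],
        by = list(label = grp), FUN = f, na.rm = TRUE)
      names(a)[-1] <- paste0(names(a)[-1], suffix)
      a
    }
    per_type <- merge(cbind(agg(mean, "_mean"),
                            n = as.integer(table(grp)[agg(mean, "_mean")$label])),
                      agg(stats::sd, "_sd"), by = "label")
  }
  list(n_skins = length(areas), total_skin_area_cm2 = total,
       per_skin = per_skin, per_type = per_type)
}

#' Compare two independent tracings of one arbor
#'
#' Reproducibility record for two traces of the same arbor: raw axon lengths
#' and branch-point counts plus their percent differences
#' (|a - b| / max(a, b) * 100).
#'
#' @param trace_a,trace_b Two [arbor_trace()] objects.
#' @return List with `axon_length` (vector of both values),
#'   `n_branch_points`, `length_pct_diff` and `branch_pct_diff`.
#' @examples
#' # published check: lengths 85020 vs 86908 um differ by 2.17%,
#' # branch points 1011 vs 1071 by 5.60%
#' percent_difference(85020, 86908)
#' @export
compare_traces <- function(trace_a, trace_b) {
  la <- total_axon_length(trace_a); lb <- total_axon_length(trace_b)
  ba <- branch_point_count(trace_a); bb <- branch_point_count(trace_b)
  list(axon_length = c(la, lb),
       n_branch_points = c(ba, bb),
       length_pct_diff = percent_difference(la, lb),
       branch_pct_diff = if (ba > 0 && bb > 0)
         percent_difference(ba, bb) else NA_real_)
}
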