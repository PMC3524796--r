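# Rule-based classification of arbors into the ten morphologic types.
#
# The ten types -- MCA, I-FACE, I-FALE, SA-FACE, LA-FACE, LD-FALE, HD-FALE,
# BE, TE, LA-FE -- are separated first by discrete characters (the kind of
# terminal specialization, single vs multiple target follicles, one vs two
# depth tiers) and then by continuous parameters (hull area; position in the
# log10 arbor-area vs log10 innervation-index plane). All numeric boundaries
# live in a single thresholds object that is echoed in every report, never
# hard-coded in the rules.

#' Classification thresholds
#'
#' @param face_area_split Hull-area boundary (um^2) between small-area and
#'   large-area circumferential arbors; default 5e5, between territories of
#'   a few hundred micrometers and of 1-2 mm diameter.
#' @param face_follicle_low,face_follicle_high Consistency bounds on
#'   follicle counts (fewer than ~10 per small-area arbor, more than ~100
#'   per large-area arbor); used for diagnostics, area is the primary
#'   splitter.
#' @param fale_index_intercept,fale_index_slope The line
#'   `log10(index) = intercept + slope * log10(area)` separating high- from
#'   low-density lanceolate arbors in the (log10 area, log10 innervation
#'   index) plane; arbors above the line are high-density. The default
#'   (slope 0, intercept -4.2) was fixed once against the default synthetic
#'   survey, where the two groups sit about an order of magnitude apart in
#'   index.
#' @param bushy_branch_density Branch points per um^2 of hull area above
#'   which a single-tier free-ending arbor is bushy (default 5e-4; bushy
#'   arbors run near 2e-3, sparse free/thick arbors orders of magnitude
#'   lower).
#' @param tier_gap Minimum terminal-depth gap (um) for a two-tier arbor,
#'   passed to [decompose_tiers()].
#' @param purity_min Minimum share of the dominant specialized ending kind
#'   among specialized endings; mixtures below it are unclassifiable.
#' @param free_dominance_ratio An arbor is treated as free-ending when its
#'   free endings outnumber specialized ones by at least this factor
#'   (dense free arbors inevitably yield a few incidental follicle-associated
#'   detections, while genuinely follicle-associated arbors carry at most
#'   occasional free endings).
#' @return A named list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(face_area_split = 5e5,
                                  face_follicle_low = 10,
                                  face_follicle_high = 100,
                                  fale_index_intercept = -4.2,
                                  fale_index_slope = 0,
                                  bushy_branch_density = 5e-4,
                                  tier_gap = 30,
                                  purity_min = 0.75,
                                  free_dominance_ratio = 6) {
  stopifnot(face_area_split > 0, bushy_branch_density > 0, tier_gap > 0,
            purity_min > 0.5, purity_min <= 1)
  structure(as.list(environment()), class = "classifier_thresholds")
}

#' @export
print.classifier_thresholds <- function(x, ...) {
  cat("<classifier_thresholds>\n")
  for (nm in names(x)) cat("  ", format(nm, width = 22), x[[nm]], "\n")
  invisible(x)
}

#' Arbor type labels
#' @return Character vector of the ten morphologic type labels.
#' @export
arbor_type_labels <- function() {
  c("MCA", "I-FACE", "I-FALE", "SA-FACE", "LA-FACE",
    "LD-FALE", "HD-FALE", "BE", "TE", "LA-FE")
}

#' Classify one arbor
#'
#' Applies the discrete-then-continuous decision sequence: (1) any merkel
#' ending gives MCA; (2) a dominant thick-ending complement gives TE; (3) a
#' two-tier free-ending arbor gives LA-FE; (4) a single-tier free-ending
#' arbor at bushy branch density gives BE; (5) circumferential arbors split
#' by follicle count (1 = I-FACE) and hull area (SA-FACE vs LA-FACE);
#' (6) lanceolate arbors split by follicle count (1 = I-FALE) and the side
#' of the configured line in (log10 area, log10 innervation index)
#' (HD-FALE above, LD-FALE below). Arbors mixing specialized ending kinds
#' beyond the purity threshold are "unclassifiable".
#'
#' @param metrics An [arbor_metrics()] record for the trace.
#' @param endings The matching `ending_set` with follicle assignments.
#' @param thresholds A [classifier_thresholds()].
#' @return List with `label`, `rule_trace` (character vector of the fired
#'   rules, sufficient to recompute the label by hand) and `diagnostics`.
#' @export
classify_arbor <- function(metrics, endings,
                           thresholds = classifier_thresholds()) {
  stopifnot(inherits(metrics, "arbor_metrics"),
            inherits(endings, "ending_set"),
            inherits(thresholds, "classifier_thresholds"))
  th <- thresholds
  kinds <- table(factor(endings$kind,
                        levels = c("lanceolate", "circumferential", "thick",
                                   "merkel", "free")))
  n_fol <- length(unique(stats::na.omit(endings$follicle_id)))
  spec <- kinds[c("lanceolate", "circumferential", "thick", "merkel")]
  n_spec <- sum(spec)
  tracev <- character(0)
  note <- function(...) tracev <<- c(tracev, sprintf(...))
  result <- function(label) list(label = label, rule_trace = tracev,
                                 diagnostics = list(
                                   kind_counts = kinds,
                                   n_follicles = n_fol,
                                   hull_area = metrics$hull_area,
                                   thresholds = th))

  if (kinds[["merkel"]] > 0) {
    note("merkel ending present -> MCA")
    return(result("MCA"))
  }
  free_dominant <- n_spec == 0 ||
    kinds[["free"]] >= th$free_dominance_ratio * n_spec
  if (!free_dominant && max(spec) / n_spec < th$purity_min) {
    note("mixed specialized ending kinds (purity %.2f < %.2f) -> unclassifiable",
         max(spec) / n_spec, th$purity_min)
    return(result("unclassifiable"))
  }
  if (!free_dominant && kinds[["thick"]] > 0 &&
      kinds[["thick"]] == max(spec)) {
    note("dominant specialized kind thick (%d endings) -> TE",
         kinds[["thick"]])
    return(result("TE"))
  }
  if (free_dominant) {
    if (isTRUE(metrics$tier_info$two_tier)) {
      note("free endings in two depth tiers (%.0f / %.0f um, %d connectors) -> LA-FE",
           metrics$tier_info$outer_depth, metrics$tier_info$inner_depth,
           metrics$tier_info$n_vertical_connectors)
      return(result("LA-FE"))
    }
    bd <- if (metrics$hull_area > 0)
      metrics$n_branch_points / metrics$hull_area else 0
    if (bd >= th$bushy_branch_density) {
      note("single-tier free arbor, branch density %.2e >= %.2e -> BE",
           bd, th$bushy_branch_density)
      return(result("BE"))
    }
    note("single-tier free arbor below bushy branch density (%.2e) -> unclassifiable",
         bd)
    return(result("unclassifiable"))
  }
  if (kinds[["circumferential"]] >= kinds[["lanceolate"]]) {
    if (n_fol <= 1) {
      note("circumferential endings on one follicle -> I-FACE")
      return(result("I-FACE"))
    }
    if (metrics$hull_area < th$face_area_split) {
      note("circumferential, %d follicles, area %.3g < %.3g -> SA-FACE",
           n_fol, metrics$hull_area, th$face_area_split)
      if (n_fol > th$face_follicle_low)
        note("consistency: follicle count %d exceeds the small-area bound %d",
             n_fol, th$face_follicle_low)
      return(result("SA-FACE"))
    }
    note("circumferential, %d follicles, area %.3g >= %.3g -> LA-FACE",
         n_fol, metrics$hull_area, th$face_area_split)
    if (n_fol < th$face_follicle_high)
      note("consistency: follicle count %d below the large-area bound %d",
           n_fol, th$face_follicle_high)
    return(result("LA-FACE"))
  }
  # lanceolate arbors
  if (n_fol <= 1) {
    note("lanceolate endings on one follicle -> I-FALE")
    return(result("I-FALE"))
  }
  if (metrics$hull_area <= 0) {
    note("lanceolate, multiple follicles, zero hull area -> unclassifiable")
    return(result("unclassifiable"))
  }
  idx <- n_fol / metrics$hull_area
  bound <- th$fale_index_intercept +
    th$fale_index_slope * log10(metrics$hull_area)
  if (log10(idx) >= bound) {
    note("lanceolate, log10(index) %.2f >= split %.2f at log10(area) %.2f -> HD-FALE",
         log10(idx), bound, log10(metrics$hull_area))
    return(result("HD-FALE"))
  }
  note("lanceolate, log10(index) %.2f < split %.2f at log10(area) %.2f -> LD-FALE",
       log10(idx), bound, log10(metrics$hull_area))
  result("LD-FALE")
}

#' Classify every arbor of a survey
#'
#' @param survey A `survey_table` from [run_survey()] or a list of
#'   `(trace, follicle_map)` pairs; see Details.
#' @param thresholds A [classifier_thresholds()].
#' @details When `survey` is a `survey_table`, its stored metrics and ending
#'   sets are reused. When the traces carry ground-truth labels (synthetic
#'   surveys), a confusion matrix of truth vs assigned labels is attached.
#' @return The survey table with a `label` column and attributes
#'   `rule_traces` (list) and, when ground truth is available, `confusion`
#'   (a table) and `agreement` (fraction of arbors whose label matches).
#' @export
classify_survey <- function(survey, thresholds = classifier_thresholds()) {
  stopifnot(inherits(survey, "survey_table"))
  arb <- survey$arbors
  if (!nrow(arb)) {
    survey$arbors$label <- character(0)
    return(survey)
  }
  labels <- character(nrow(arb))
  traces <- vector("list", nrow(arb))
  for (i in seq_len(nrow(arb))) {
    cl <- classify_arbor(attr(survey, "metrics")[[i]],
                         attr(survey, "endings")[[i]], thresholds)
    labels[i] <- cl$label
    traces[[i]] <- cl$rule_trace
  }
  survey$arbors$label <- labels
  attr(survey, "rule_traces") <- traces
  truth <- arb$true_label
  if (!is.null(truth) && any(!is.na(truth))) {
    lv <- union(arbor_type_labels(), unique(c(truth, labels)))
    conf <- table(truth = factor(truth, levels = lv),
                  assigned = factor(labels, levels = lv))
    conf <- conf[rowSums(conf) > 0, colSums(conf) > 0, drop = FALSE]
    attr(survey, "confusion") <- conf
    attr(survey, "agreement") <- mean(labels == truth, na.rm = TRUE)
  }
  survey
}
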