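#' Pixel area of one class in a CFZ map
#'
#' @param map a [label_map()].
#' @param class_id class index in `0:4`.
#' @return Integer pixel count.
#' @export
class_area <- function(map, class_id) {
  if (length(class_id) != 1 || !class_id %in% 0:4)
    stop("class_id must be a single value in 0:4", call. = FALSE)
  sum(unclass(map) == as.integer(class_id))
}

#' CFZ area ratios Ra, Rv, Rt
#'
#' The three ratio biomarkers relate avascular CFZ area to the area of
#' the vasculature it flanks:
#' `Ra = paCFZ area / artery area`, `Rv = pvCFZ area / vein area`,
#' `Rt = (paCFZ + pvCFZ area) / (artery + vein area)`.
#' Areas are raw pixel counts of the map classes (no small-component
#' exclusion). A zero denominator yields `NA` (undefined, distinct from a
#' true zero ratio) for that ratio.
#'
#' @param map a [label_map()].
#' @return Named numeric vector `c(Ra, Rv, Rt)`.
#' @export
cfz_ratios <- function(map) {
  m <- unclass(map)
  a <- tabulate(as.integer(m) + 1L, nbins = 5L)  # classes 0..4
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(Ra = safe_div(a[4], a[2]),
    Rv = safe_div(a[5], a[3]),
    Rt = safe_div(a[4] + a[5], a[2] + a[3]))
}

#' Connected CFZ components with the two-pixel exclusion
#'
#' Components of the selected CFZ class mask are extracted and every
#' component of two pixels or fewer is discarded (such specks are
#' indistinguishable from noise at en-face OCTA resolution).
#' `which = "both"` analyses the union mask (periarterial together with
#' perivenous), so touching components of the two classes merge.
#'
#' @param map a [label_map()].
#' @param which `"paCFZ"` (class 3), `"pvCFZ"` (class 4) or `"both"`.
#' @param connectivity 4 or 8.
#' @return A `component_set` of the retained components.
#' @export
cfz_components <- function(map, which = c("both", "paCFZ", "pvCFZ"),
                           connectivity = 8) {
  which <- match.arg(which)
  m <- unclass(map)
  sel <- switch(which, paCFZ = m == 3L, pvCFZ = m == 4L,
                both = m == 3L | m == 4L)
  find_candidates(sel + 0L, connectivity = connectivity,
                  min_candidate_area = 3L)
}

#' CFZ counts and mean sizes Na, Nv, Nt, Ma, Mv, Mt
#'
#' Counts are the numbers of retained (> 2 px) connected components of
#' the periarterial class, the perivenous class, and their union; the
#' mean sizes are the mean retained-component pixel areas. The mean of an
#' empty component set is `NA` (missing), never 0.
#'
#' @param map a [label_map()].
#' @param connectivity 4 or 8.
#' @return Named numeric vector `c(Na, Nv, Nt, Ma, Mv, Mt)`.
#' @export
cfz_counts_and_means <- function(map, connectivity = 8) {
  one <- function(which) {
    areas <- cfz_components(map, which, connectivity)$areas
    c(n = length(areas), m = if (length(areas)) mean(areas) else NA_real_)
  }
  pa <- one("paCFZ"); pv <- one("pvCFZ"); tot <- one("both")
  c(Na = unname(pa["n"]), Nv = unname(pv["n"]), Nt = unname(tot["n"]),
    Ma = unname(pa["m"]), Mv = unname(pv["m"]), Mt = unname(tot["m"]))
}

#' All nine CFZ biomarkers for one map
#'
#' @param map a [label_map()].
#' @param connectivity 4 or 8.
#' @return Named numeric vector of `Ra, Rv, Rt, Na, Nv, Nt, Ma, Mv, Mt`.
#' @export
cfz_features <- function(map, connectivity = 8) {
  c(cfz_ratios(map), cfz_counts_and_means(map, connectivity))
}

#' Split image columns into nasal and temporal halves
#'
#' Which side of the en-face image is nasal depends on eye laterality.
#' With images in standard fundus display orientation, the nasal side of
#' a right eye (OD) defaults to the right half; the convention is
#' configurable because exports differ between devices. For odd widths
#' the left half receives `floor(width/2)` columns.
#'
#' @param width image width in pixels.
#' @param laterality `"OD"` or `"OS"`.
#' @param nasal_side_for_OD `"right"` (default) or `"left"`.
#' @return `list(nasal = columns, temporal = columns)` (1-based indices).
#' @export
hemifield_columns <- function(width, laterality,
                              nasal_side_for_OD = "right") {
  laterality <- match.arg(laterality, c("OD", "OS"))
  nasal_side_for_OD <- match.arg(nasal_side_for_OD, c("right", "left"))
  half <- floor(width / 2)
  left <- seq_len(half)
  right <- seq.int(half + 1L, width)
  nasal_right <- (laterality == "OD") == (nasal_side_for_OD == "right")
  if (nasal_right) list(nasal = right, temporal = left)
  else list(nasal = left, temporal = right)
}

#' Regional CFZ biomarkers: whole image, nasal half, temporal half
#'
#' The whole-image features are computed on the full map; the nasal and
#' temporal features are computed by cropping to the respective column
#' half (chosen by eye laterality) and re-running the full analysis on
#' the crop, so connected components are re-derived inside each half and
#' the two-pixel exclusion applies post-crop.
#'
#' @param map a [label_map()].
#' @param metadata an [eye_metadata()] row (supplies laterality).
#' @param connectivity 4 or 8.
#' @param nasal_side_for_OD see [hemifield_columns()].
#' @return A three-row `data.frame` (regions `whole`, `nasal`,
#'   `temporal`) with the metadata columns and the nine biomarkers.
#' @export
regional_features <- function(map, metadata, connectivity = 8,
                              nasal_side_for_OD = "right") {
  halves <- hemifield_columns(ncol(map), metadata$laterality, nasal_side_for_OD)
  crops <- list(
    whole = map,
    nasal = label_map(unclass(map)[, halves$nasal, drop = FALSE]),
    temporal = label_map(unclass(map)[, halves$temporal, drop = FALSE]))
  rows <- lapply(names(crops), function(rg) {
    fv <- cfz_features(crops[[rg]], connectivity)
    cbind(data.frame(subject_id = metadata$subject_id,
                     laterality = metadata$laterality,
                     group = metadata$group, region = rg,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Feature table for a list of samples
#'
#' Convenience wrapper running [regional_features()] over a cohort (for
#' example the output of [generate_cohort()]) and stacking the rows.
#'
#' @param samples list of `list(truth = label_map, metadata)` entries; a
#'   `map` element is used when `truth` is absent (e.g. predictions).
#' @param connectivity 4 or 8.
#' @param nasal_side_for_OD see [hemifield_columns()].
#' @return A `data.frame` with one row per sample and region.
#' @export
cohort_feature_table <- function(samples, connectivity = 8,
                                 nasal_side_for_OD = "right") {
  rows <- lapply(samples, function(s) {
    map <- if (!is.null(s$truth)) s$truth else s$map
    regional_features(map, s$metadata, connectivity, nasal_side_for_OD)
  })
  do.call(rbind, rows)
}
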