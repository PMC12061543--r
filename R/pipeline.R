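#' Parameters of the CFZ candidate-generation pipeline
#'
#' The semi-automated pipeline derives CFZ candidates from a grayscale
#' image in four steps: Gaussian denoising, adaptive local-mean
#' thresholding to a binary avascular mask, connected-component
#' extraction, and assignment of each candidate to the periarterial or
#' perivenous class by adjacency to the artery/vein masks.
#'
#' @param gaussian_sigma denoising Gaussian sigma in pixels (`>= 0`).
#' @param threshold_window odd local-mean window size in pixels (`>= 3`).
#' @param threshold_offset intensity offset: a pixel is avascular iff its
#'   intensity is below `local mean - offset`.
#' @param adjacency_radius disk radius (px) used to dilate the vessel
#'   masks when measuring candidate adjacency.
#' @param connectivity pixel connectivity for components, 4 or 8.
#' @param min_candidate_area smallest candidate component kept, pixels.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(gaussian_sigma = 1.0, threshold_window = 31,
                            threshold_offset = 0.10, adjacency_radius = 3,
                            connectivity = 8, min_candidate_area = 1) {
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0", call. = FALSE)
  threshold_window <- as.integer(threshold_window)
  if (threshold_window < 3 || threshold_window %% 2 == 0)
    stop("threshold_window must be odd and >= 3", call. = FALSE)
  if (adjacency_radius < 1) stop("adjacency_radius must be >= 1", call. = FALSE)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 threshold_window = threshold_window,
                 threshold_offset = threshold_offset,
                 adjacency_radius = as.integer(adjacency_radius),
                 connectivity = as.integer(connectivity),
                 min_candidate_area = as.integer(min_candidate_area)),
            class = "pipeline_params")
}

#' Gaussian denoising
#'
#' Separable 2-D Gaussian convolution with reflective (half-sample
#' symmetric) borders; `sigma = 0` returns the input unchanged.
#'
#' @param image an [octa_image()] or numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Same type as the input.
#' @export
gaussian_denoise <- function(image, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  px <- if (inherits(image, "octa_image")) image$pixels else image
  sm <- cpp_gaussian_blur(px, sigma)
  if (inherits(image, "octa_image"))
    octa_image(pmin(pmax(sm, 0), 1), field_mm = image$field_mm,
               bit_depth = image$bit_depth)
  else sm
}

#' Adaptive local-mean thresholding
#'
#' Marks a pixel as avascular when its intensity falls below the mean of
#' its `window x window` neighbourhood minus `offset`. The local mean
#' uses reflective borders.
#'
#' @param image an [octa_image()] or numeric matrix.
#' @param window odd window size (`>= 3`).
#' @param offset intensity offset subtracted from the local mean.
#' @return Binary integer matrix (1 = avascular).
#' @export
adaptive_threshold <- function(image, window, offset) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3", call. = FALSE)
  px <- if (inherits(image, "octa_image")) image$pixels else image
  mu <- cpp_local_mean(px, window)
  (px < mu - offset) + 0L
}

#' Connected candidate components of an avascular mask
#'
#' @param mask binary matrix (nonzero = avascular).
#' @param connectivity 4 or 8.
#' @param min_candidate_area components smaller than this are dropped
#'   (ids are re-compacted in raster order).
#' @return A `component_set`: `list(component_labels, areas, connectivity)`
#'   with component ids `1..K` assigned in raster order of each
#'   component's first pixel and `areas[k]` its pixel count.
#' @export
find_candidates <- function(mask, connectivity = 8, min_candidate_area = 1) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- cpp_label_components(m, as.integer(connectivity))
  K <- max(lab)
  areas <- if (K > 0) tabulate(lab[lab > 0L], nbins = K) else integer(0)
  if (min_candidate_area > 1 && K > 0) {
    keep <- which(areas >= min_candidate_area)
    remap <- integer(K)
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    areas <- areas[keep]
  }
  structure(list(component_labels = lab, areas = as.integer(areas),
                 connectivity = as.integer(connectivity)),
            class = "component_set")
}

#' Assign CFZ candidates to vessel classes by adjacency
#'
#' Each candidate component is compared against the artery and vein masks
#' dilated by a disk of `adjacency_radius`. The component is assigned to
#' the class with the larger pixel overlap; components overlapping
#' neither dilated mask are rejected. Equal nonzero overlaps go to the
#' periarterial class with a warning (deterministic artery-first
#' tie-break). The three outputs partition the candidate pixels.
#'
#' @param candidates a `component_set` from [find_candidates()].
#' @param artery_mask,vein_mask disjoint binary matrices.
#' @param adjacency_radius dilation disk radius in pixels.
#' @return `list(paCFZ, pvCFZ, rejected, log)`; the masks are binary
#'   matrices and `log` is a data.frame with one row per component
#'   (`id`, `area`, `artery_overlap`, `vein_overlap`, `decision`).
#' @export
assign_by_adjacency <- function(candidates, artery_mask, vein_mask,
                                adjacency_radius = 3) {
  lab <- candidates$component_labels
  if (!all(dim(artery_mask) == dim(lab)) || !all(dim(vein_mask) == dim(lab)))
    stop("masks must share the candidate map's shape", call. = FALSE)
  if (any(artery_mask != 0 & vein_mask != 0))
    stop("artery and vein masks must be disjoint", call. = FALSE)
  K <- length(candidates$areas)
  dil_a <- cpp_dilate_disk(matrix(as.integer(artery_mask != 0), nrow(lab), ncol(lab)),
                           as.integer(adjacency_radius))
  dil_v <- cpp_dilate_disk(matrix(as.integer(vein_mask != 0), nrow(lab), ncol(lab)),
                           as.integer(adjacency_radius))
  in_a <- lab[dil_a == 1L]; in_v <- lab[dil_v == 1L]
  ov_a <- tabulate(in_a[in_a > 0L], nbins = K)
  ov_v <- tabulate(in_v[in_v > 0L], nbins = K)
  decision <- ifelse(ov_a == 0 & ov_v == 0, "rejected",
              ifelse(ov_a > ov_v, "paCFZ",
              ifelse(ov_v > ov_a, "pvCFZ", "paCFZ")))
  ties <- which(ov_a == ov_v & ov_a > 0)
  if (length(ties))
    warning(sprintf("tie in vessel adjacency for component(s) %s; assigned periarterial",
                    paste(ties, collapse = ", ")), call. = FALSE)
  dec_of_pixel <- c("", decision)[lab + 1L]
  shape <- dim(lab)
  out <- list(
    paCFZ = matrix(as.integer(dec_of_pixel == "paCFZ"), shape[1], shape[2]),
    pvCFZ = matrix(as.integer(dec_of_pixel == "pvCFZ"), shape[1], shape[2]),
    rejected = matrix(as.integer(dec_of_pixel == "rejected"), shape[1], shape[2]),
    log = data.frame(id = seq_len(K), area = candidates$areas,
                     artery_overlap = ov_a, vein_overlap = ov_v,
                     decision = decision, stringsAsFactors = FALSE))
  out
}

#' Compose a five-class CFZ map from disjoint masks
#'
#' @param artery_mask,vein_mask,paCFZ_mask,pvCFZ_mask pairwise disjoint
#'   binary matrices of equal shape.
#' @return A [label_map()] with classes 1-4 from the four masks and 0
#'   elsewhere.
#' @export
compose_cfz_map <- function(artery_mask, vein_mask, paCFZ_mask, pvCFZ_mask) {
  masks <- list(artery = artery_mask, vein = vein_mask,
                paCFZ = paCFZ_mask, pvCFZ = pvCFZ_mask)
  nm <- names(masks)
  for (i in 1:3) for (j in (i + 1):4)
    if (any(masks[[i]] != 0 & masks[[j]] != 0))
      stop(sprintf("masks overlap: %s and %s", nm[i], nm[j]), call. = FALSE)
  out <- matrix(0L, nrow(artery_mask), ncol(artery_mask))
  for (k in 1:4) out[masks[[k]] != 0] <- k
  label_map(out)
}

#' Run the full CFZ candidate pipeline
#'
#' Deterministic composition of [gaussian_denoise()],
#' [adaptive_threshold()], [find_candidates()], [assign_by_adjacency()]
#' and [compose_cfz_map()]. Before thresholding, vessel pixels are
#' replaced by the median extravascular intensity so that bright
#' vasculature does not inflate the local mean in its halo (which would
#' otherwise flag normally perfused pixels beside every large vessel);
#' vessel pixels are then removed from the avascular mask so candidates
#' are strictly extravascular.
#'
#' @param image an [octa_image()] or numeric matrix.
#' @param artery_mask,vein_mask disjoint binary vessel masks (external
#'   input or taken from a segmentation).
#' @param params a [pipeline_params()].
#' @return `list(map = label_map, log = assignment data.frame)`.
#' @export
run_cfz_pipeline <- function(image, artery_mask, vein_mask,
                             params = pipeline_params()) {
  stopifnot(inherits(params, "pipeline_params"))
  den <- gaussian_denoise(image, params$gaussian_sigma)
  px <- if (inherits(den, "octa_image")) den$pixels else den
  vessels <- artery_mask != 0 | vein_mask != 0
  px[vessels] <- median(px[!vessels])
  mask <- adaptive_threshold(px, params$threshold_window, params$threshold_offset)
  mask[vessels] <- 0L
  cand <- find_candidates(mask, params$connectivity, params$min_candidate_area)
  asg <- assign_by_adjacency(cand, artery_mask, vein_mask, params$adjacency_radius)
  map <- compose_cfz_map(artery_mask, vein_mask, asg$paCFZ, asg$pvCFZ)
  list(map = map, log = asg$log)
}
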