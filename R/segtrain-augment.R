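#' On-the-fly training augmentation
#'
#' Applies a random subset of the six training-time transforms — random
#' horizontal flip, zoom, rotation, shift, shear and brightness — with
#' shared geometric parameters for the image and its label map. The
#' label map is resampled with nearest-neighbour interpolation so labels
#' are never blended; brightness affects the image only. Deterministic
#' under `seed`.
#'
#' Default parameter ranges (configurable): zoom 0.9-1.1, rotation
#' +/- 15 degrees, shift +/- 5% of the image side, shear +/- 5 degrees,
#' brightness +/- 0.1 intensity.
#'
#' @param image numeric matrix (or [octa_image()]) of intensities.
#' @param map a [label_map()] of equal shape.
#' @param seed RNG seed for this draw.
#' @param toggles named logical list enabling each transform; see
#'   [augment_toggles()].
#' @param ranges named list of half-ranges: `zoom`, `rotate_deg`,
#'   `shift_frac`, `shear_deg`, `brightness`.
#' @return `list(image, map)` with the same types as the inputs.
#' @export
augment_pair <- function(image, map, seed, toggles = augment_toggles(),
                         ranges = list(zoom = 0.1, rotate_deg = 15,
                                       shift_frac = 0.05, shear_deg = 5,
                                       brightness = 0.1)) {
  with_seed(seed, augment_pair_impl(image, map, toggles, ranges))
}

#' @param flip,zoom,rotate,shift,shear,brightness logical toggles.
#' @rdname augment_pair
#' @export
augment_toggles <- function(flip = TRUE, zoom = TRUE, rotate = TRUE,
                            shift = TRUE, shear = TRUE, brightness = TRUE) {
  list(flip = flip, zoom = zoom, rotate = rotate, shift = shift,
       shear = shear, brightness = brightness)
}

# Core transform; consumes the *current* RNG stream (train_fold draws
# augmentations from its own seeded stream).
augment_pair_impl <- function(image, map, toggles, ranges) {
  is_oi <- inherits(image, "octa_image")
  px <- if (is_oi) image$pixels else image
  lab <- unclass(map)
  if (!all(dim(px) == dim(lab)))
    stop("image and label map shapes differ", call. = FALSE)

  if (isTRUE(toggles$flip) && runif(1) < 0.5) {
    px <- px[, ncol(px):1, drop = FALSE]
    lab <- lab[, ncol(lab):1, drop = FALSE]
  }

  s <- if (isTRUE(toggles$zoom)) runif(1, 1 - ranges$zoom, 1 + ranges$zoom) else 1
  th <- if (isTRUE(toggles$rotate)) runif(1, -ranges$rotate_deg, ranges$rotate_deg) * pi / 180 else 0
  dxy <- if (isTRUE(toggles$shift)) runif(2, -ranges$shift_frac, ranges$shift_frac) * dim(px) else c(0, 0)
  sh <- if (isTRUE(toggles$shear)) tan(runif(1, -ranges$shear_deg, ranges$shear_deg) * pi / 180) else 0

  if (s != 1 || th != 0 || any(dxy != 0) || sh != 0) {
    A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      matrix(c(1, 0, sh, 1), 2, 2)
    ctr <- dim(px) / 2
    off <- ctr - A %*% ctr + dxy
    m <- rbind(t(A), as.numeric(off))  # 3 x 2 as expected by EBImage
    dm <- dim(px)
    px <- EBImage::imageData(EBImage::affine(EBImage::Image(px), m,
                                             filter = "bilinear",
                                             output.dim = dm, bg.col = 0,
                                             antialias = FALSE))
    lab_w <- EBImage::imageData(EBImage::affine(EBImage::Image(lab + 0), m,
                                                filter = "none",
                                                output.dim = dm, bg.col = 0))
    lab <- matrix(as.integer(round(lab_w)), dm[1], dm[2])
    px <- pmin(pmax(px, 0), 1)
  }

  if (isTRUE(toggles$brightness)) {
    px <- pmin(pmax(px + runif(1, -ranges$brightness, ranges$brightness), 0), 1)
  }

  list(image = if (is_oi) octa_image(px, field_mm = image$field_mm,
                                     bit_depth = image$bit_depth) else px,
       map = label_map(lab))
}
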