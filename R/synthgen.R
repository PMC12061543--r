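#' Specification for a synthetic en-face vessel image
#'
#' Builds the parameter set driving the synthetic OCTA-like image
#' generator. The generator emulates the appearance the CFZ analysis
#' relies on: bright large vessels entering the frame and branching
#' inward, a speckled capillary texture, and darker avascular bands
#' (capillary-free zones) hugging each large vessel. Disease stage is
#' modelled through the CFZ band geometry: wider, less fragmented bands
#' for more advanced stages, which raises CFZ ratios and mean component
#' sizes and lowers component counts.
#'
#' Stage presets (overridable through `...`):
#' \describe{
#'   \item{control}{band half-widths 3/3 px (periarterial/perivenous),
#'     fragmentation 0.55 — narrow bands frequently interrupted by
#'     capillary encroachment.}
#'   \item{NoDR}{half-widths 4/4 px, fragmentation 0.40.}
#'   \item{mild}{half-widths 6/5 px, fragmentation 0.22 — wide, mostly
#'     contiguous bands.}
#' }
#'
#' @param stage disease stage preset: `"control"`, `"NoDR"` or `"mild"`.
#' @param image_size pixels per side (square images).
#' @param seed integer seed; the same spec and seed give bit-identical
#'   output.
#' @param ... override any preset field: `n_primary_vessels`,
#'   `vessel_width_px`, `cfz_halfwidth_px` (length-2, periarterial then
#'   perivenous), `cfz_fragmentation` (probability of interrupting a band),
#'   `capillary_density`, `noise_sd`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(stage = c("control", "NoDR", "mild"),
                           image_size = 256, seed = 1, ...) {
  stage <- match.arg(stage)
  preset <- switch(stage,
    control = list(cfz_halfwidth_px = c(pa = 3, pv = 3), cfz_fragmentation = 0.55),
    NoDR    = list(cfz_halfwidth_px = c(pa = 4, pv = 4), cfz_fragmentation = 0.40),
    mild    = list(cfz_halfwidth_px = c(pa = 6, pv = 5), cfz_fragmentation = 0.22))
  spec <- list(
    image_size = as.integer(image_size),
    n_primary_vessels = 6L,
    vessel_width_px = 5,
    cfz_halfwidth_px = preset$cfz_halfwidth_px,
    cfz_fragmentation = preset$cfz_fragmentation,
    capillary_density = 0.35,
    noise_sd = 0.03,
    stage = stage,
    seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown))
    stop("unknown synthetic_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec[names(dots)] <- dots
  validate_synthetic_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$image_size >= 16, spec$n_primary_vessels >= 2)
  if (any(spec$cfz_halfwidth_px < 0))
    stop("cfz_halfwidth_px must be >= 0", call. = FALSE)
  for (p in c("cfz_fragmentation", "capillary_density"))
    if (spec[[p]] < 0 || spec[[p]] > 1)
      stop(p, " must be a probability in [0, 1]", call. = FALSE)
  if (spec$vessel_width_px >= spec$image_size)
    stop("vessel width must be smaller than the image", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(spec)
}

# Biased random-walk vessel growth. Trunks of alternating class enter
# from the image border aimed at the centre and meander inward, shedding
# branches of reduced calibre. Runs on the *current* RNG stream.
grow_vessel_tree <- function(spec) {
  n <- spec$image_size
  k <- spec$n_primary_vessels
  ctr <- (n + 1) / 2
  phi <- 2 * pi * ((seq_len(k) - 1) + runif(k, -0.2, 0.2)) / k
  # entry points on the bounding circle, clamped into the frame
  r0 <- pmin(pmax(ctr + (n / 2) * sin(phi), 1), n)
  c0 <- pmin(pmax(ctr + (n / 2) * cos(phi), 1), n)
  theta <- atan2(ctr - r0, ctr - c0) + runif(k, -0.3, 0.3)
  rad <- rep(spec$vessel_width_px / 2, k)
  cls <- rep_len(c(1L, 2L), k)
  active <- rep(TRUE, k)
  r <- r0; c <- c0
  step <- 1.2
  max_walkers <- 12L * k
  out_r <- vector("list", 512); out_c <- out_r; out_rad <- out_r; out_cls <- out_r
  it <- 0L
  while (any(active) && it < 4L * n) {
    it <- it + 1L
    idx <- which(active)
    out_r[[it]] <- r[idx]; out_c[[it]] <- c[idx]
    out_rad[[it]] <- rad[idx]; out_cls[[it]] <- cls[idx]
    theta[idx] <- theta[idx] + rnorm(length(idx), 0, 0.18)
    # steer gently back toward the centre so trunks stay in frame
    to_ctr <- atan2(ctr - r[idx], ctr - c[idx])
    d <- sqrt((r[idx] - ctr)^2 + (c[idx] - ctr)^2)
    pull <- pmin(0.20, 0.25 * d / n)
    dth <- ((to_ctr - theta[idx] + pi) %% (2 * pi)) - pi
    theta[idx] <- theta[idx] + pull * dth
    r[idx] <- r[idx] + step * sin(theta[idx])
    c[idx] <- c[idx] + step * cos(theta[idx])
    rad[idx] <- rad[idx] * 0.9975
    # branching: spawn a thinner child walker
    can_branch <- idx[rad[idx] > 1.1 & length(r) < max_walkers]
    if (length(can_branch)) {
      b <- can_branch[runif(length(can_branch)) < 0.025]
      if (length(b)) {
        side <- sample(c(-1, 1), length(b), replace = TRUE)
        r <- c(r, r[b]); c <- c(c, c[b])
        theta <- c(theta, theta[b] + side * runif(length(b), 0.5, 1.0))
        rad <- c(rad, rad[b] * 0.72)
        cls <- c(cls, cls[b])
        active <- c(active, rep(TRUE, length(b)))
        rad[b] <- rad[b] * 0.92
      }
    }
    gone <- r < -5 | r > n + 5 | c < -5 | c > n + 5 | rad < 0.7
    active[gone] <- FALSE
  }
  list(r = unlist(out_r[seq_len(it)]), c = unlist(out_c[seq_len(it)]),
       rad = unlist(out_rad[seq_len(it)]), cls = unlist(out_cls[seq_len(it)]))
}

#' Generate disjoint artery and vein masks
#'
#' Alternating artery/vein trunks enter from the image border and branch
#' inward as smooth biased random walks with decreasing calibre. Where a
#' vein crossing overlaps an artery, the pixel is kept arterial so the
#' two masks are disjoint.
#'
#' @param spec a [synthetic_spec()].
#' @return `list(artery, vein)` of binary integer matrices.
#' @export
generate_vessel_tree <- function(spec) {
  validate_synthetic_spec(spec)
  with_seed(spec$seed, {
    tr <- grow_vessel_tree(spec)
    n <- spec$image_size
    a <- tr$cls == 1L
    artery <- cpp_stamp_disks(n, n, tr$r[a], tr$c[a], tr$rad[a])
    vein <- cpp_stamp_disks(n, n, tr$r[!a], tr$c[!a], tr$rad[!a])
    vein[artery == 1L] <- 0L
    list(artery = artery, vein = vein)
  })
}

# CFZ bands: dilate each vessel class by its band half-width, subtract the
# vasculature, resolve periarterial/perivenous overlap artery-first, then
# interrupt the bands with a smooth random "capillary encroachment" field
# cut at the fragmentation quantile. Runs on the current RNG stream.
carve_cfz_bands <- function(spec, artery, vein) {
  n <- spec$image_size
  hw <- round(spec$cfz_halfwidth_px)
  vessels <- artery == 1L | vein == 1L
  pa <- if (hw[1] > 0) cpp_dilate_disk(artery, hw[1]) else artery * 0L
  pv <- if (hw[2] > 0) cpp_dilate_disk(vein, hw[2]) else vein * 0L
  pa[vessels] <- 0L
  pv[vessels | pa == 1L] <- 0L
  frag <- spec$cfz_fragmentation
  field <- cpp_gaussian_blur(matrix(runif(n * n), n, n), 2.0)
  if (frag >= 1) {
    pa[] <- 0L; pv[] <- 0L
  } else if (frag > 0) {
    cut <- field <= quantile(field, frag)
    pa[cut] <- 0L
    pv[cut] <- 0L
  }
  list(pa = pa, pv = pv)
}

#' Generate one synthetic sample with constructive ground truth
#'
#' Renders a grayscale image (bright vessels, mid-gray speckled capillary
#' texture, dark CFZ bands, additive Gaussian noise clipped to `[0, 1]`)
#' together with the exact five-class label map used to render it.
#'
#' @param spec a [synthetic_spec()].
#' @param metadata optional [eye_metadata()] row; defaults to a synthetic
#'   subject labelled with the spec's stage.
#' @return `list(image = octa_image, truth = label_map, metadata)`.
#' @export
generate_sample <- function(spec, metadata = NULL) {
  validate_synthetic_spec(spec)
  if (is.null(metadata))
    metadata <- eye_metadata(sprintf("SYN%07d", spec$seed), "OD", spec$stage)
  with_seed(spec$seed, {
    tr <- grow_vessel_tree(spec)
    n <- spec$image_size
    a <- tr$cls == 1L
    artery <- cpp_stamp_disks(n, n, tr$r[a], tr$c[a], tr$rad[a])
    vein <- cpp_stamp_disks(n, n, tr$r[!a], tr$c[!a], tr$rad[!a])
    vein[artery == 1L] <- 0L
    bands <- carve_cfz_bands(spec, artery, vein)

    truth <- matrix(0L, n, n)
    truth[bands$pa == 1L] <- 3L
    truth[bands$pv == 1L] <- 4L
    truth[artery == 1L] <- 1L
    truth[vein == 1L] <- 2L

    # rendering levels keep the physical intensity hierarchy: capillary
    # texture 0.55-0.77 (floor + smoothed speckle), large veins 0.85,
    # arteries 0.97, avascular CFZ 0.10
    speckle <- matrix(rbinom(n * n, 1L, spec$capillary_density), n, n)
    img <- 0.55 + 0.22 * cpp_gaussian_blur(speckle + 0, 1.0)
    img[truth == 3L | truth == 4L] <- 0.10
    img[vein == 1L] <- 0.85
    img[artery == 1L] <- 0.97
    if (spec$noise_sd > 0) img <- img + rnorm(n * n, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)

    list(image = octa_image(img, bit_depth = NA_integer_),
         truth = label_map(truth), metadata = metadata)
  })
}

#' Generate a three-group synthetic cohort
#'
#' Produces `3 * n_per_group` samples (control, NoDR, mild) with distinct
#' subject ids, random lateralities and group-specific stage presets.
#' Deterministic under `seed`.
#'
#' @param n_per_group samples per group (one image per subject).
#' @param seed integer master seed; per-sample seeds are derived from it.
#' @param image_size pixels per side for every sample.
#' @param stage_effect if `FALSE` every group uses the control preset
#'   (group labels are kept), which is useful for null-calibration
#'   experiments.
#' @param ... further [synthetic_spec()] overrides applied to all groups.
#' @return A list of samples as returned by [generate_sample()].
#' @export
generate_cohort <- function(n_per_group, seed = 1, image_size = 256,
                            stage_effect = TRUE, ...) {
  stopifnot(n_per_group >= 1)
  groups <- rep(c("control", "NoDR", "mild"), each = n_per_group)
  n_tot <- length(groups)
  lat <- with_seed(seed, sample(c("OD", "OS"), n_tot, replace = TRUE))
  base <- (as.integer(seed) %% 20000L) * 100000L
  lapply(seq_len(n_tot), function(i) {
    stage <- if (stage_effect) groups[i] else "control"
    spec <- synthetic_spec(stage, image_size = image_size,
                           seed = base + i, ...)
    md <- eye_metadata(sprintf("%s-%03d", groups[i], ((i - 1) %% n_per_group) + 1),
                       lat[i], groups[i])
    generate_sample(spec, metadata = md)
  })
}
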