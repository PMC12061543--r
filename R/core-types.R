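#' Construct an en-face angiography image object
#'
#' An `octa_image` wraps a 2-D matrix of grayscale intensities in `[0, 1]`
#' together with the physical field of view. En-face OCTA scans are
#' typically acquired over a 6 mm x 6 mm macular field; the matrix follows
#' the usual raster convention (row-major, origin at the top-left).
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`, at least
#'   16 x 16.
#' @param field_mm numeric length-2 physical field size in millimetres
#'   (height, width); both strictly positive.
#' @param bit_depth optional integer recording the bit depth of the source
#'   file (provenance only; intensities are always stored rescaled).
#'
#' @return An object of class `octa_image` with elements `pixels`,
#'   `height`, `width`, `field_mm`, `bit_depth`.
#' @export
octa_image <- function(pixels, field_mm = c(6, 6), bit_depth = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  field_mm <- rep(as.numeric(field_mm), length.out = 2)
  if (any(!is.finite(field_mm)) || any(field_mm <= 0))
    stop("`field_mm` must be strictly positive", call. = FALSE)
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         field_mm = field_mm, bit_depth = as.integer(bit_depth)),
    class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("<octa_image> %d x %d px, %.1f x %.1f mm, intensities [%.3f, %.3f]\n",
              x$height, x$width, x$field_mm[1], x$field_mm[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Label alphabet of the five-class CFZ map, frozen in the file format.
CFZ_CLASSES <- c(background = 0L, artery = 1L, vein = 2L,
                 paCFZ = 3L, pvCFZ = 4L)

# Display palette for the five classes (background, artery, vein,
# periarterial CFZ, perivenous CFZ).
CFZ_PALETTE <- c("#000000", "#D94040", "#4060D9", "#F2B950", "#50C8C8")

#' Construct a five-class CFZ label map
#'
#' A `label_map` is an integer matrix over the fixed alphabet
#' 0 = background, 1 = artery, 2 = vein, 3 = periarterial CFZ,
#' 4 = perivenous CFZ.
#'
#' @param labels integer matrix with values in `0:4`.
#' @return An object of class `label_map` (an integer matrix).
#' @export
label_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- labels[!labels %in% 0:4]
  if (length(bad))
    stop(sprintf("label map contains invalid class value(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  structure(labels, class = c("label_map", "matrix", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  counts <- tabulate(as.integer(x) + 1L, nbins = 5L)
  cat(sprintf("<label_map> %d x %d px; bg %d, artery %d, vein %d, paCFZ %d, pvCFZ %d\n",
              nrow(x), ncol(x), counts[1], counts[2], counts[3], counts[4], counts[5]))
  invisible(x)
}

#' Per-eye metadata record
#'
#' @param subject_id opaque subject identifier (string).
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param group cohort label: `"control"`, `"NoDR"` (diabetic, no
#'   retinopathy) or `"mild"` (mild non-proliferative retinopathy).
#' @return A one-row `data.frame` with class `eye_metadata`.
#' @export
eye_metadata <- function(subject_id, laterality, group) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  group <- match.arg(group, c("control", "NoDR", "mild"))
  structure(
    data.frame(subject_id = as.character(subject_id),
               laterality = laterality, group = group,
               stringsAsFactors = FALSE),
    class = c("eye_metadata", "data.frame"))
}
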