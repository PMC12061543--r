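#' Read a grayscale en-face angiography image
#'
#' Reads a PNG or TIFF file and rescales intensities to `[0, 1]`
#' (`value / (2^bit_depth - 1)`). Multi-channel files are accepted only
#' when all colour channels are identical (i.e. gray stored as RGB); an
#' alpha channel, if present, is ignored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param field_mm physical field size in mm passed to [octa_image()].
#' @return An [octa_image()]; the source bit depth is kept in `$bit_depth`.
#' @export
read_octa_image <- function(path, field_mm = c(6, 6)) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    bits <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(px, "bits.per.sample")
    if (is.null(bits)) bits <- NA_integer_
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3) {
    nch <- dim(px)[3]
    ncol_check <- min(nch, 3L)
    for (k in seq_len(ncol_check - 1L)) {
      if (!isTRUE(all.equal(px[, , k], px[, , k + 1L], tolerance = 0)))
        stop("multi-channel image with non-identical channels: ", path,
             call. = FALSE)
    }
    px <- px[, , 1L]
  }
  octa_image(px, field_mm = field_mm, bit_depth = bits)
}

# Bit depth lives at byte 25 (1-based) of the PNG stream, inside IHDR.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25)
  if (length(hdr) < 25) return(NA_integer_)
  as.integer(hdr[25])
}

#' Read and write five-class CFZ label maps as PNG
#'
#' Label maps are stored as 8-bit grayscale PNG files whose pixel values
#' are the class indices 0-4 directly (0 background, 1 artery, 2 vein,
#' 3 periarterial CFZ, 4 perivenous CFZ). The write -> read round trip is
#' bit-identical.
#'
#' @param path path to the PNG file.
#' @return [read_label_map()] returns a [label_map()];
#'   [write_label_map()] returns `path` invisibly.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("cannot read label map: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1L]
  vals <- round(px * 255)
  bad <- unique(vals[vals > 4])
  if (length(bad))
    stop(sprintf("label map %s contains invalid class value(s): %s",
                 path, paste(sort(bad), collapse = ", ")), call. = FALSE)
  label_map(matrix(as.integer(vals), nrow(px), ncol(px)))
}

#' @param map a [label_map()].
#' @rdname read_label_map
#' @export
write_label_map <- function(map, path) {
  map <- label_map(unclass(map))
  png::writePNG(unclass(map) / 255, path)
  invisible(path)
}

#' Blank out the device layer-indicator overlay
#'
#' OCTA exports carry a device-rendered layer indicator in the bottom-left
#' corner which must be excluded from quantification. All pixels inside
#' the rectangle are set to background (class 0); everything else is
#' unchanged. The operation is idempotent.
#'
#' @param map a [label_map()].
#' @param roi rectangle as `c(row, col, height, width)` (1-based top-left
#'   corner); a zero `height` or `width` is a no-op. See
#'   [layer_indicator_roi()] for the default bottom-left rectangle.
#' @return The edited [label_map()].
#' @export
exclude_layer_indicator <- function(map, roi) {
  map <- label_map(unclass(map))
  roi <- as.integer(round(roi))
  if (length(roi) != 4) stop("`roi` must be c(row, col, height, width)", call. = FALSE)
  h <- roi[3]; w <- roi[4]
  if (h < 0 || w < 0) stop("roi height/width must be non-negative", call. = FALSE)
  if (h == 0 || w == 0) return(map)
  r1 <- roi[1]; c1 <- roi[2]
  if (r1 < 1 || c1 < 1 || r1 + h - 1 > nrow(map) || c1 + w - 1 > ncol(map))
    stop("roi extends outside the image bounds", call. = FALSE)
  map[r1:(r1 + h - 1), c1:(c1 + w - 1)] <- 0L
  label_map(unclass(map))
}

#' Default layer-indicator rectangle
#'
#' The indicator size is device-dependent and not standardised; the
#' default is a configurable rectangle of 12% of the image height by 25%
#' of the width, anchored at the bottom-left corner.
#'
#' @param dim image dimensions `c(height, width)` or a [label_map()].
#' @param height_frac,width_frac fraction of image height/width covered.
#' @return `c(row, col, height, width)` suitable for
#'   [exclude_layer_indicator()].
#' @export
layer_indicator_roi <- function(dim, height_frac = 0.12, width_frac = 0.25) {
  if (is.matrix(dim)) dim <- c(nrow(dim), ncol(dim))
  h <- floor(dim[1] * height_frac)
  w <- floor(dim[2] * width_frac)
  c(row = dim[1] - h + 1L, col = 1L, height = h, width = w)
}

FEATURE_COLUMNS <- c("Ra", "Rv", "Rt", "Na", "Nv", "Nt", "Ma", "Mv", "Mt")

#' Write a CFZ biomarker table to CSV
#'
#' One row per (image, region) with columns `subject_id`, `laterality`,
#' `group`, `region` and the nine biomarkers `Ra, Rv, Rt, Na, Nv, Nt, Ma,
#' Mv, Mt`. Rows are written in deterministic order (sorted by
#' `subject_id`, `laterality`, `region`) so output bytes are invariant to
#' input order. Undefined values (e.g. the mean size of an empty
#' component set) are written as empty fields.
#'
#' @param records data.frame with the columns above (e.g. rows built by
#'   [regional_features()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  cols <- c("subject_id", "laterality", "group", "region", FEATURE_COLUMNS)
  if (nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    missing_cols <- setdiff(cols, names(records))
    if (length(missing_cols))
      stop("feature table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    records <- records[cols]
    ord <- order(records$subject_id, records$laterality, records$region,
                 method = "radix")
    records <- records[ord, , drop = FALSE]
  }
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an image-metadata sidecar CSV
#'
#' @param path CSV with columns `subject_id`, `laterality`, `group` and
#'   optionally `image_path` / `label_path`.
#' @return A `data.frame` with validated `laterality` and `group` levels.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "laterality", "group")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(md$laterality %in% c("OD", "OS")))
    stop("laterality must be OD or OS", call. = FALSE)
  if (!all(md$group %in% c("control", "NoDR", "mild")))
    stop("group must be control, NoDR or mild", call. = FALSE)
  md
}
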