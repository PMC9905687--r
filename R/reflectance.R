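#' Five-band raster stack
#'
#' In-memory container for an aligned five-band reflectance raster with a
#' per-pixel validity mask. Band order is fixed as blue, green, red,
#' red edge, near infrared (`B`, `G`, `R`, `RE`, `NIR`).
#'
#' @param bands numeric array `nrow x ncol x 5`, reflectance in `[0, 1]`
#'   for valid pixels (invalid pixels may hold any value; they are ignored).
#' @param mask logical matrix `nrow x ncol`; `TRUE` marks a valid pixel.
#'   Defaults to all valid.
#' @param resolution_mm ground sampling distance in mm/pixel.
#'
#' @return An object of class `pn_stack`: a list with elements `bands`,
#'   `mask` and `resolution_mm`.
#' @export
raster_stack <- function(bands, mask = NULL, resolution_mm = 7.25) {
  bands <- as.array(bands)
  if (length(dim(bands)) != 3L || dim(bands)[3] != 5L) {
    stop("`bands` must be an nrow x ncol x 5 array (B, G, R, RE, NIR)",
         call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow = dim(bands)[1], ncol = dim(bands)[2])
  }
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(bands)[1:2])) {
    stop("`mask` dimensions must match the band planes", call. = FALSE)
  }
  storage.mode(mask) <- "logical"
  dimnames(bands) <- list(NULL, NULL, BAND_NAMES)
  structure(
    list(bands = bands, mask = mask, resolution_mm = resolution_mm),
    class = "pn_stack"
  )
}

#' @export
print.pn_stack <- function(x, ...) {
  d <- dim(x$bands)
  cat(sprintf(
    "<pn_stack> %d x %d pixels, 5 bands (B, G, R, RE, NIR), %.2f mm/pixel\n",
    d[1], d[2], x$resolution_mm
  ))
  cat(sprintf("  valid pixels: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.pn_stack <- function(x) dim(x$bands)

#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based and windows are half-open: a ROI with
#' `x0 = 0, width = 10` covers pixel columns 0..9. `x` indexes columns,
#' `y` rows.
#'
#' @param x0,y0 top-left corner (0-based).
#' @param width,height extent in pixels; must be positive.
#' @return An object of class `pn_roi`.
#' @export
roi_rect <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "pn_roi")
}

#' Physically sized region of interest
#'
#' Converts a physical quadrat footprint (e.g. the 30 cm x 30 cm sampling
#' quadrat) centred on a point into pixel coordinates given the raster
#' resolution.
#'
#' @param size_cm side length of the square footprint, cm.
#' @param center_x,center_y centre in pixel coordinates (0-based); defaults
#'   to the raster centre when resolved against a stack.
#' @param resolution_mm mm/pixel used for the conversion.
#' @return A `pn_roi`.
#' @export
roi_physical <- function(size_cm, center_x, center_y, resolution_mm) {
  side <- max(1L, round(size_cm * 10 / resolution_mm))
  roi_rect(
    x0 = max(0L, round(center_x - side / 2)),
    y0 = max(0L, round(center_y - side / 2)),
    width = side, height = side
  )
}

# Clip a ROI against a stack, returning 1-based row/col index vectors.
roi_indices <- function(stack, roi) {
  d <- dim(stack$bands)
  if (is.null(roi)) {
    return(list(rows = seq_len(d[1]), cols = seq_len(d[2])))
  }
  rows <- seq.int(roi$y0 + 1L, min(d[1], roi$y0 + roi$height))
  cols <- seq.int(roi$x0 + 1L, min(d[2], roi$x0 + roi$width))
  if (roi$y0 + 1L > d[1] || roi$x0 + 1L > d[2] ||
      length(rows) < 1L || length(cols) < 1L) {
    stop("ROI does not intersect the raster", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Read a five-band raster stack from disk
#'
#' Reads the multi-page TIFF layout written by [write_trial()]: pages 1-5
#' are the B, G, R, RE, NIR reflectance planes (32-bit samples in
#' `[0, 1]`); an optional page 6 is a validity mask (1 = valid pixel,
#' 0 = nodata). Files without a mask page are treated as fully valid.
#'
#' @param path path to a TIFF file.
#' @param resolution_mm mm/pixel recorded on the returned stack (the plain
#'   TIFF container carries no georeferencing).
#' @return A [raster_stack()] object.
#' @export
read_stack <- function(path, resolution_mm = 7.25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  if (!length(pages) %in% c(5L, 6L)) {
    stop(sprintf(
      "expected a 5-band stack (plus optional mask page), got %d pages",
      length(pages)
    ), call. = FALSE)
  }
  bands <- array(NA_real_, c(dim(pages[[1]]), 5L))
  for (b in 1:5) bands[, , b] <- pages[[b]]
  mask <- if (length(pages) == 6L) pages[[6]] >= 0.5 else NULL
  raster_stack(bands, mask = mask, resolution_mm = resolution_mm)
}

#' Radiometric correction: digital numbers to reflectance
#'
#' Applies a per-band linear map `gain * DN + offset`, then clips to
#' `[0, 1]`. With `gain = 1, offset = 0` this is the identity on in-range
#' data, so stacks already holding reflectance pass through unchanged.
#'
#' @param stack a [raster_stack()].
#' @param gain,offset length-1 or length-5 numeric vectors (recycled per
#'   band, order B, G, R, RE, NIR). Gains must be positive.
#' @return A corrected `pn_stack`.
#' @export
dn_to_reflectance <- function(stack, gain = 1, offset = 0) {
  stopifnot(inherits(stack, "pn_stack"))
  gain <- rep_len(as.numeric(gain), 5L)
  offset <- rep_len(as.numeric(offset), 5L)
  if (any(gain <= 0)) stop("all gains must be > 0", call. = FALSE)
  out <- stack
  for (b in 1:5) {
    v <- gain[b] * stack$bands[, , b] + offset[b]
    out$bands[, , b] <- pmin(1, pmax(0, v))
  }
  out
}

#' Mask non-canopy background pixels
#'
#' Thresholding removes standing water and soil background before canopy
#' reflectance is averaged. Two rules are provided: `ndvi_threshold` masks
#' pixels with NDVI below `t` (default rule at the vegetative stages) and
#' `nir_threshold` masks pixels with NIR reflectance below `t` (useful at
#' ripening, when canopy NDVI itself collapses). Masking only ever removes
#' pixels; previously invalid pixels stay invalid.
#'
#' @param stack a [raster_stack()].
#' @param rule `"ndvi_threshold"` or `"nir_threshold"`.
#' @param t threshold. NDVI thresholds must lie in (-1, 1), NIR thresholds
#'   in (0, 1).
#' @return A `pn_stack` with an updated mask.
#' @export
mask_background <- function(stack, rule = c("ndvi_threshold", "nir_threshold"),
                            t = 0.3) {
  stopifnot(inherits(stack, "pn_stack"))
  rule <- match.arg(rule)
  nir <- stack$bands[, , "NIR"]
  if (rule == "ndvi_threshold") {
    if (t <= -1 || t >= 1) stop("NDVI threshold must be in (-1, 1)", call. = FALSE)
    red <- stack$bands[, , "R"]
    den <- nir + red
    ndvi <- ifelse(den == 0, 0, (nir - red) / den)
    keep <- ndvi >= t
  } else {
    if (t <= 0 || t >= 1) stop("NIR threshold must be in (0, 1)", call. = FALSE)
    keep <- nir >= t
  }
  out <- stack
  out$mask <- stack$mask & keep
  out
}

#' Mean canopy reflectance over a region of interest
#'
#' Arithmetic mean of the valid (unmasked) pixels of each band inside the
#' ROI — the per-quadrat canopy reflectance feeding the vegetation-index
#' library.
#'
#' @param stack a [raster_stack()].
#' @param roi a [roi_rect()] / [roi_physical()], or `NULL` for the whole
#'   raster.
#' @return A one-row tibble with columns `b_B`, `b_G`, `b_R`, `b_RE`,
#'   `b_NIR`.
#' @export
roi_mean <- function(stack, roi = NULL) {
  stopifnot(inherits(stack, "pn_stack"))
  idx <- roi_indices(stack, roi)
  m <- stack$mask[idx$rows, idx$cols, drop = FALSE]
  if (!any(m)) stop("ROI contains no unmasked pixels", call. = FALSE)
  vals <- vapply(1:5, function(b) {
    plane <- stack$bands[idx$rows, idx$cols, b, drop = FALSE]
    mean(plane[which(m)])
  }, numeric(1))
  tibble::as_tibble(as.list(setNames(vals, paste0("b_", BAND_NAMES))))
}
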