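#' GLCM configuration
#'
#' Settings for moving-window gray-level co-occurrence matrix texture
#' extraction: window size (3, 6, 9 or 12 pixels; even windows anchor the
#' centre at the top-left pixel of the central 2 x 2), number of gray
#' levels for per-band min-max quantization, the pixel offsets considered
#' (default: the four directions 0/45/90/135 degrees at distance 1,
#' averaged) and whether pairs are counted symmetrically. Windows shrink
#' at patch borders rather than padding, so no reflectance values are
#' invented.
#'
#' @param window window side in pixels.
#' @param gray_levels number of quantization levels (>= 2).
#' @param offsets integer matrix of `(dx, dy)` displacements, one row per
#'   offset.
#' @param symmetric count each co-occurrence in both orders?
#' @return An object of class `pn_glcm_config`.
#' @export
glcm_config <- function(window = 3, gray_levels = 32,
                        offsets = rbind(c(1L, 0L), c(1L, 1L),
                                        c(0L, 1L), c(-1L, 1L)),
                        symmetric = TRUE) {
  stopifnot(window >= 2, gray_levels >= 2, ncol(offsets) == 2,
            nrow(offsets) >= 1)
  storage.mode(offsets) <- "integer"
  structure(list(window = as.integer(window),
                 gray_levels = as.integer(gray_levels),
                 offsets = offsets, symmetric = isTRUE(symmetric)),
            class = "pn_glcm_config")
}

#' Quantize a band plane to discrete gray levels
#'
#' Equal-width bins over the unmasked min-max range; a constant plane maps
#' entirely to level 0. Masked (NA) pixels stay NA.
#'
#' @param plane numeric matrix.
#' @param gray_levels number of levels.
#' @param mask optional logical matrix (`TRUE` = valid).
#' @return Integer matrix with values in `0 .. gray_levels - 1` (NA where
#'   masked).
#' @export
quantize <- function(plane, gray_levels = 32, mask = NULL) {
  stopifnot(gray_levels >= 2)
  plane <- as.matrix(plane)
  if (!is.null(mask)) plane[!mask] <- NA_real_
  vals <- plane[is.finite(plane)]
  out <- matrix(NA_integer_, nrow(plane), ncol(plane))
  if (length(vals) == 0L) return(out)
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    out[is.finite(plane)] <- 0L
    return(out)
  }
  lev <- floor((plane - lo) / (hi - lo) * gray_levels)
  lev <- pmin(lev, gray_levels - 1)
  out[is.finite(plane)] <- as.integer(lev[is.finite(plane)])
  out
}

#' Gray-level co-occurrence matrix of one window
#'
#' Counts co-occurring level pairs at each configured offset over a block
#' of quantized levels, symmetrizes if configured, normalizes each
#' offset's matrix to sum 1 and averages over the offsets that produced at
#' least one pair.
#'
#' @param window_levels integer matrix of gray levels (NA = masked).
#' @param config a [glcm_config()]; `config$window` is ignored here (the
#'   supplied block is the window).
#' @param gray_levels matrix dimension; defaults to `config$gray_levels`.
#' @return A `gray_levels x gray_levels` matrix summing to 1.
#' @export
glcm <- function(window_levels, config = glcm_config(),
                 gray_levels = config$gray_levels) {
  window_levels <- as.matrix(window_levels)
  L <- gray_levels
  acc <- matrix(0, L, L)
  used <- 0L
  for (o in seq_len(nrow(config$offsets))) {
    dx <- config$offsets[o, 1]; dy <- config$offsets[o, 2]
    counts <- matrix(0, L, L)
    nr <- nrow(window_levels); nc <- ncol(window_levels)
    for (i in seq_len(nr)) {
      i2 <- i + dy
      if (i2 < 1 || i2 > nr) next
      for (j in seq_len(nc)) {
        j2 <- j + dx
        if (j2 < 1 || j2 > nc) next
        a <- window_levels[i, j]; b <- window_levels[i2, j2]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
        if (config$symmetric) counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1
      }
    }
    tot <- sum(counts)
    if (tot > 0) {
      acc <- acc + counts / tot
      used <- used + 1L
    }
  }
  if (used == 0L) {
    stop("window is smaller than every offset reach (no co-occurring pairs)",
         call. = FALSE)
  }
  acc / used
}

#' Haralick features of a normalized co-occurrence matrix
#'
#' @param P square matrix of co-occurrence probabilities summing to 1
#'   (levels indexed from 0).
#' @return Named numeric vector `MEAN, VAR, HOM, CON, DIS, ENT, SEC, COR`.
#'   `COR` is defined as 1 when either marginal is degenerate.
#' @export
haralick_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalized to sum 1", call. = FALSE)
  L <- nrow(P)
  iv <- matrix(0:(L - 1), L, L)
  jv <- t(iv)
  mu_i <- sum(iv * P); mu_j <- sum(jv * P)
  var_i <- sum((iv - mu_i)^2 * P); var_j <- sum((jv - mu_j)^2 * P)
  pos <- P > 0
  denom <- sqrt(var_i * var_j)
  c(
    MEAN = mu_i,
    VAR = var_i,
    HOM = sum(P / (1 + (iv - jv)^2)),
    CON = sum((iv - jv)^2 * P),
    DIS = sum(abs(iv - jv) * P),
    ENT = -sum(P[pos] * log(P[pos])),
    SEC = sum(P^2),
    COR = if (denom == 0) 1 else sum((iv - mu_i) * (jv - mu_j) * P) / denom
  )
}

texture_codes <- function() sprintf("T%02d", 1:40)

#' Dictionary mapping texture-feature indices to band and feature
#'
#' Index `k` (1..40) maps to band `ceiling(k / 8)` and the feature
#' `MEAN, VAR, HOM, CON, DIS, ENT, SEC, COR` in that order, e.g. index 25
#' is `MEAN4` (mean texture of the red-edge band).
#'
#' @return A tibble with columns `index`, `code` (T01..T40), `band`,
#'   `band_name`, `feature`, `label`.
#' @export
texture_feature_dictionary <- function() {
  idx <- 1:40
  band <- ceiling(idx / 8)
  feat <- TEXTURE_FEATURES[(idx - 1) %% 8 + 1]
  tibble::tibble(
    index = idx, code = texture_codes(), band = band,
    band_name = BAND_NAMES[band], feature = feat,
    label = paste0(feat, band)
  )
}

#' Moving-window texture features of a raster stack
#'
#' For each band: quantize over the unmasked min-max range of the full
#' plane, compute the eight Haralick features per pixel with a truncated
#' moving window, and average each feature map over the unmasked pixels of
#' the ROI. Returns the 40 values in the standard numbering (8 features x
#' 5 bands, band-major).
#'
#' @param stack a [raster_stack()].
#' @param roi a [roi_rect()] or `NULL` for the whole patch.
#' @param config a [glcm_config()].
#' @return Named numeric vector of length 40 (`T01` .. `T40`).
#' @export
texture_vector <- function(stack, roi = NULL, config = glcm_config()) {
  stopifnot(inherits(stack, "pn_stack"), inherits(config, "pn_glcm_config"))
  idx <- roi_indices(stack, roi)
  roi_mask <- stack$mask[idx$rows, idx$cols, drop = FALSE]
  if (!any(roi_mask)) stop("ROI contains no unmasked pixels", call. = FALSE)
  out <- numeric(40)
  for (b in 1:5) {
    lev <- quantize(stack$bands[, , b], config$gray_levels, mask = stack$mask)
    maps <- glcm_texture_map_cpp(lev, config$gray_levels, config$window,
                                 config$offsets, config$symmetric)
    for (f in 1:8) {
      sub <- maps[idx$rows, idx$cols, f, drop = FALSE]
      out[(b - 1) * 8 + f] <- mean(sub[which(roi_mask)], na.rm = TRUE)
    }
  }
  setNames(out, texture_codes())
}

#' Texture features for every sample of a trial
#'
#' @param trial a `pn_trial` tibble with a `patch` list-column (or any
#'   tibble with one).
#' @param config a [glcm_config()].
#' @param keep columns carried through (default `sample_id`/`stage`/`pn`
#'   where present).
#' @return A tibble with 40 texture columns `T01` .. `T40`.
#' @export
texture_table <- function(trial, config = glcm_config(),
                          keep = intersect(c("sample_id", "stage", "pn"),
                                           names(trial))) {
  if (is.null(trial$patch)) {
    stop("trial has no `patch` column; regenerate with include_patches = TRUE",
         call. = FALSE)
  }
  tex <- t(vapply(trial$patch, texture_vector, numeric(40), config = config))
  dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(trial), dplyr::all_of(keep)),
    tibble::as_tibble(tex)
  )
}
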