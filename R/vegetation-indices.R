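# The 25-index vegetation-index library. Formulas follow the source
# study's printed forms, several of which deviate from the common
# literature definitions (GNDVI over green/red instead of NIR/green, TVI
# built on the red edge, SIPI normalized by NIR+B); for those a
# `variant = "literature"` escape hatch restores the conventional formula.
# Square roots lost in the printed rendering of MSAVI, MSR, MTVI and RDVI
# are restored (the sqrt-free MSR reading would be algebraically identical
# to NDVI, which contradicts the study's own distinct correlation values).

VI_NAMES <- c(
  "NIRv", "CIgreen", "CIrededge", "CVI", "DVI", "EVI", "GI", "GNDVI",
  "MCARI", "MNVI", "MSAVI", "MSR", "MTCI", "MTVI", "NLI", "NDVI", "OSAVI",
  "RDVI", "RVI1", "RVI2", "SIPI", "TCARI", "TVI", "VARI", "VDVI"
)

# Safe division: NA (undefined marker) instead of Inf/NaN on zero
# denominators; undefined values propagate as missing.
vi_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
vi_sqrt <- function(x) ifelse(x < 0, NA_real_, sqrt(x))

VI_FORMULAS <- list(
  NIRv      = function(B, G, R, RE, NIR) NIR * vi_div(NIR - R, NIR + R),
  CIgreen   = function(B, G, R, RE, NIR) vi_div(NIR, G) - 1,
  CIrededge = function(B, G, R, RE, NIR) vi_div(NIR, RE) - 1,
  CVI       = function(B, G, R, RE, NIR) vi_div(NIR * R, G^2),
  DVI       = function(B, G, R, RE, NIR) NIR - R,
  EVI       = function(B, G, R, RE, NIR)
    vi_div(2.5 * (NIR - R), NIR + 6 * R - 7.5 * B + 1),
  GI        = function(B, G, R, RE, NIR) vi_div(G, R),
  GNDVI     = function(B, G, R, RE, NIR) vi_div(G - R, G + R),
  MCARI     = function(B, G, R, RE, NIR)
    ((RE - R) - 0.2 * (RE - G)) * vi_div(RE, R),
  MNVI      = function(B, G, R, RE, NIR)
    vi_div(1.5 * (NIR^2 - R), NIR^2 + R + 0.5),
  MSAVI     = function(B, G, R, RE, NIR)
    (2 * NIR + 1 - vi_sqrt((2 * NIR + 1)^2 - 8 * (NIR - R))) / 2,
  MSR       = function(B, G, R, RE, NIR)
    vi_div(vi_div(NIR, R) - 1, vi_sqrt(vi_div(NIR, R) + 1)),
  MTCI      = function(B, G, R, RE, NIR) vi_div(NIR - RE, RE - R),
  MTVI      = function(B, G, R, RE, NIR)
    vi_div(1.5 * (1.2 * (NIR - G) - 2.5 * (R - G)),
           vi_sqrt((2 * NIR + 1)^2 - (NIR - 5 * R) - 0.5)),
  NLI       = function(B, G, R, RE, NIR) vi_div(NIR^2 - R, NIR^2 + R),
  NDVI      = function(B, G, R, RE, NIR) vi_div(NIR - R, NIR + R),
  OSAVI     = function(B, G, R, RE, NIR)
    vi_div(1.16 * (NIR - R), NIR + R + 0.16),
  RDVI      = function(B, G, R, RE, NIR) vi_div(NIR - R, vi_sqrt(NIR + R)),
  RVI1      = function(B, G, R, RE, NIR) vi_div(NIR, R),
  RVI2      = function(B, G, R, RE, NIR) vi_div(NIR, G),
  SIPI      = function(B, G, R, RE, NIR) vi_div(NIR - B, NIR + B),
  TCARI     = function(B, G, R, RE, NIR)
    3 * ((RE - R) - 0.2 * (RE - G) * vi_div(RE, R)),
  TVI       = function(B, G, R, RE, NIR) 60 * (RE - G) - 100 * (R - G),
  VARI      = function(B, G, R, RE, NIR) vi_div(G - R, G + R - B),
  VDVI      = function(B, G, R, RE, NIR)
    vi_div(2 * G - R - B, 2 * G + R + B)
)

VI_LITERATURE <- list(
  GNDVI = function(B, G, R, RE, NIR) vi_div(NIR - G, NIR + G),
  TVI   = function(B, G, R, RE, NIR) 0.5 * (120 * (NIR - G) - 200 * (R - G)),
  SIPI  = function(B, G, R, RE, NIR) vi_div(NIR - B, NIR - R)
)

#' Names of the 25 vegetation indices
#' @return Character vector of index abbreviations.
#' @export
vi_names <- function() VI_NAMES

#' Compute one vegetation index
#'
#' @param name one of [vi_names()].
#' @param b_B,b_G,b_R,b_RE,b_NIR band reflectances in `[0, 1]` (vectorized).
#' @param variant `"printed"` (the source study's formulas, default) or
#'   `"literature"` (conventional formulas for GNDVI, TVI and SIPI; all
#'   other indices are identical under both variants).
#' @return Numeric vector; `NA` marks values undefined by a zero
#'   denominator (or a negative square-root argument).
#' @export
compute_vi <- function(name, b_B, b_G, b_R, b_RE, b_NIR,
                       variant = c("printed", "literature")) {
  variant <- match.arg(variant)
  if (!name %in% VI_NAMES) stop("unknown vegetation index: ", name, call. = FALSE)
  f <- if (variant == "literature" && name %in% names(VI_LITERATURE)) {
    VI_LITERATURE[[name]]
  } else {
    VI_FORMULAS[[name]]
  }
  f(b_B, b_G, b_R, b_RE, b_NIR)
}

#' Compute all 25 vegetation indices
#'
#' @param data a data frame with columns `b_B`, `b_G`, `b_R`, `b_RE`,
#'   `b_NIR` (one row per sample), e.g. a `pn_trial` or [roi_mean()]
#'   output.
#' @inheritParams compute_vi
#' @return A tibble with the 25 index columns, one row per input row; any
#'   non-band input columns named in `keep` are carried through.
#' @param keep columns of `data` to carry into the result (default
#'   `sample_id`/`stage`/`pn` where present).
#' @export
compute_all_vis <- function(data, variant = c("printed", "literature"),
                            keep = intersect(c("sample_id", "stage", "pn"),
                                             names(data))) {
  variant <- match.arg(variant)
  need <- paste0("b_", BAND_NAMES)
  if (!all(need %in% names(data))) {
    stop("`data` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vis <- purrr::map(setNames(VI_NAMES, VI_NAMES), function(nm) {
    compute_vi(nm, data$b_B, data$b_G, data$b_R, data$b_RE, data$b_NIR,
               variant = variant)
  })
  dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(data), dplyr::all_of(keep)),
    tibble::as_tibble(vis)
  )
}
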