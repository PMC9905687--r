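#' Synthetic trial configuration
#'
#' Describes a two-factor paddy trial: five nitrogen doses crossed with two
#' controlled leakage (infiltration) intensities, replicated plots, three
#' quadrats sampled per plot at each of three growth stages. The defaults
#' give 5 x 2 x 2 x 3 = 60 quadrat samples per stage and 180 over the
#' season.
#'
#' Noise parameters, all standard deviations and all `>= 0`:
#' `sigma_plot` (plot-level vigor), `sigma_pn` (residual Pn noise,
#' umol m-2 s-1), `sigma_band` (plot-mean reflectance noise),
#' `sigma_spad`, `sigma_ph` (ground-truth measurement noise),
#' `sigma_quadrat` (latent per-quadrat physiological deviation `q`, fed
#' into Pn, SPAD and PH but not the imagery) and `sigma_structure` (latent
#' per-quadrat canopy-structure deviation `t`, fed into Pn and the band-4
#' texture but not the band means).
#'
#' @param n_replicates plots per treatment.
#' @param nitrogen_doses nitrogen fertilizer levels N1..N5, kg/ha.
#' @param leakage_levels leakage intensities W1, W2, mm/day.
#' @param stages ordered subset of
#'   `c("jointing_booting", "heading_flowering", "ripening")`.
#' @param quadrats_per_plot quadrats measured per plot per stage.
#' @param patch_size image patch side, pixels (41 px is about 30 cm at
#'   7.25 mm/pixel).
#' @param resolution_mm ground sampling distance, mm/pixel.
#' @param sigma_plot,sigma_pn,sigma_band,sigma_spad,sigma_ph,sigma_quadrat,sigma_structure
#'   noise standard deviations (see Details).
#' @param texture_cor_length Gaussian-random-field correlation length of
#'   the patch texture, pixels.
#' @param texture_sd baseline within-patch reflectance standard deviation.
#' @param skew_strength coupling of the band-4 (red edge) texture skewness
#'   to crop status; this plants the band-4 MEAN texture feature as the
#'   strongest single texture correlate of Pn.
#' @param seed default random seed used by [generate_trial()].
#' @return An object of class `pn_trial_config` (a named list).
#' @export
trial_config <- function(n_replicates = 2,
                         nitrogen_doses = c(0, 150, 225, 300, 375),
                         leakage_levels = c(3, 5),
                         stages = GROWTH_STAGES,
                         quadrats_per_plot = 3,
                         patch_size = 41,
                         resolution_mm = 7.25,
                         sigma_plot = 0.05,
                         sigma_pn = 0.5,
                         sigma_band = 0.008,
                         sigma_spad = 0.8,
                         sigma_ph = 2,
                         sigma_quadrat = 1,
                         sigma_structure = 1,
                         texture_cor_length = 2.5,
                         texture_sd = 0.035,
                         skew_strength = 1.1,
                         seed = 42) {
  stages <- match.arg(stages, GROWTH_STAGES, several.ok = TRUE)
  if (length(stages) < 1L) stop("at least one growth stage required", call. = FALSE)
  if (patch_size < 3) stop("patch_size must be at least 3 pixels", call. = FALSE)
  sig <- c(sigma_plot, sigma_pn, sigma_band, sigma_spad, sigma_ph,
           sigma_quadrat, sigma_structure)
  if (any(sig < 0)) stop("all noise standard deviations must be >= 0", call. = FALSE)
  stopifnot(n_replicates >= 1, quadrats_per_plot >= 1,
            length(nitrogen_doses) >= 1, length(leakage_levels) >= 1)
  structure(list(
    n_replicates = as.integer(n_replicates),
    nitrogen_doses = as.numeric(nitrogen_doses),
    leakage_levels = as.numeric(leakage_levels),
    stages = stages,
    quadrats_per_plot = as.integer(quadrats_per_plot),
    patch_size = as.integer(patch_size),
    resolution_mm = resolution_mm,
    sigma_plot = sigma_plot,
    sigma_pn = sigma_pn,
    sigma_band = sigma_band,
    sigma_spad = sigma_spad,
    sigma_ph = sigma_ph,
    sigma_quadrat = sigma_quadrat,
    sigma_structure = sigma_structure,
    texture_cor_length = texture_cor_length,
    texture_sd = texture_sd,
    skew_strength = skew_strength,
    seed = as.integer(seed)
  ), class = "pn_trial_config")
}

#' @export
print.pn_trial_config <- function(x, ...) {
  n_trt <- length(x$nitrogen_doses) * length(x$leakage_levels)
  cat("<pn_trial_config>\n")
  cat(sprintf("  %d nitrogen x %d leakage = %d treatments, %d replicate plot(s)\n",
              length(x$nitrogen_doses), length(x$leakage_levels), n_trt,
              x$n_replicates))
  cat(sprintf("  %d quadrats/plot -> %d samples per stage, stages: %s\n",
              x$quadrats_per_plot,
              n_trt * x$n_replicates * x$quadrats_per_plot,
              paste(x$stages, collapse = ", ")))
  cat(sprintf("  patch %d x %d px at %.2f mm/pixel, seed %d\n",
              x$patch_size, x$patch_size, x$resolution_mm, x$seed))
  invisible(x)
}

#' Read a trial configuration from a YAML file
#'
#' The YAML keys map 1:1 to the arguments of [trial_config()]; absent keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @return A `pn_trial_config`.
#' @export
read_trial_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(trial_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(trial_config, vals)
}
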