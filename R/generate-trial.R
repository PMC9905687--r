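# Latent crop-status model behind the synthetic trial.
#
# A single latent vigor score v(plot) drives everything observable:
#   v = g(N) + leakage bonus + plot effect
# with the nitrogen response g(N) a fixed rise-dip-partial-recovery lookup
# (maximum at N3, dip at N4, partial recovery at N5) and the lower leakage
# intensity (W1) receiving a small bonus. Two further latent deviations are
# drawn per quadrat: q (physiological, visible to Pn/SPAD/PH but not to the
# camera) and t (canopy structure, visible to Pn and to the band-4 texture
# skewness but not to the band means). These make ground measurements and
# image texture carry genuinely complementary information about Pn.
G_NITROGEN <- c(0, 0.55, 1, 0.45, 0.65)
W_BONUS <- 0.08
PN_VIGOR_GAIN <- 0.2
PN_QUADRAT_EFFECT <- 0.9
PN_STRUCTURE_EFFECT <- 0.8
SPAD_NITROGEN_GAIN <- 8
SPAD_W_BONUS <- 0.6
SPAD_QUADRAT_EFFECT <- 1.4
PH_DOSE_GAIN <- 16
PH_VIGOR_GAIN <- 4
PH_QUADRAT_EFFECT <- 0.8
# Centering/scale of vigor used by the texture-skewness channel (mean and
# sd of v over the default treatment grid).
VIGOR_CENTER <- 0.55
VIGOR_SCALE <- 0.33
SKEW_VIGOR_WEIGHT <- 0.6
SKEW_STRUCTURE_WEIGHT <- 0.5
# Relative within-patch texture amplitude per band (B, G, R, RE, NIR).
TEXTURE_REL_SD <- c(0.25, 0.6, 0.3, 1, 1.3)

STAGE_PARAMS <- list(
  pn_base = c(jointing_booting = 25, heading_flowering = 20, ripening = 12),
  ph_base = c(jointing_booting = 72, heading_flowering = 92, ripening = 88),
  spad_base = c(jointing_booting = 37, heading_flowering = 40, ripening = 31)
)

# Band-mean model: intercept + slope * v per stage (B, G, R, RE, NIR).
# Visible and red-edge reflectance fall with vigor; NIR rises at the two
# green stages and collapses at ripening.
BAND_MODEL <- list(
  jointing_booting = cbind(
    intercept = c(0.048, 0.220, 0.058, 0.320, 0.330),
    slope     = c(-0.020, -0.045, -0.025, -0.030, 0.100)
  ),
  heading_flowering = cbind(
    intercept = c(0.043, 0.172, 0.052, 0.300, 0.320),
    slope     = c(-0.018, -0.030, -0.020, -0.028, 0.090)
  ),
  ripening = cbind(
    intercept = c(0.031, 0.037, 0.046, 0.090, 0.031),
    slope     = c(-0.004, -0.007, -0.007, -0.010, 0.003)
  )
)

# Stationary Gaussian random field: white noise smoothed with a separable
# Gaussian kernel of the given correlation length, standardized to zero
# mean and unit sample variance.
grf_field <- function(n, cor_length) {
  if (cor_length <= 0) {
    z <- matrix(rnorm(n * n), n, n)
  } else {
    h <- ceiling(3 * cor_length)
    m <- n + 2L * h
    w <- matrix(rnorm(m * m), m, m)
    kern <- exp(-0.5 * ((-h:h) / cor_length)^2)
    conv <- matrix(0, n, m)
    for (i in seq_len(n)) conv[i, i:(i + 2L * h)] <- kern
    z <- conv %*% w %*% t(conv)
  }
  s <- sd(as.vector(z))
  if (s == 0) return(matrix(0, n, n))
  (z - mean(z)) / s
}

# Skew a standardized field by u: g = (z + u (z^2 - 1) / 2) / sqrt(1 + u^2/2).
# E[g] = 0, Var[g] = 1, skewness monotone in u; the per-patch min-max gray
# quantization makes the GLCM MEAN texture respond to exactly this shape
# parameter, independent of the patch mean and scale.
skew_field <- function(z, u) {
  (z + u * (z^2 - 1) / 2) / sqrt(1 + u^2 / 2)
}

render_patch <- function(band_means, v, t_struct, config) {
  n <- config$patch_size
  bands <- array(NA_real_, c(n, n, 5L))
  u <- config$skew_strength *
    (SKEW_VIGOR_WEIGHT * (v - VIGOR_CENTER) / VIGOR_SCALE +
       SKEW_STRUCTURE_WEIGHT * t_struct)
  for (b in 1:5) {
    z <- grf_field(n, config$texture_cor_length)
    if (b == 4L) z <- skew_field(z, u)
    sd_b <- config$texture_sd * TEXTURE_REL_SD[b] *
      (1 + 0.3 * (v - VIGOR_CENTER))
    plane <- band_means[b] + sd_b * z
    bands[, , b] <- pmin(0.995, pmax(0.002, plane))
  }
  raster_stack(bands, resolution_mm = config$resolution_mm)
}

nitrogen_response <- function(doses) {
  if (length(doses) > length(G_NITROGEN)) {
    stop("at most ", length(G_NITROGEN), " nitrogen doses supported", call. = FALSE)
  }
  G_NITROGEN[seq_along(doses)]
}

#' Generate a synthetic UAV rice trial
#'
#' Draws a full seeded trial — treatment grid, latent crop status, ground
#' truth (Pn, plant height, SPAD) and textured five-band image patches —
#' with the qualitative response structure of a nitrogen x leakage paddy
#' experiment: Pn declines across growth stages; the nitrogen response
#' peaks at N3, dips at N4 and partially recovers at N5; the lower leakage
#' intensity slightly raises Pn; visible/red-edge band means fall and NIR
#' rises with vigor at the vegetative stages, with all bands collapsing at
#' ripening.
#'
#' All randomness flows from `seed` through one stream in a fixed order:
#' plot effects first, then per-stage/per-quadrat ground-truth draws, then
#' (only if `include_patches`) the patch textures row by row. Ground-truth
#' tables are therefore identical for the same seed whether or not patches
#' are rendered.
#'
#' @param config a [trial_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param include_patches render the image patches (list-column `patch`)?
#'   Disable for latent-table-only experiments.
#' @return A tibble of class `pn_trial`, one row per quadrat per stage,
#'   with treatment labels, latent vigor, ground truth (`pn`, `ph`,
#'   `spad`), plot-mean band reflectances `b_B` .. `b_NIR` and optionally a
#'   `patch` list-column of [raster_stack()] objects. The configuration is
#'   attached as attribute `config`.
#' @export
generate_trial <- function(config = trial_config(), seed = config$seed,
                           include_patches = TRUE) {
  stopifnot(inherits(config, "pn_trial_config"))
  set.seed(as.integer(seed))

  gN <- nitrogen_response(config$nitrogen_doses)
  plots <- tidyr::expand_grid(
    n_idx = seq_along(config$nitrogen_doses),
    w_idx = seq_along(config$leakage_levels),
    replicate = seq_len(config$n_replicates)
  )
  plots$plot_id <- sprintf("P%02d", seq_len(nrow(plots)))
  plots$plot_eff <- rnorm(nrow(plots), 0, config$sigma_plot)

  grid <- tidyr::expand_grid(
    stage = factor(config$stages, levels = config$stages),
    plots,
    quadrat = seq_len(config$quadrats_per_plot)
  )
  n <- nrow(grid)

  q <- rnorm(n, 0, config$sigma_quadrat)
  t_struct <- rnorm(n, 0, config$sigma_structure)
  band_noise <- matrix(rnorm(n * 5L, 0, config$sigma_band), n, 5L)
  eps_pn <- rnorm(n, 0, config$sigma_pn)
  eps_spad <- rnorm(n, 0, config$sigma_spad)
  eps_ph <- rnorm(n, 0, config$sigma_ph)

  dose <- config$nitrogen_doses[grid$n_idx]
  leak <- config$leakage_levels[grid$w_idx]
  w1 <- leak == min(config$leakage_levels)
  v <- gN[grid$n_idx] + W_BONUS * w1 + grid$plot_eff
  stage_chr <- as.character(grid$stage)

  pn <- unname(STAGE_PARAMS$pn_base[stage_chr]) * (1 + PN_VIGOR_GAIN * v) +
    PN_QUADRAT_EFFECT * q + PN_STRUCTURE_EFFECT * t_struct + eps_pn
  pn <- pmax(pn, 0.1)
  max_dose <- max(config$nitrogen_doses)
  ph <- unname(STAGE_PARAMS$ph_base[stage_chr]) +
    PH_DOSE_GAIN * (if (max_dose > 0) dose / max_dose else 0) +
    PH_VIGOR_GAIN * grid$plot_eff + PH_QUADRAT_EFFECT * q + eps_ph
  ph <- pmax(ph, 1)
  spad <- unname(STAGE_PARAMS$spad_base[stage_chr]) +
    SPAD_NITROGEN_GAIN * gN[grid$n_idx] +
    SPAD_W_BONUS * w1 + SPAD_QUADRAT_EFFECT * q + eps_spad
  spad <- pmin(pmax(spad, 0.5), 59.5)

  intercepts <- t(vapply(stage_chr, function(s) BAND_MODEL[[s]][, "intercept"],
                         numeric(5)))
  slopes <- t(vapply(stage_chr, function(s) BAND_MODEL[[s]][, "slope"],
                     numeric(5)))
  band_means <- intercepts + slopes * v + band_noise
  band_means <- pmin(pmax(band_means, 0.003), 0.98)
  colnames(band_means) <- paste0("b_", BAND_NAMES)

  out <- tibble::tibble(
    sample_id = sprintf("%s_%s_q%d", substr(stage_chr, 1, 4), grid$plot_id,
                        grid$quadrat),
    stage = grid$stage,
    plot_id = grid$plot_id,
    replicate = grid$replicate,
    quadrat = grid$quadrat,
    n_level = factor(paste0("N", grid$n_idx),
                     levels = paste0("N", seq_along(config$nitrogen_doses))),
    w_level = factor(paste0("W", grid$w_idx),
                     levels = paste0("W", seq_along(config$leakage_levels))),
    n_dose = dose,
    w_leak = leak,
    vigor = v,
    pn = pn,
    ph = ph,
    spad = spad
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(band_means))

  if (include_patches) {
    out$patch <- lapply(seq_len(n), function(i) {
      render_patch(band_means[i, ], v[i], t_struct[i], config)
    })
  }

  attr(out, "config") <- config
  class(out) <- c("pn_trial", class(out))
  out
}

#' Nonlinear-link variant of the synthetic trial
#'
#' Replaces the linear Pn link with a saturating, interaction-bearing
#' function of the plot-mean band reflectances, so that an ordinary linear
#' model is misspecified by construction while flexible learners can
#' recover the response. The functional form is
#'
#' \deqn{Pn = 8 + 9\,\sigma(60(b_{NIR}-0.385))
#'   + 7\,\sigma(60(0.195-b_G))\,\sigma(60(b_{NIR}-0.385))
#'   + 3500\,(b_R-0.044)^2 + \varepsilon,}
#'
#' with \eqn{\sigma} the logistic function and \eqn{\varepsilon \sim
#' N(0, \sigma_{pn})}: a steep NIR saturation, a green-by-NIR saturation
#' product (an interaction no additive linear model can represent) and a
#' non-monotone quadratic term centred on the sampled red-band mean. With `sigma_pn = 0` the response is an exact
#' deterministic function of the band means. The variant's default
#' configuration widens the within-treatment reflectance dispersion
#' (`sigma_band = 0.02`) so the band means explore the nonlinear surface,
#' and uses `sigma_pn = 0.3`.
#'
#' @param config a [trial_config()]; the variant's own default differs
#'   from [trial_config()] defaults only in `sigma_band` and `sigma_pn`.
#' @param seed integer seed.
#' @param include_patches render image patches?
#' @return A `pn_trial` tibble as from [generate_trial()], with `pn`
#'   replaced by the nonlinear link.
#' @export
nonlinear_link_variant <- function(config = trial_config(sigma_band = 0.02,
                                                         sigma_pn = 0.3),
                                   seed = config$seed,
                                   include_patches = TRUE) {
  trial <- generate_trial(config, seed = seed,
                          include_patches = include_patches)
  eps <- rnorm(nrow(trial), 0, config$sigma_pn)
  trial$pn <- nonlinear_pn_link(trial$b_NIR, trial$b_G, trial$b_R) + eps
  attr(trial, "link") <- "nonlinear"
  trial
}

# Deterministic part of the nonlinear Pn link (exported for documentation
# and testing of the misspecification-by-construction property).
#' Deterministic nonlinear Pn response surface
#'
#' The noise-free part of the [nonlinear_link_variant()] link.
#'
#' @param b_nir,b_g,b_r band reflectances.
#' @return Pn in umol m-2 s-1.
#' @export
nonlinear_pn_link <- function(b_nir, b_g, b_r) {
  s_nir <- stats::plogis(60 * (b_nir - 0.385))
  s_g <- stats::plogis(60 * (0.195 - b_g))
  8 + 9 * s_nir + 7 * s_g * s_nir + 3500 * (b_r - 0.044)^2
}
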