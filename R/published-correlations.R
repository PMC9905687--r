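#' Published VI-Pn correlation coefficients
#'
#' Reference Pearson correlation coefficients between the 25 vegetation
#' indices and rice canopy net photosynthetic rate reported by the UAV
#' paddy field study this pipeline re-implements, at each of the three
#' growth stages (n = 60 quadrat samples per stage). Shipped as a
#' plain-text table; useful as a worked example for the selection rule —
#' applying the two-sided p < 0.05 criterion at n = 60 to the
#' jointing-booting column selects 16 indices.
#'
#' @param long return in long format (`feature`, `stage`, `r`)? Default
#'   wide (one column per stage).
#' @return A tibble of correlation coefficients.
#' @export
published_vi_correlations <- function(long = FALSE) {
  path <- system.file("extdata", "vi_pn_correlations.csv", package = "uavpn",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!long) return(tab)
  tidyr::pivot_longer(tab, -"feature", names_to = "stage", values_to = "r")
}

#' Correlation table from published r values
#'
#' Rebuilds a [correlation_table()] (r, two-sided p, stars) from reported
#' correlation coefficients and a known sample size, so the selection rule
#' can be applied to published results.
#'
#' @param r named numeric vector of correlation coefficients (names =
#'   feature names), or a tibble with `feature` and `r` columns.
#' @param n sample size behind the coefficients.
#' @param stage optional stage label.
#' @return A `pn_correlation_table` tibble.
#' @export
correlation_table_from_r <- function(r, n, stage = NA_character_) {
  if (is.data.frame(r)) {
    feats <- r$feature
    rv <- r$r
  } else {
    feats <- names(r)
    rv <- as.numeric(r)
  }
  stopifnot(n >= 3, all(abs(rv) <= 1))
  tval <- abs(rv) * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  out <- tibble::tibble(
    feature = feats, r = rv, p = p, n = as.integer(n),
    stars = dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ ""),
    stage = stage
  )
  class(out) <- c("pn_correlation_table", class(out))
  out
}
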