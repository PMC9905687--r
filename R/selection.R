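#' Pearson correlation with significance
#'
#' Sample Pearson r and its two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; neither constant.
#' @return A named list with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
    2 * pt(tval, df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}

#' Critical |r| for a given significance level
#'
#' The smallest absolute Pearson correlation significant at level `alpha`
#' (two-sided) for sample size `n`; e.g. about 0.254 at `alpha = 0.05`,
#' `n = 60`.
#'
#' @param alpha significance level.
#' @param n sample size.
#' @return Critical absolute correlation.
#' @export
critical_r <- function(alpha, n) {
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(tcrit^2 + n - 2)
}

#' Correlation table of candidate features against Pn
#'
#' Computes Pearson r and two-sided p for every feature column against the
#' target, with significance stars (`*` p < 0.05, `**` p < 0.01). Samples
#' with an undefined (missing) feature value are excluded for that feature
#' only; features left constant or with fewer than 3 complete pairs get
#' `NA`.
#'
#' @param data data frame containing the feature columns and the target.
#' @param features character vector of feature column names; defaults to
#'   all numeric columns except the target.
#' @param target target column name (default `"pn"`).
#' @param stage optional stage label recorded on each row.
#' @return A tibble of class `pn_correlation_table` with columns
#'   `feature`, `r`, `p`, `n`, `stars`, `stage`.
#' @export
correlation_table <- function(data, features = NULL, target = "pn",
                              stage = NA_character_) {
  data <- tibble::as_tibble(data)
  if (!target %in% names(data)) stop("missing target column: ", target,
                                     call. = FALSE)
  if (is.null(features)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(num, target)
  }
  y <- data[[target]]
  rows <- purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    res <- tryCatch(pearson_with_p(x, y),
                    error = function(e) list(r = NA_real_, p = NA_real_,
                                             n = sum(is.finite(x) & is.finite(y))))
    tibble::tibble(feature = f, r = res$r, p = res$p, n = as.integer(res$n))
  })
  rows$stars <- dplyr::case_when(
    is.na(rows$p) ~ "",
    rows$p < 0.01 ~ "**",
    rows$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  rows$stage <- stage
  class(rows) <- c("pn_correlation_table", class(rows))
  rows
}

#' Stage-wise feature selection rule
#'
#' All features significant at `alpha` are selected; if fewer than `k_min`
#' pass, the top `k_min` by `|r|` are taken instead, so a stage where
#' nothing reaches significance still yields a usable input set. Features
#' are returned ordered by `|r|` descending (name ascending on ties).
#'
#' @param table a [correlation_table()] (or any tibble with `feature`,
#'   `r`, `p`).
#' @param alpha significance level (default 0.05).
#' @param k_min minimum number of features (default 5).
#' @return Character vector of selected feature names, ranked.
#' @export
select_features <- function(table, alpha = 0.05, k_min = 5) {
  stopifnot(alpha > 0, alpha <= 1, k_min >= 1)
  tab <- dplyr::filter(tibble::as_tibble(table), !is.na(.data$r))
  tab <- dplyr::arrange(tab, dplyr::desc(abs(.data$r)), .data$feature)
  sig <- dplyr::filter(tab, .data$p < alpha)
  if (nrow(sig) >= k_min) sig$feature else head(tab$feature, k_min)
}
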