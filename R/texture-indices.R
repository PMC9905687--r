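# Texture-index families built from pairs of GLCM features. NDTI and DTI
# follow the usual normalized-difference and difference forms. The
# renormalized form RDTI is difference over the square root of the sum,
# by analogy with the renormalized difference vegetation index; the
# absolute value under the root guards pairs involving negative features
# (correlation can be negative).

#' Texture-index families
#'
#' `ndti(t1, t2) = (t1 - t2) / (t1 + t2)` (0 when the denominator is 0),
#' `dti(t1, t2) = t1 - t2`, and
#' `rdti(t1, t2) = (t1 - t2) / sqrt(|t1 + t2|)` (0 when the denominator is
#' 0). All are vectorized and antisymmetric in their arguments.
#'
#' @param t1,t2 texture feature values.
#' @return Numeric vector.
#' @export
ndti <- function(t1, t2) {
  den <- t1 + t2
  ifelse(den == 0, 0, (t1 - t2) / den)
}

#' @rdname ndti
#' @export
dti <- function(t1, t2) t1 - t2

#' @rdname ndti
#' @export
rdti <- function(t1, t2) {
  den <- sqrt(abs(t1 + t2))
  ifelse(den == 0, 0, (t1 - t2) / den)
}

TI_FAMILIES <- list(NDTI = ndti, DTI = dti, RDTI = rdti)

# Pearson r of every column of M against y, NA for zero-variance columns.
cor_cols <- function(M, y) {
  keep <- is.finite(y)
  suppressWarnings(as.vector(cor(M[keep, , drop = FALSE], y[keep],
                                 use = "pairwise.complete.obs")))
}

#' Exhaustive texture-index pair search
#'
#' Evaluates, for each family (NDTI, DTI, RDTI), the Pearson correlation
#' with Pn of the index built from every ordered pair of the 40 texture
#' features, and reports the best pair per family (maximum `|r|`, ties
#' broken by the lexicographically smallest `(i, j)`). The full 40 x 40
#' correlation matrices (diagonal undefined; entry `(i, j)` equals
#' `-(j, i)` for NDTI and DTI) are returned heatmap-ready.
#'
#' Zero-variance or undefined index columns are treated as missing (their
#' matrix entries stay `NA`) rather than failing the whole search.
#'
#' @param texture data frame or matrix with the 40 texture columns
#'   `T01` .. `T40` (extra columns are ignored).
#' @param pn numeric vector of Pn values, one per row; must not be
#'   constant.
#' @return An object of class `pn_pair_search`: list with `matrices` (one
#'   40 x 40 matrix per family), `best` (tibble: family, i, j, feature1,
#'   feature2, r) and `n`.
#' @export
pair_search <- function(texture, pn) {
  codes <- texture_codes()
  if (is.data.frame(texture)) {
    missing_cols <- setdiff(codes, names(texture))
    if (length(missing_cols)) {
      stop("texture table lacks columns: ",
           paste(head(missing_cols, 5), collapse = ", "), call. = FALSE)
    }
    T40 <- as.matrix(texture[codes])
  } else {
    T40 <- as.matrix(texture)
    if (ncol(T40) != 40L) stop("expected 40 texture columns", call. = FALSE)
    colnames(T40) <- codes
  }
  n <- nrow(T40)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(pn) != n) stop("`pn` length must match rows", call. = FALSE)
  if (isTRUE(sd(pn) == 0)) stop("Pn is constant; correlation undefined", call. = FALSE)

  dict <- texture_feature_dictionary()
  mats <- lapply(TI_FAMILIES, function(f) {
    m <- matrix(NA_real_, 40, 40, dimnames = list(dict$label, dict$label))
    for (i in 1:40) {
      ti <- f(T40[, i], T40[, -i, drop = FALSE])
      r <- suppressWarnings(cor_cols(ti, pn))
      m[i, -i] <- r
    }
    m
  })

  best <- purrr::map_dfr(names(mats), function(fam) {
    m <- mats[[fam]]
    if (all(is.na(m))) {
      return(tibble::tibble(family = fam, i = NA_integer_, j = NA_integer_,
                            feature1 = NA_character_, feature2 = NA_character_,
                            r = NA_real_))
    }
    target <- max(abs(m), na.rm = TRUE)
    hits <- which(abs(m) == target, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    tibble::tibble(family = fam, i = as.integer(i), j = as.integer(j),
                   feature1 = dict$label[i], feature2 = dict$label[j],
                   r = m[i, j])
  })

  structure(list(matrices = mats, best = best, n = n),
            class = "pn_pair_search")
}

#' @export
print.pn_pair_search <- function(x, ...) {
  cat(sprintf("<pn_pair_search> %d samples, 3 families x %d ordered pairs\n",
              x$n, 40 * 39))
  print(x$best)
  invisible(x)
}

#' Values of the best texture-index pairs
#'
#' Recomputes, per sample, the index value of each family's best pair
#' found by [pair_search()] — the three columns (`NDTI`, `DTI`, `RDTI`)
#' that enter the fused model inputs.
#'
#' @param search a `pn_pair_search`.
#' @param texture texture table with columns `T01` .. `T40`.
#' @return A tibble with columns `NDTI`, `DTI`, `RDTI`.
#' @export
best_pair_values <- function(search, texture) {
  stopifnot(inherits(search, "pn_pair_search"))
  T40 <- as.matrix(as.data.frame(texture)[texture_codes()])
  vals <- purrr::map(setNames(search$best$family, search$best$family),
                     function(fam) {
    row <- dplyr::filter(search$best, .data$family == fam)
    TI_FAMILIES[[fam]](T40[, row$i], T40[, row$j])
  })
  tibble::as_tibble(vals)
}

#' Heatmaps of the pair-search correlation matrices
#'
#' One facet per family; tile `(i, j)` is the Pearson r between the index
#' of features `(i, j)` and Pn.
#'
#' @param object a `pn_pair_search`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pn_pair_search <- function(object, ...) {
  df <- purrr::map_dfr(names(object$matrices), function(fam) {
    m <- object$matrices[[fam]]
    tibble::tibble(
      family = fam,
      i = rep(1:40, times = 40),
      j = rep(1:40, each = 40),
      r = as.vector(m)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey85") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "texture feature j", y = "texture feature i",
                  fill = "r vs Pn") +
    ggplot2::theme_minimal()
}
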