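#' Write a synthetic trial to disk
#'
#' Serializes a [generate_trial()] result: one multi-page TIFF per image
#' patch (pages 1-5 = B, G, R, RE, NIR reflectance, 32-bit samples; page 6
#' = validity mask) and one UTF-8 CSV ground-truth table per growth stage
#' with columns `plot_id, quadrat, stage, n_level, w_level, pn, ph, spad,
#' file`. The layout round-trips through [read_stack()] /
#' [read_trial()].
#'
#' @param trial a `pn_trial` tibble with a `patch` column.
#' @param dir output directory (created if absent).
#' @return Invisibly, a tibble listing the files written.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(trial) == 0L) return(invisible(tibble::tibble(file = character())))
  if (is.null(trial$patch)) {
    stop("trial has no `patch` column; regenerate with include_patches = TRUE",
         call. = FALSE)
  }
  files <- character(nrow(trial))
  for (i in seq_len(nrow(trial))) {
    stack <- trial$patch[[i]]
    fn <- sprintf("%s.tif", trial$sample_id[i])
    pages <- c(
      lapply(1:5, function(b) {
        m <- stack$bands[, , b]
        m[] <- pmin(1, pmax(0, m))
        m
      }),
      list(stack$mask * 1)
    )
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 32L,
                    compression = "none")
    files[i] <- fn
  }
  truth <- dplyr::select(tibble::as_tibble(trial), -dplyr::any_of("patch"))
  truth$file <- files
  for (st in levels(droplevels(truth$stage))) {
    readr::write_csv(
      dplyr::filter(truth, .data$stage == st),
      file.path(dir, sprintf("ground_truth_%s.csv", st))
    )
  }
  invisible(tibble::tibble(file = files))
}

#' Read a written trial back from disk
#'
#' Reads the CSV + TIFF layout produced by [write_trial()].
#'
#' @param dir directory written by [write_trial()].
#' @param resolution_mm mm/pixel recorded on the patches.
#' @return A tibble with ground truth and a `patch` list-column.
#' @export
read_trial <- function(dir, resolution_mm = 7.25) {
  csvs <- sort(list.files(dir, pattern = "^ground_truth_.*\\.csv$",
                          full.names = TRUE))
  if (length(csvs) == 0L) stop("no ground-truth tables in ", dir, call. = FALSE)
  truth <- dplyr::bind_rows(lapply(csvs, readr::read_csv,
                                   show_col_types = FALSE))
  truth$stage <- factor(truth$stage,
                        levels = intersect(GROWTH_STAGES, unique(truth$stage)))
  truth <- dplyr::arrange(truth, .data$stage)
  truth$patch <- lapply(truth$file, function(f) {
    read_stack(file.path(dir, f), resolution_mm = resolution_mm)
  })
  truth
}
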