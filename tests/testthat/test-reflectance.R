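test_that("a written trial round-trips through the raster reader", {
  cfg <- fast_config(quadrats_per_plot = 1, n_replicates = 1)
  trial <- generate_trial(cfg, seed = 2)
  dir <- withr::local_tempdir()
  write_trial(trial, dir)
  for (i in c(1, 5, 10)) {
    back <- read_stack(file.path(dir, paste0(trial$sample_id[i], ".tif")))
    expect_lt(max(abs(back$bands - trial$patch[[i]]$bands)), 1e-6)
    expect_identical(back$mask, trial$patch[[i]]$mask)
  }
})

test_that("a 60-sample stage writes 60 rasters and a 60-row table", {
  trial <- generate_trial(trial_config(stages = "ripening", patch_size = 9),
                          seed = 6)
  dir <- withr::local_tempdir()
  write_trial(trial, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 60)
  tab <- readr::read_csv(file.path(dir, "ground_truth_ripening.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), 60)
  expect_true(all(c("plot_id", "stage", "n_level", "w_level", "pn", "ph",
                    "spad") %in% names(tab)))
  # full round trip through read_trial
  back <- read_trial(dir)
  expect_equal(back$pn, trial$pn)
  expect_lt(max(abs(back$patch[[3]]$bands - trial$patch[[3]]$bands)), 1e-6)
})

test_that("writing an empty collection creates an empty directory", {
  trial <- generate_trial(fast_config(), seed = 1)[0, ]
  dir <- withr::local_tempdir()
  expect_no_error(write_trial(trial, dir))
  expect_length(list.files(dir), 0)
})

test_that("read_stack rejects wrong band counts and maps nodata to the mask", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tif")
  tiff::writeTIFF(replicate(3, matrix(0.5, 4, 4), simplify = FALSE), bad,
                  bits.per.sample = 32L)
  expect_error(read_stack(bad), "5-band")
  expect_error(read_stack(file.path(dir, "absent.tif")), "not found")

  msk <- matrix(TRUE, 4, 4); msk[1, ] <- FALSE
  st <- make_stack(0.3, n = 4, mask = msk)
  write_trial(tibble::tibble(sample_id = "one", stage = factor("ripening"),
                             patch = list(st)), dir)
  back <- read_stack(file.path(dir, "one.tif"))
  expect_identical(back$mask, msk)
})

test_that("radiometric correction is a clipped per-band linear map", {
  dn <- make_stack(5000, n = 4)
  refl <- dn_to_reflectance(dn, gain = 1e-4, offset = 0)
  expect_equal(unname(refl$bands[1, 1, ]), rep(0.5, 5))

  st <- make_stack(0.37, n = 4)
  expect_equal(dn_to_reflectance(st, 1, 0)$bands, st$bands)

  over <- dn_to_reflectance(make_stack(1.2, n = 4), gain = 1, offset = 0)
  expect_true(all(over$bands == 1))
  expect_error(dn_to_reflectance(st, gain = 0), "> 0")

  # linearity below the clip: f(a x) - offset = a (f(x) - offset)
  x <- matrix(runif(16, 0.1, 0.4), 4, 4)
  stx <- make_stack(x, n = 4)
  f1 <- dn_to_reflectance(stx, gain = 0.9, offset = 0.05)$bands
  st2 <- make_stack(2 * x, n = 4)
  f2 <- dn_to_reflectance(st2, gain = 0.9, offset = 0.05)$bands
  expect_equal(f2 - 0.05, 2 * (f1 - 0.05), tolerance = 1e-12)
})

test_that("background masking removes exactly the pixels failing the rule", {
  lush <- make_band_stack(c(0.05, 0.2, 0.05, 0.3, 0.45), n = 6)  # NDVI 0.8
  expect_equal(sum(mask_background(lush, "ndvi_threshold", 0.3)$mask), 36)

  flat <- make_band_stack(c(0.05, 0.2, 0.3, 0.3, 0.3), n = 6)    # NDVI 0
  expect_equal(sum(mask_background(flat, "ndvi_threshold", 0.3)$mask), 0)

  # planted water pixels: NIR ~ 0.02 on 10% of the patch
  set.seed(1)
  st <- make_band_stack(c(0.05, 0.2, 0.05, 0.3, 0.45), n = 10)
  water <- sample(100, 10)
  nir <- st$bands[, , 5]
  nir[water] <- 0.02
  st$bands[, , 5] <- nir
  masked <- mask_background(st, "nir_threshold", 0.1)
  expect_identical(which(!masked$mask), sort(water))

  # masking never resurrects an invalid pixel
  pre <- matrix(TRUE, 10, 10); pre[1, 1] <- FALSE
  st2 <- st; st2$mask <- pre
  expect_false(mask_background(st2, "ndvi_threshold", -0.5)$mask[1, 1])

  expect_error(mask_background(st, "ndvi_threshold", 1.5), "NDVI")
  expect_error(mask_background(st, "nir_threshold", 0), "NIR")
})

test_that("ROI means average only unmasked pixels", {
  st <- make_stack(0.4, n = 8)
  expect_equal(unlist(roi_mean(st)), setNames(rep(0.4, 5),
               paste0("b_", c("B", "G", "R", "RE", "NIR"))))

  half <- matrix(0.2, 8, 8); half[, 5:8] <- 0.4
  st2 <- make_stack(half, n = 8)
  expect_equal(roi_mean(st2)$b_G, 0.3)

  msk <- matrix(TRUE, 8, 8); msk[, 1:4] <- FALSE
  st3 <- make_stack(half, n = 8, mask = msk)
  expect_equal(roi_mean(st3)$b_R, 0.4)

  # invariant to adding masked pixels and restriction by rectangle
  expect_equal(roi_mean(st3, roi_rect(4, 0, 4, 8))$b_B, 0.4)
  all_masked <- make_stack(0.4, n = 4, mask = matrix(FALSE, 4, 4))
  expect_error(roi_mean(all_masked), "unmasked")
  expect_error(roi_mean(st, roi_rect(100, 0, 4, 4)), "intersect")
})

test_that("physical ROI sizing converts cm to pixels at the stack resolution", {
  r <- roi_physical(30, center_x = 20, center_y = 20, resolution_mm = 7.25)
  expect_equal(r$width, round(300 / 7.25))
  expect_equal(r$width, 41)
})
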