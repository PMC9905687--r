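test_that("quantization bins equal-width over the observed range", {
  expect_true(all(quantize(matrix(0.7, 5, 5), 32) == 0L))
  expect_equal(quantize(matrix(c(0, 1, 1, 0), 2, 2), 2),
               matrix(c(0L, 1L, 1L, 0L), 2, 2))
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(quantize(ramp, 4), oracle_quantize(ramp, 4), ignore_attr = TRUE)
  set.seed(1)
  x <- matrix(runif(64), 8, 8)
  expect_equal(quantize(x, 8), oracle_quantize(x, 8), ignore_attr = TRUE)
  # masked pixels neither set the range nor receive a level
  m <- matrix(TRUE, 4, 4); m[1, 1] <- FALSE
  x2 <- matrix(seq(0, 1, length.out = 16), 4, 4); x2[1, 1] <- 100
  q <- quantize(x2, 4, mask = m)
  expect_true(is.na(q[1, 1]))
  expect_equal(max(q, na.rm = TRUE), 3L)
})

test_that("single-window co-occurrence matrices match hand enumeration", {
  # constant window: all mass on one diagonal cell
  P <- glcm(matrix(2L, 3, 3), glcm_config(gray_levels = 4))
  expect_equal(P[3, 3], 1)
  expect_equal(sum(P), 1)

  # 2x2 checkerboard, single horizontal offset, symmetric
  cb <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  cfg <- glcm_config(gray_levels = 2, offsets = rbind(c(1L, 0L)))
  P2 <- glcm(cb, cfg)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # normalization holds for arbitrary windows and all four offsets
  set.seed(2)
  for (i in 1:5) {
    w <- matrix(sample(0:7, 25, replace = TRUE), 5, 5)
    expect_equal(sum(glcm(w, glcm_config(gray_levels = 8))), 1,
                 tolerance = 1e-12)
  }
  expect_error(glcm(matrix(0L, 1, 1), glcm_config(gray_levels = 2)), "offset")
})

test_that("Haralick features take their closed-form values on known matrices", {
  # all mass at (3, 3): a degenerate, perfectly homogeneous texture
  P <- matrix(0, 8, 8); P[4, 4] <- 1
  f <- haralick_features(P)
  expect_equal(f, c(MEAN = 3, VAR = 0, HOM = 1, CON = 0, DIS = 0, ENT = 0,
                    SEC = 1, COR = 1))

  # two-level checkerboard matrix
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f2 <- haralick_features(P2)
  expect_equal(f2, c(MEAN = 0.5, VAR = 0.25, HOM = 0.5, CON = 1, DIS = 1,
                     ENT = log(2), SEC = 0.5, COR = -1))

  # uniform matrix over L^2 cells
  for (L in c(2, 5, 8)) {
    fu <- haralick_features(matrix(1 / L^2, L, L))
    expect_equal(unname(fu["SEC"]), 1 / L^2)
    expect_equal(unname(fu["ENT"]), 2 * log(L))
  }
  expect_error(haralick_features(matrix(0.3, 2, 2)), "normalized")
})

test_that("a constant band yields the degenerate texture vector", {
  st <- make_stack(0.4, n = 9)
  tv <- texture_vector(st)
  expect_length(tv, 40)
  for (b in 0:4) {
    expect_equal(unname(tv[b * 8 + c(3, 7)]), c(1, 1))  # HOM, SEC
    expect_equal(unname(tv[b * 8 + c(2, 4, 5, 6)]), rep(0, 4))  # VAR,CON,DIS,ENT
  }
})

test_that("moving-window features match the brute-force oracle exactly", {
  set.seed(11)
  cases <- expand.grid(n = c(8, 12), window = c(3, 6, 9, 12))
  for (ci in seq_len(nrow(cases))) {
    n <- cases$n[ci]; w <- cases$window[ci]
    lev <- matrix(sample(0:7, n * n, replace = TRUE), n, n)
    for (off in list(default_offsets(), rbind(c(1L, 1L)))) {
      for (sym in c(TRUE, FALSE)) {
        got <- uavpn:::glcm_texture_map_cpp(lev, 8L, as.integer(w), off, sym)
        want <- oracle_texture_map(lev, 8, w, off, sym)
        expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
        expect_identical(is.na(got), is.na(want))
      }
    }
  }
})

test_that("oracle equivalence holds under masking", {
  set.seed(12)
  lev <- matrix(sample(0:5, 100, replace = TRUE), 10, 10)
  lev[sample(100, 15)] <- NA
  got <- uavpn:::glcm_texture_map_cpp(lev, 6L, 3L, default_offsets(), TRUE)
  want <- oracle_texture_map(lev, 6, 3, default_offsets(), TRUE)
  expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
  expect_identical(is.na(got), is.na(want))
})

test_that("four-direction averaged features are invariant to 90-degree rotation", {
  set.seed(13)
  bands <- array(runif(10 * 10 * 5), c(10, 10, 5))
  st <- raster_stack(bands)
  rot <- raster_stack(array(apply(bands, 3, function(m) t(m[nrow(m):1, ])),
                            c(10, 10, 5)))
  cfg <- glcm_config(window = 3)
  expect_equal(texture_vector(st, config = cfg),
               texture_vector(rot, config = cfg), tolerance = 1e-10)
})

test_that("texture responds monotonically to checkerboard contrast", {
  # a smooth ramp with a checkerboard of growing amplitude mixed in:
  # neighbouring-pixel jumps grow with the amplitude, so CON/ENT rise
  # while HOM/SEC fall
  n <- 12
  ramp <- outer(1:n, 1:n, function(i, j) (i + j) / (2 * n))
  cb <- outer(1:n, 1:n, function(i, j) (i + j) %% 2 - 0.5)
  feats <- sapply(c(0, 0.1, 0.3), function(a) {
    texture_vector(make_stack(ramp + a * cb, n = n),
                   config = glcm_config(gray_levels = 8))[1:8]
  })
  for (f in c(4, 6)) expect_true(all(diff(feats[f, ]) > 0))  # CON, ENT
  for (f in c(3, 7)) expect_true(all(diff(feats[f, ]) < 0))  # HOM, SEC
})

test_that("the feature dictionary maps index 25 to the red-edge mean", {
  d <- texture_feature_dictionary()
  expect_equal(nrow(d), 40)
  expect_equal(d$label[25], "MEAN4")
  expect_equal(d$band_name[25], "RE")
  expect_equal(d$label[8], "COR1")
  expect_equal(d$code, sprintf("T%02d", 1:40))
})
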