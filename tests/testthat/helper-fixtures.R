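# Small in-code fixtures.

# A stack with every band set to a constant (or a supplied matrix).
make_stack <- function(value = 0.4, n = 8, mask = NULL) {
  bands <- array(NA_real_, c(n, n, 5))
  for (b in 1:5) {
    bands[, , b] <- if (is.matrix(value)) value else matrix(value, n, n)
  }
  raster_stack(bands, mask = mask)
}

# A stack with per-band constants.
make_band_stack <- function(vals, n = 8, mask = NULL) {
  bands <- array(NA_real_, c(n, n, 5))
  for (b in 1:5) bands[, , b] <- matrix(vals[b], n, n)
  raster_stack(bands, mask = mask)
}

# Fast small trial configuration for pipeline tests.
fast_config <- function(...) {
  trial_config(stages = "jointing_booting", patch_size = 15, ...)
}

default_offsets <- function() rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
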