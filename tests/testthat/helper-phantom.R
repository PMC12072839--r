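# Shared fixtures: a small fast phantom and a reference mask with a
# known damage fraction, built in code at test time.

small_spec <- function(...) {
  phantom_spec(body_semi_axes = c(2.4, 1.8), pixel_pitch = 0.06,
               image_shape = c(96L, 96L), ...)
}

# 100 x 100 all-solid block (10,000 object px) with a 50 x 10 damage
# rectangle: weighted fraction exactly 0.05.
block_mask <- function() {
  m <- matrix(1L, 100L, 100L)
  m[21:70, 41:50] <- 2L
  m
}

# Default-geometry phantom mask targeting a 5% damage fraction.
reference_mask <- function(seed = 11L) {
  generate_slice(phantom_spec(), target_fraction = 0.05, seed = seed)$mask
}
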