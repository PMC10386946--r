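# Shared fixtures: protocols and small generators used across test files.

ir_p <- ir_protocol_invivo()
se_p <- se_protocol_invivo()
ref_p <- ir_protocol_reference()

# the 20-sample log-spaced inversion-time ladder of a bench T1 series
nmr_tis <- function(x = 5, n = 20) 0.001 * x * 1000^((seq_len(n) - 1) / (n - 1))

# small brain phantom (48 x 48) for fast map-level tests
small_brain <- function(snr = Inf, seed = 1, protocol = ir_p) {
  make_brain_phantom(brain_phantom_spec(shape = c(48, 48, 1),
                                        snr = snr, seed = seed), protocol)
}

# matrix with uniform bright discs at given centers (tube-detection fixture)
disc_image <- function(nx, ny, centers, radius, value = 1) {
  img <- matrix(0, nx, ny)
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(nrow(centers)))
    img[(x - centers[i, 1])^2 + (y - centers[i, 2])^2 <= radius^2] <- value
  img
}
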