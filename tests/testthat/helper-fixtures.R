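# Shared fixture builders; everything is generated in code at test time.

flat_image <- function(value, n = 8, bit_depth = 16, pixel_size = 1,
                       role = "I") {
  intensity_image(matrix(value, n, n), bit_depth = bit_depth,
                  pixel_size = pixel_size, role = role)
}

# A noise-free triplet with a prescribed per-pixel OD matrix.
triplet_from_od <- function(od, imax = 10000, imin = 0, pixel_size = 1) {
  list(
    I = intensity_image(imin + (imax - imin) * 10^(-od),
                        pixel_size = pixel_size, role = "I"),
    Imax = intensity_image(matrix(imax, nrow(od), ncol(od)),
                           pixel_size = pixel_size, role = "Imax"),
    Imin = intensity_image(matrix(imin, nrow(od), ncol(od)),
                           pixel_size = pixel_size, role = "Imin")
  )
}

# Absorbance image with stained disks on a flat background.
disk_field <- function(centers, radius_um, od, shape = c(128, 128),
                       pixel_size = 1, background = 0) {
  m <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    rr <- outer((seq_len(shape[1]) - 0.5) * pixel_size - centers[i, 1],
                rep(1, shape[2]))
    cc <- outer(rep(1, shape[1]),
                (seq_len(shape[2]) - 0.5) * pixel_size - centers[i, 2])
    m[rr^2 + cc^2 <= radius_um^2] <- background + od
  }
  absorbance_image(m, pixel_size = pixel_size)
}

# 13-point dilution series following Beer-Lambert exactly (or with
# multiplicative noise on A).
calibration_series <- function(epsilon = 2555, noise_sd = 0,
                               path_length_m = 0.01) {
  conc <- seq(4.16e-6, 54.12e-6, length.out = 13)   # mol/L
  A <- epsilon * (conc * 1e3) * path_length_m
  if (noise_sd > 0) A <- A * (1 + rnorm(length(A), 0, noise_sd))
  data.frame(concentration_mol_per_L = conc, absorbance = A,
             path_length_m = path_length_m)
}
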