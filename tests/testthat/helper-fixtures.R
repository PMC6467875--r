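# Shared fixture builders: everything generated in code, no stored data.

kB <- bilayerperm::unit_constants()$kB

# free_energy_profile object from an analytic potential (uncensored bins)
analytic_profile <- function(Gfun, h, bin_width = 0.1, temperature = 310) {
  mids <- seq(-h + bin_width / 2, h - bin_width / 2, by = bin_width)
  df <- data.frame(z_nm = mids, G_kcal_mol = Gfun(mids),
                   counts = 1000L, censored = FALSE, stderr = 0)
  attr(df, "temperature") <- temperature
  attr(df, "bin_width") <- bin_width
  attr(df, "h") <- h
  class(df) <- c("free_energy_profile", "data.frame")
  df
}

# canonical particle-table rows for one molecule
particle_rows <- function(id, role, species, frame, time_ps, x, y, z) {
  data.frame(frame = frame, time_ps = time_ps, role = role,
             species = species, molecule_id = id, x_nm = x, y_nm = y,
             z_nm = z, stringsAsFactors = FALSE)
}

# double-peak potential closure matching the generator family
gauss_potential <- function(H, sigma, z_peak, well_depth = 0,
                            well_sigma = 0.5) {
  function(z)
    H * (exp(-(z - z_peak)^2 / (2 * sigma^2)) +
           exp(-(z + z_peak)^2 / (2 * sigma^2))) -
      well_depth * exp(-z^2 / (2 * well_sigma^2))
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}

# inverse-CDF sampler from the Boltzmann density exp(-G/kT) on [-h, h]
sample_boltzmann <- function(Gfun, n, h, temperature) {
  zg <- seq(-h, h, length.out = 20001)
  dens <- exp(-Gfun(zg) / (kB * temperature))
  cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  stats::approx(cdf, zg, xout = stats::runif(n), ties = "ordered")$y
}
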