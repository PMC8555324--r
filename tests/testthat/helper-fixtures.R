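# Shared small fixtures: compact detector and optics so spot tests stay fast.

small_detector <- function() lynx_detector(size_mm = 160, pitch_mm = 1)

small_pattern <- function() spot_pattern(spacing_mm = 45)

small_moments <- function(sigma_iso = 3, theta = 2, corr = -0.25) {
  A <- sigma_iso^2
  C <- theta^2
  m <- optics_moments(A = A, B = corr * sqrt(A * C), C = C)
  my <- m
  my$axis <- "y"
  list(x = m, y = my)
}

simulate_small_planes <- function(energy = 150, perturbation = gantry_perturbation(),
                                  seed = 1, moments = small_moments()) {
  simulate_spot_planes(energy, moments = moments, pattern = small_pattern(),
                       detector = small_detector(),
                       perturbation = perturbation, seed = seed)
}

# Gaussian spot image built directly (independent of simulate_spot_planes)
direct_spot_image <- function(sigma_x, sigma_y = sigma_x, centre = c(0, 0),
                              detector = small_detector(), amp = 1) {
  ax <- (-floor(detector$size_mm / detector$pitch_mm / 2):
           floor(detector$size_mm / detector$pitch_mm / 2)) * detector$pitch_mm
  gx <- exp(-(ax - centre[1])^2 / (2 * sigma_x^2))
  gy <- exp(-(ax - centre[2])^2 / (2 * sigma_y^2))
  dose_plane(amp * outer(gy, gx), detector$pitch_mm)
}
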