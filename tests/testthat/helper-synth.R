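# Shared fixtures, built in code.

# noiseless analytic profiles on a 65 nm grid
noiseless_rp <- function(fov = 4000) render_params(fov = fov, snr = Inf)

make_edge_profile <- function(I_BG = 5, I_AMP = 100, x_c = 1300, sigma = 122,
                              direction = "rising", n_px = 60,
                              pixel_size = 65, noise_sd = 0) {
  x <- (seq_len(n_px) - 0.5) * pixel_size
  y <- erf_edge(x, I_BG, I_AMP, x_c, sigma, direction)
  if (noise_sd > 0) y <- y + rnorm(n_px, 0, noise_sd)
  intensity_profile(x, y, pixel_size)
}

# brute-force quadrature of the exponential-decay x Gaussian convolution
emg_quadrature <- function(x, x_c, sigma, lambda) {
  k <- 1 / lambda
  vapply(x, function(xx) {
    stats::integrate(function(u)
      exp(k * (u - x_c)) * stats::dnorm(xx - u, 0, sigma),
      lower = x_c - 40 * lambda - 10 * sigma, upper = x_c,
      rel.tol = 1e-12, abs.tol = 0)$value
  }, 0)
}

# segments derived from the true phase labels of a telegraph trajectory
true_segments <- function(tr) {
  ph <- tr$phases
  idx <- c(1L, which(ph[-1] != ph[-length(ph)]) + 1L)
  ends <- c(idx[-1] - 1L, length(ph))
  slope <- vapply(seq_along(idx), function(i) {
    if (ends[i] == idx[i]) return(0)
    (tr$observed_lengths[ends[i]] - tr$observed_lengths[idx[i]]) /
      (tr$times[ends[i]] - tr$times[idx[i]])
  }, 0)
  # give zero-length boundary segments the phase-consistent slope sign
  slope[ends == idx & ph[idx] == "growth"] <- 100
  slope[ends == idx & ph[idx] == "shrink"] <- -100
  t_end <- tr$times[ends]
  t_end[length(t_end)] <- max(tr$times)
  t_start <- c(tr$times[1], head(t_end, -1))
  keep <- t_end > t_start
  out <- data.frame(t_start = t_start[keep], t_end = t_end[keep],
                    slope = slope[keep], phase = NA_character_)
  class(out) <- c("phase_segments", class(out))
  out
}
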