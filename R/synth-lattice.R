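# Synthetic microtubule lattices and rendered fluorescence profiles.
#
# The lattice is a 13-protofilament array with 8 nm axial dimer spacing;
# all protofilaments project onto one axial coordinate (the diffraction-
# limited transverse width is unresolved). Dimer k occupies the axial site
# centred at (k - 1/2) * 8 nm, counted from the lattice start at x = 0.

N_PF <- 13L
DIMER_NM <- 8

#' Sample a tip-erosion lattice configuration
#'
#' Draws per-protofilament missing lengths under Model A (all eroded
#' protofilaments shortened by the same `d`) or Model B (missing lengths
#' i.i.d. exponential with mean `d`, truncated at the lattice length), rounds
#' them to the 8 nm dimer grid, and labels each present dimer independently
#' with probability `label_fraction`.
#'
#' @param spec a [taper_model_spec()].
#' @param lattice_length lattice length (nm).
#' @param label_fraction Bernoulli labeling probability per dimer
#'   (default 0.09).
#' @param seed optional integer seed.
#' @return a `lattice_config`: `n_pf`, `dimer_spacing`, `lattice_length`,
#'   `missing_per_pf` (nm, multiples of 8), `labeled_positions` (axial nm).
#' @export
sample_taper_config <- function(spec, lattice_length, label_fraction = 0.09,
                                seed = NULL) {
  stopifnot(inherits(spec, "taper_model_spec"), lattice_length > 0)
  if (spec$model == "A" && spec$d > lattice_length)
    stop("Model A requires lattice_length >= d")
  if (!is.null(seed)) set.seed(seed)
  n_dimers <- floor(lattice_length / DIMER_NM)
  missing_dimers <- integer(N_PF)
  eroded <- if (spec$N > 0) sample.int(N_PF, spec$N) else integer(0)
  if (spec$model == "A") {
    missing_dimers[eroded] <- round(spec$d / DIMER_NM)
  } else {
    raw <- if (spec$d > 0) rexp(length(eroded), rate = 1 / spec$d) else
      numeric(length(eroded))
    raw <- pmin(raw, lattice_length)
    missing_dimers[eroded] <- round(raw / DIMER_NM)
  }
  missing_dimers <- pmin(missing_dimers, n_dimers)
  labeled <- vector("list", N_PF)
  for (p in seq_len(N_PF)) {
    n_present <- n_dimers - missing_dimers[p]
    if (n_present <= 0) { labeled[[p]] <- numeric(0); next }
    lab <- runif(n_present) < label_fraction
    labeled[[p]] <- (which(lab) - 0.5) * DIMER_NM
  }
  structure(list(n_pf = N_PF, dimer_spacing = DIMER_NM,
                 lattice_length = lattice_length,
                 missing_per_pf = missing_dimers * DIMER_NM,
                 labeled_positions = unlist(labeled)),
            class = "lattice_config")
}

#' @export
print.lattice_config <- function(x, ...) {
  cat(sprintf(
    "lattice_config: %d pf x %g nm, %d labeled dimers, missing per pf: %s nm\n",
    x$n_pf, x$lattice_length, length(x$labeled_positions),
    paste(x$missing_per_pf, collapse = "/")))
  invisible(x)
}

#' Render a lattice configuration into a noisy intensity profile
#'
#' Each labeled dimer contributes a unit Gaussian mass of SD `psf_sigma`
#' integrated over each pixel (Gaussian CDF difference across the pixel, not
#' centre-point sampling). Gaussian noise with SD = plateau mean / `snr` is
#' added, where the plateau mean is the average noiseless intensity over
#' pixels at least 4 `psf_sigma` behind the most eroded protofilament tip
#' (and 4 `psf_sigma` inside the lattice start).
#'
#' @param config a `lattice_config` from [sample_taper_config()].
#' @param rp a [render_params()]; `rp$fov` must cover the lattice plus a
#'   4 sigma margin (default does).
#' @param lattice_offset axial position of the lattice start within the
#'   field of view (nm); default 4 `psf_sigma`.
#' @param seed optional integer seed (noise only).
#' @return an [intensity_profile()] with attribute `tip_position` (nominal
#'   full-lattice tip, nm) and `plateau` (noiseless plateau mean).
#' @export
render_profile <- function(config, rp = render_params(), lattice_offset = NULL,
                           seed = NULL) {
  stopifnot(inherits(config, "lattice_config"), inherits(rp, "render_params"))
  if (!is.null(seed)) set.seed(seed)
  margin <- 4 * rp$psf_sigma
  if (is.null(lattice_offset)) lattice_offset <- margin
  fov <- if (is.null(rp$fov)) config$lattice_length + lattice_offset + margin
         else rp$fov
  if (fov < config$lattice_length + lattice_offset + margin - 1e-9)
    stop("fov must cover the lattice plus a 4*psf_sigma margin")
  npx <- floor(fov / rp$pixel_size)
  centers <- (seq_len(npx) - 0.5) * rp$pixel_size
  pos <- config$labeled_positions + lattice_offset
  noiseless <- cpp_render_positions(pos, npx, rp$pixel_size, rp$psf_sigma)
  # plateau: >= 4 sigma behind the most eroded tip and inside the lattice
  most_eroded_tip <- lattice_offset + config$lattice_length -
    max(config$missing_per_pf)
  sel <- centers <= most_eroded_tip - margin &
    centers >= lattice_offset + margin
  plateau <- if (any(sel)) mean(noiseless[sel]) else
    rp$label_fraction * N_PF * rp$pixel_size / DIMER_NM
  intens <- noiseless
  if (is.finite(rp$snr)) intens <- intens + rnorm(npx, 0, plateau / rp$snr)
  out <- intensity_profile(centers, intens, rp$pixel_size)
  attr(out, "tip_position") <- lattice_offset + config$lattice_length
  attr(out, "plateau") <- plateau
  out
}

synth_profile_grid <- function(rp, span = 4000) {
  fov <- if (is.null(rp$fov)) span else rp$fov
  npx <- floor(fov / rp$pixel_size)
  (seq_len(npx) - 0.5) * rp$pixel_size
}

#' Synthesize an EB-comet profile from the analytic EMG model
#'
#' Evaluates [comet_emg()] at pixel centers; optional Gaussian noise with
#' SD = `I_lattice` / `rp$snr` (the lattice plateau sets the SNR scale).
#'
#' @param params named list with `I_BG`, `I_lattice`, `I_EB`, `x_c`, `sigma`,
#'   `lambda` (decay length, nm).
#' @param rp a [render_params()] (pixel size, fov, snr).
#' @param noise add noise? Default `TRUE`.
#' @param seed optional integer seed.
#' @return an [intensity_profile()].
#' @export
synth_comet_profile <- function(params, rp = render_params(), noise = TRUE,
                                seed = NULL) {
  stopifnot(inherits(rp, "render_params"))
  if (!is.null(seed)) set.seed(seed)
  x <- synth_profile_grid(rp)
  y <- comet_emg(x, params$I_BG, params$I_lattice, params$I_EB, params$x_c,
                 params$sigma, params$lambda)
  if (noise && is.finite(rp$snr))
    y <- y + rnorm(length(x), 0, params$I_lattice / rp$snr)
  intensity_profile(x, y, rp$pixel_size)
}

#' Synthesize a step-plus-peak (tip-tracker) profile
#'
#' Evaluates [tog2_step_peak()] at pixel centers; optional Gaussian noise
#' with SD = `I_lattice` / `rp$snr`.
#'
#' @param params named list with `I_BG`, `I_lattice`, `I_peak`, `x_c`,
#'   `x_peak`, `sigma`, and optionally `sigma_psf` (default 97.5 nm).
#' @param rp a [render_params()].
#' @param noise add noise? Default `TRUE`.
#' @param seed optional integer seed.
#' @return an [intensity_profile()].
#' @export
synth_tog2_profile <- function(params, rp = render_params(), noise = TRUE,
                               seed = NULL) {
  stopifnot(inherits(rp, "render_params"))
  if (!is.null(seed)) set.seed(seed)
  sigma_psf <- if (is.null(params$sigma_psf)) 97.5 else params$sigma_psf
  x <- synth_profile_grid(rp)
  y <- tog2_step_peak(x, params$I_BG, params$I_lattice, params$I_peak,
                      params$x_c, params$x_peak, params$sigma, sigma_psf)
  if (noise && is.finite(rp$snr))
    y <- y + rnorm(length(x), 0, params$I_lattice / rp$snr)
  intensity_profile(x, y, rp$pixel_size)
}
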