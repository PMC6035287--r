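# Parameter containers with validation. Units package-wide: nm, s, min^-1
# for frequencies, uM for concentrations.

check_finite <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.null(v) && (!is.numeric(v) || any(!is.finite(v))))
      stop(sprintf("parameter '%s' must be finite numeric", nm), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parameters of a drift-diffusion tip trajectory
#'
#' @param v_g growth speed (nm/s).
#' @param D_p polymerization diffusion coefficient (nm^2/s).
#' @param sigma_err per-frame measurement noise SD (nm).
#' @param dt sampling interval (s); default 0.7 s.
#' @param duration total time (s); default 300 s (5 min).
#' @return a `trajectory_params` list.
#' @export
trajectory_params <- function(v_g, D_p = 0, sigma_err = 0, dt = 0.7,
                              duration = 300) {
  check_finite(v_g = v_g, D_p = D_p, sigma_err = sigma_err, dt = dt,
               duration = duration)
  stopifnot(dt > 0, duration >= dt, D_p >= 0, sigma_err >= 0)
  structure(list(v_g = v_g, D_p = D_p, sigma_err = sigma_err, dt = dt,
                 duration = duration), class = "trajectory_params")
}

#' Parameters of a two-state dynamic-instability (telegraph) process
#'
#' @param v_g growth speed (nm/s).
#' @param v_s shrinkage speed (nm/s, positive).
#' @param f_cat catastrophe frequency (min^-1).
#' @param f_res rescue frequency (min^-1).
#' @param seed_length reflecting floor length (nm): shrinkage stops at the
#'   stable seed.
#' @return an `instability_params` list.
#' @export
instability_params <- function(v_g, v_s, f_cat, f_res, seed_length = 0) {
  check_finite(v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res,
               seed_length = seed_length)
  stopifnot(v_s > 0, f_cat >= 0, f_res >= 0)
  structure(list(v_g = v_g, v_s = v_s, f_cat = f_cat, f_res = f_res,
                 seed_length = seed_length), class = "instability_params")
}

#' Tip-erosion model specification
#'
#' Model A: each of `N` eroded protofilaments is shortened by the same length
#' `d`. Model B: the missing lengths are i.i.d. exponential with mean `d`.
#'
#' @param model `"A"` (sharp) or `"B"` (gradual).
#' @param N number of eroded protofilaments (0..13).
#' @param d characteristic missing length (nm).
#' @return a `taper_model_spec` list.
#' @export
taper_model_spec <- function(model = c("A", "B"), N, d) {
  model <- match.arg(model)
  check_finite(N = N, d = d)
  if (N < 0 || N > 13 || N != round(N)) stop("N must be an integer in 0..13")
  stopifnot(d >= 0)
  structure(list(model = model, N = as.integer(N), d = d),
            class = "taper_model_spec")
}

#' Rendering parameters for synthetic fluorescence profiles
#'
#' Defaults reproduce the imaging conditions the analyses assume: 9% labeled
#' tubulin, a Gaussian PSF of 122 nm SD, 65 nm pixels and signal-to-noise
#' ratio 7 (noise SD = mean plateau intensity / snr).
#'
#' @param label_fraction Bernoulli labeling probability per dimer.
#' @param psf_sigma PSF standard deviation (nm).
#' @param pixel_size image pixel size (nm).
#' @param snr plateau-mean / noise-SD ratio; `Inf` for noiseless.
#' @param fov field of view (nm); `NULL` = chosen from the lattice length
#'   plus a 4*`psf_sigma` margin on each side.
#' @return a `render_params` list.
#' @export
render_params <- function(label_fraction = 0.09, psf_sigma = 122,
                          pixel_size = 65, snr = 7, fov = NULL) {
  check_finite(label_fraction = label_fraction, psf_sigma = psf_sigma,
               pixel_size = pixel_size, fov = fov)
  if (!is.numeric(snr) || is.na(snr) || snr <= 0) stop("snr must be > 0")
  stopifnot(label_fraction >= 0, label_fraction <= 1, psf_sigma > 0,
            pixel_size > 0, is.null(fov) || fov > 0)
  structure(list(label_fraction = label_fraction, psf_sigma = psf_sigma,
                 pixel_size = pixel_size, snr = snr, fov = fov),
            class = "render_params")
}

#' Intensity line profile
#'
#' @param x pixel-center coordinates (nm), equally spaced.
#' @param intensity intensities (arbitrary units).
#' @param pixel_size pixel size (nm).
#' @return an `intensity_profile` object.
#' @export
intensity_profile <- function(x, intensity, pixel_size) {
  stopifnot(length(x) == length(intensity), pixel_size > 0)
  if (length(x) > 1) {
    dx <- diff(x)
    if (max(abs(dx - pixel_size)) > 1e-6 * pixel_size)
      stop("x must be equally spaced at pixel_size")
  }
  structure(list(x = as.numeric(x), intensity = as.numeric(intensity),
                 pixel_size = pixel_size), class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: %d pixels of %g nm, x in [%g, %g] nm\n",
              length(x$x), x$pixel_size, min(x$x), max(x$x)))
  invisible(x)
}
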