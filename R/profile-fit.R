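# Least-squares fits of the convolved intensity models to 1D line profiles.
#
# Every fit returns a classed object with the fitted parameters, the residual
# sum of squares, and an acceptance flag. Flagged fits are reported, never
# silently dropped; the averaging step consumes only accepted fits.

new_fit <- function(cls, pars, rss, flag, flag_reason = NULL, extra = list()) {
  structure(c(pars, list(rss = rss, flagged = flag,
                         flag_reason = flag_reason), extra), class = cls)
}

fit_window <- function(profile, center, halfwidth) {
  if (is.null(halfwidth)) return(seq_along(profile$x))
  which(profile$x >= center - halfwidth & profile$x <= center + halfwidth)
}

guess_edge_center <- function(profile, direction) {
  g <- diff(profile$intensity)
  i <- if (direction == "rising") which.max(g) else which.min(g)
  0.5 * (profile$x[i] + profile$x[i + 1])
}

#' Fit an error-function edge to a tip profile
#'
#' Nonlinear least squares of the [erf_edge()] model (sum of squared
#' deviations), used for sub-pixel localization of the microtubule tip and
#' for measuring the apparent edge width sigma. The linear parameters
#' (`I_BG`, `I_AMP`) are profiled out analytically and (`x_c`, `sigma`) are
#' optimized by a multi-start simplex (starts at the steepest gradient and
#' at the supplied/approximate tip). Fits with non-positive amplitude or
#' sigma pinned at its bounds are flagged.
#'
#' @param profile an [intensity_profile()].
#' @param direction `"falling"` (lattice at low x; default), `"rising"`, or
#'   `"auto"`.
#' @param init optional named list with `x_c` (and optionally `sigma`).
#' @param window halfwidth (nm) of the fit window around the candidate tip
#'   (default 1000 nm, i.e. +/- 1 um); `NULL` fits the whole profile.
#' @param sigma_bounds allowed sigma range (nm).
#' @return a `tip_fit`: `I_BG`, `I_AMP`, `x_c`, `sigma`, `rss`, `direction`,
#'   `flagged`.
#' @export
fit_tip_erf <- function(profile, direction = c("falling", "rising", "auto"),
                        init = NULL, window = 1000,
                        sigma_bounds = c(15, 2000)) {
  stopifnot(inherits(profile, "intensity_profile"))
  direction <- match.arg(direction)
  if (direction == "auto") {
    g <- diff(profile$intensity)
    direction <- if (max(g) >= -min(g)) "rising" else "falling"
  }
  xc0 <- if (!is.null(init$x_c)) init$x_c else
    guess_edge_center(profile, direction)
  s0 <- if (!is.null(init$sigma)) init$sigma else 122
  idx <- fit_window(profile, xc0, window)
  if (length(idx) < 8) stop("fit window contains too few pixels")
  x <- profile$x[idx]; y <- profile$intensity[idx]
  dir <- if (direction == "rising") 1L else -1L
  inits <- unique(c(xc0, guess_edge_center(
    intensity_profile(x, y, profile$pixel_size), direction),
    xc0 + profile$pixel_size))
  f <- cpp_fit_erf(x, y, dir, inits, s0, sigma_bounds[1], sigma_bounds[2])
  flag <- !isTRUE(f$ok)
  new_fit("tip_fit",
          list(I_BG = f$I_BG, I_AMP = f$I_AMP, x_c = f$x_c, sigma = f$sigma),
          f$rss, flag,
          flag_reason = if (flag) "non-convergence, sigma at bounds, or I_AMP <= 0",
          extra = list(direction = direction,
                       pixel_size = profile$pixel_size, n = length(idx)))
}

emg_inits <- function(x, y, pixel_size) {
  ntail <- max(3L, round(length(x) * 0.1))
  I_BG <- mean(tail(y, ntail))
  I_lat <- max(mean(head(y, ntail)) - I_BG, 1e-3)
  # the steepest descent marks the front of the comet / lattice edge;
  # the profile maximum (comet peak) is an alternative start
  g <- diff(y)
  x_c <- 0.5 * (x[which.min(g)] + x[which.min(g) + 1])
  I_EB <- max(max(y) - I_BG - I_lat, 0.1 * I_lat)
  list(I_BG = I_BG, I_lattice = I_lat, I_EB = I_EB, x_c = x_c,
       sigma = 122, lambda = 300, x_max = x[which.max(y)])
}

#' Fit the lattice + exponentially-modified-Gaussian comet model
#'
#' Least-squares fit of [comet_emg()]: an erfc lattice edge plus the
#' PSF-convolved exponential decay of an EB comet. `x_c` is the position of
#' the maximum molecule density (the start of the exponential decay). Fits
#' whose decay length collapses below one pixel are flagged.
#'
#' @param profile an [intensity_profile()].
#' @param init optional named list overriding the data-driven starting
#'   values (`I_BG`, `I_lattice`, `I_EB`, `x_c`, `sigma`, `lambda`).
#' @param window fit-window halfwidth (nm) around the candidate tip;
#'   `NULL` = whole profile.
#' @return a `comet_fit`: `I_BG`, `I_lattice`, `I_EB`, `x_c`, `sigma`,
#'   `lambda`, `rss`, `flagged`.
#' @export
fit_comet_emg <- function(profile, init = NULL, window = 1000) {
  stopifnot(inherits(profile, "intensity_profile"))
  px <- profile$pixel_size
  start <- emg_inits(profile$x, profile$intensity, px)
  x_max <- start$x_max; start$x_max <- NULL
  start[names(init)] <- init
  idx <- fit_window(profile, start$x_c, window)
  if (length(idx) < 10) stop("fit window contains too few pixels")
  x <- profile$x[idx]; y <- profile$intensity[idx]
  lower <- c(I_BG = -Inf, I_lattice = 0, I_EB = 0, x_c = min(x) - 500,
             sigma = 10, lambda = px / 4)
  upper <- c(I_BG = Inf, I_lattice = Inf, I_EB = Inf, x_c = max(x) + 500,
             sigma = 1500, lambda = 5000)
  fits <- list()
  for (st in list(start,
                  modifyList(start, list(x_c = x_max)),
                  modifyList(start, list(lambda = 100)),
                  modifyList(start, list(lambda = 700)))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ comet_emg(x, I_BG, I_lattice, I_EB, x_c, sigma, lambda),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  # nested candidate: no decay component, model reduces to the plain edge.
  # Guards against degenerate data (I_EB ~ 0) where the full model's
  # gradient is singular and the optimizer can wander.
  edge <- tryCatch(fit_tip_erf(profile, "falling",
                               init = list(x_c = start$x_c),
                               window = window),
                   error = function(e) NULL)
  rsses <- vapply(fits, function(f) sum(residuals(f)^2), 0)
  if (!is.null(edge) && !edge$flagged && !is.na(edge$rss) &&
      (!length(fits) || edge$rss <= min(rsses) * (1 + 1e-7))) {
    return(new_fit("comet_fit",
                   list(I_BG = edge$I_BG, I_lattice = edge$I_AMP,
                        I_EB = 0, x_c = edge$x_c, sigma = edge$sigma,
                        lambda = NA_real_),
                   edge$rss, TRUE, "degenerate comet: no decay component",
                   extra = list(pixel_size = px, n = length(idx))))
  }
  if (!length(fits))
    return(new_fit("comet_fit",
                   as.list(setNames(rep(NA_real_, 6), names(start))),
                   NA_real_, TRUE, "non-convergence",
                   extra = list(pixel_size = px, n = length(idx))))
  f <- fits[[which.min(rsses)]]
  p <- as.list(coef(f))
  flag <- p$lambda < px || p$sigma <= lower["sigma"] * 1.05
  new_fit("comet_fit", p, min(rsses), flag,
          flag_reason = if (flag) "decay length below one pixel or sigma at bound",
          extra = list(pixel_size = px, n = length(idx)))
}

#' Fit the step-plus-Gaussian-peak (tip-tracker) model
#'
#' Least-squares fit of [tog2_step_peak()] with the peak width fixed at
#' `sigma_psf`. `x_peak` is the fitted peak position relative to the fitted
#' lattice tip (negative = behind the tip). A fit whose peak amplitude is
#' driven to zero is reported as a flagged "no peak" fit.
#'
#' @param profile an [intensity_profile()].
#' @param sigma_psf fixed PSF standard deviation (nm), default 97.5
#'   (1.5 pixels at 65 nm).
#' @param init optional named list overriding starting values.
#' @param window fit-window halfwidth (nm); `NULL` = whole profile.
#' @param sigma_bounds allowed range for the lattice edge width (nm). The
#'   edge width is the PSF convolved with tip taper, so it cannot fall much
#'   below the PSF SD; the default lower bound 0.8 `sigma_psf` prevents the
#'   near-degenerate "sharp edge + displaced peak" reinterpretation of a
#'   blurred edge.
#' @return a `tog2_fit`: `I_BG`, `I_lattice`, `I_peak`, `x_c`, `x_peak`,
#'   `sigma`, `sigma_psf`, `rss`, `flagged`.
#' @export
fit_tog2_step_peak <- function(profile, sigma_psf = 97.5, init = NULL,
                               window = 1000, sigma_bounds = NULL) {
  if (is.null(sigma_bounds)) sigma_bounds <- c(0.8 * sigma_psf, 600)
  stopifnot(inherits(profile, "intensity_profile"), sigma_psf > 0)
  px <- profile$pixel_size
  # stage 1: plain edge fit for starting values
  edge <- fit_tip_erf(profile, "falling", init = init, window = window)
  xc0 <- if (!is.null(init$x_c)) init$x_c else
    if (!edge$flagged) edge$x_c else guess_edge_center(profile, "falling")
  idx <- fit_window(profile, xc0, window)
  if (length(idx) < 10) stop("fit window contains too few pixels")
  x <- profile$x[idx]; y <- profile$intensity[idx]
  ntail <- max(3L, round(length(x) * 0.1))
  I_BG0 <- if (!edge$flagged) edge$I_BG else mean(tail(y, ntail))
  I_lat0 <- if (!edge$flagged) max(edge$I_AMP, 1e-3) else
    max(mean(head(y, ntail)) - I_BG0, 1e-3)
  resid0 <- y - erf_edge(x, I_BG0, I_lat0, xc0, 122)
  xpk0 <- x[which.max(resid0)] - xc0
  start <- list(I_BG = I_BG0, I_lattice = I_lat0,
                I_peak = max(max(resid0), 0.05 * I_lat0),
                x_c = xc0, x_peak = xpk0, sigma = 122)
  start[names(init)] <- init
  lower <- c(I_BG = -Inf, I_lattice = 0, I_peak = 0, x_c = min(x) - 500,
             x_peak = -1500, sigma = sigma_bounds[1])
  upper <- c(I_BG = Inf, I_lattice = Inf, I_peak = Inf, x_c = max(x) + 500,
             x_peak = 1500, sigma = sigma_bounds[2])
  fits <- list()
  for (st in list(start, modifyList(start, list(x_peak = -100)),
                  modifyList(start, list(x_peak = 0)))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ tog2_step_peak(x, I_BG, I_lattice, I_peak, x_c, x_peak, sigma,
                           sigma_psf),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits))
    return(new_fit("tog2_fit",
                   as.list(setNames(rep(NA_real_, 6), names(start))),
                   NA_real_, TRUE, "non-convergence",
                   extra = list(sigma_psf = sigma_psf, pixel_size = px,
                                n = length(idx))))
  rsses <- vapply(fits, function(f) sum(residuals(f)^2), 0)
  f <- fits[[which.min(rsses)]]
  p <- as.list(coef(f))
  no_peak <- p$I_peak <= 1e-6 * max(p$I_lattice, 1)
  new_fit("tog2_fit", p, min(rsses), no_peak,
          flag_reason = if (no_peak) "no peak (I_peak at zero)",
          extra = list(sigma_psf = sigma_psf, pixel_size = px,
                       n = length(idx)))
}

#' Peak-to-lattice intensity ratio of a step-plus-peak fit
#'
#' Compares the integrated intensity of the point-like accumulation with the
#' lattice intensity per pixel, correcting for the different convolutions of
#' a delta function and a step:
#' \deqn{\mathrm{ratio} = I_{peak}\sqrt{2\pi}\,\sigma_{PSF} / (I_{lattice}\cdot\mathrm{pixel})}
#' With `sigma_psf` in nm and division by the pixel size the ratio is
#' dimensionless; equivalently `sigma_psf` may be given in pixels
#' (`convention = "pixels"`), which yields the same number.
#'
#' @param fit a `tog2_fit` from [fit_tog2_step_peak()].
#' @param pixel_size pixel size (nm); defaults to the fit's.
#' @param convention `"nm"` (divide by pixel size) or `"pixels"`
#'   (sigma already in pixel units).
#' @return the dimensionless ratio; `NA` (with a warning) if
#'   `I_lattice <= 0`.
#' @export
peak_to_lattice_ratio <- function(fit, pixel_size = NULL,
                                  convention = c("nm", "pixels")) {
  stopifnot(inherits(fit, "tog2_fit"))
  convention <- match.arg(convention)
  if (is.null(pixel_size)) pixel_size <- fit$pixel_size
  if (is.na(fit$I_lattice) || fit$I_lattice <= 0) {
    warning("I_lattice <= 0: ratio undefined")
    return(NA_real_)
  }
  s <- if (convention == "nm") fit$sigma_psf / pixel_size else fit$sigma_psf
  fit$I_peak * sqrt(2 * pi) * s / fit$I_lattice
}

#' Per-timepoint Gaussian amplitude series of an EB comet
#'
#' For each kymograph row (time point), fits a Gaussian with background
#' \eqn{I(x) = I_{BG} + I_A e^{-(x - x_c)^2 / 2\sigma^2}} around the tracked
#' comet position and returns the amplitude series, normalized either to the
#' first fitted frame or to the mean over supplied reference frames. Fits
#' with sigma below one pixel or amplitude below twice the residual noise SD
#' are flagged.
#'
#' @param kymograph numeric matrix, rows = time, columns = position.
#' @param pixel_size pixel size (nm).
#' @param dt frame interval (s).
#' @param positions optional per-frame comet position (nm); default tracks
#'   the running intensity maximum.
#' @param roi_halfwidth_px halfwidth of the fit window in pixels (default 3,
#'   i.e. a 6-pixel-wide window plus the center).
#' @param reference_frames frame indices whose mean amplitude normalizes the
#'   series; default `1L` (first frame).
#' @return an `amplitude_series` data frame: `t`, `I_A`, `x_c`, `sigma`,
#'   `normalized`, `flagged`.
#' @export
fit_comet_amplitude_series <- function(kymograph, pixel_size, dt = 1,
                                       positions = NULL, roi_halfwidth_px = 3,
                                       reference_frames = 1L) {
  stopifnot(is.matrix(kymograph), pixel_size > 0, roi_halfwidth_px >= 2)
  nt <- nrow(kymograph); npx <- ncol(kymograph)
  xall <- (seq_len(npx) - 0.5) * pixel_size
  res <- data.frame(t = (seq_len(nt) - 1) * dt, I_A = NA_real_,
                    x_c = NA_real_, sigma = NA_real_, flagged = TRUE)
  prev <- if (!is.null(positions)) positions[1] else
    xall[which.max(kymograph[1, ])]
  hw <- roi_halfwidth_px * pixel_size
  for (i in seq_len(nt)) {
    ctr <- if (!is.null(positions)) positions[i] else prev
    idx <- which(xall >= ctr - 2 * hw & xall <= ctr + 2 * hw)
    if (length(idx) < 5) next
    x <- xall[idx]; y <- kymograph[i, idx]
    st <- list(I_BG = min(y), I_A = max(y) - min(y),
               x_c = x[which.max(y)], sigma = 1.5 * pixel_size)
    f <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(y ~ I_BG + I_A * exp(-(x - x_c)^2 / (2 * sigma^2)),
                        start = st,
                        lower = c(-Inf, 0, min(x), pixel_size / 4),
                        upper = c(Inf, Inf, max(x), 20 * pixel_size),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    p <- as.list(coef(f))
    noise_sd <- sd(residuals(f))
    res$I_A[i] <- p$I_A; res$x_c[i] <- p$x_c; res$sigma[i] <- p$sigma
    res$flagged[i] <- p$sigma < pixel_size || p$I_A < 2 * noise_sd
    if (is.null(positions) && !res$flagged[i]) prev <- p$x_c
  }
  ref <- mean(res$I_A[reference_frames], na.rm = TRUE)
  res$normalized <- res$I_A / ref
  class(res) <- c("amplitude_series", class(res))
  res
}
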