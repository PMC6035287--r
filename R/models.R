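# Analytic intensity models shared by the synthetic generator and the fitters.
# All coordinates are in nm; the microtubule lattice sits at low x and the
# growing plus end at high x, so a tubulin profile is a falling (erfc) edge.

erf_ <- function(z) 2 * pnorm(z * sqrt(2)) - 1
erfc_ <- function(z) 2 * pnorm(-z * sqrt(2))

#' Error-function edge model for a PSF-convolved microtubule tip
#'
#' Intensity of a homogeneously labeled lattice ending at `x_c`, blurred by a
#' Gaussian PSF (possibly broadened further by tip tapering):
#' \deqn{I(x) = I_{BG} + \tfrac12 I_{AMP}\,(1 \pm \mathrm{erf}((x - x_c)/\sqrt{2}\sigma))}
#' The `falling` form (complementary error function) describes a lattice at
#' low x; `rising` is its mirror image.
#'
#' @param x positions (nm).
#' @param I_BG background intensity.
#' @param I_AMP edge amplitude.
#' @param x_c tip position (nm).
#' @param sigma edge standard deviation (nm): PSF blur convolved with taper.
#' @param direction `"falling"` (lattice at low x, default) or `"rising"`.
#' @return numeric vector of intensities.
#' @export
erf_edge <- function(x, I_BG, I_AMP, x_c, sigma, direction = c("falling", "rising")) {
  direction <- match.arg(direction)
  stopifnot(sigma > 0)
  z <- (x - x_c) / (sqrt(2) * sigma)
  if (direction == "falling") I_BG + 0.5 * I_AMP * erfc_(z)
  else I_BG + 0.5 * I_AMP * (1 + erf_(z))
}

#' EB-comet model: erfc lattice plus exponentially modified Gaussian
#'
#' The end-binding protein density is an exponential decay that starts at the
#' tip `x_c` (the position of the maximum molecule density) and decays away
#' from the tip into the lattice, with decay length `lambda`. Convolved with a
#' Gaussian PSF of width `sigma` this is an exponentially modified Gaussian;
#' the lattice-bound fraction contributes a complementary-error-function edge:
#' \deqn{I(x) = I_{BG} + \tfrac12 I_{lattice}\,\mathrm{erfc}\!\left(\frac{x-x_c}{\sqrt2\sigma}\right)
#'  + \tfrac12 I_{EB}\, e^{\frac{\kappa}{2}(\sigma^2\kappa + 2(x-x_c))}\,
#'    \mathrm{erfc}\!\left(\frac{\sigma^2\kappa + x - x_c}{\sqrt2\sigma}\right)}
#' with rate \eqn{\kappa = 1/\lambda}. The EMG term is evaluated in log space
#' (via `pnorm(log.p = TRUE)`) so it neither overflows nor loses precision for
#' extreme \eqn{\lambda/\sigma}.
#'
#' @param x positions (nm).
#' @param I_BG background intensity.
#' @param I_lattice lattice edge amplitude.
#' @param I_EB amplitude of the unconvolved exponential decay.
#' @param x_c position of maximum EB density / lattice edge (nm).
#' @param sigma PSF standard deviation (nm).
#' @param lambda exponential decay length (nm), must be positive.
#' @return numeric vector of intensities.
#' @export
comet_emg <- function(x, I_BG, I_lattice, I_EB, x_c, sigma, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda (decay length) must be > 0")
  stopifnot(sigma > 0)
  k <- 1 / lambda
  u <- x - x_c
  # 0.5*exp(a)*erfc(z/sqrt(2)) = exp(a + pnorm(-z, log.p = TRUE))
  a <- k * u + 0.5 * k^2 * sigma^2
  z <- (k * sigma^2 + u) / sigma
  emg <- exp(a + pnorm(-z, log.p = TRUE))
  I_BG + 0.5 * I_lattice * erfc_(u / (sqrt(2) * sigma)) + I_EB * emg
}

#' Step-plus-peak model for tip-tracker accumulations
#'
#' Sum of a complementary-error-function lattice edge and a Gaussian peak of
#' fixed width `sigma_psf` (a point-like accumulation convolved with the PSF)
#' centred at `x_c + x_peak`; negative `x_peak` places the peak behind the
#' lattice tip:
#' \deqn{I(x) = I_{BG} + \tfrac12 I_{lattice}\,\mathrm{erfc}\!\left(\frac{x-x_c}{\sqrt2\sigma}\right)
#'  + I_{peak}\, e^{-\tfrac12 ((x - x_c - x_{peak})/\sigma_{PSF})^2}}
#'
#' @param x positions (nm).
#' @param I_BG background intensity.
#' @param I_lattice lattice edge amplitude.
#' @param I_peak peak amplitude.
#' @param x_c lattice tip position (nm).
#' @param x_peak peak offset relative to the lattice tip (nm; negative =
#'   behind the tip).
#' @param sigma lattice edge standard deviation (nm).
#' @param sigma_psf PSF standard deviation (nm), fixed (default 97.5 nm =
#'   1.5 pixels at 65 nm/pixel).
#' @return numeric vector of intensities.
#' @export
tog2_step_peak <- function(x, I_BG, I_lattice, I_peak, x_c, x_peak, sigma,
                           sigma_psf = 97.5) {
  stopifnot(sigma > 0, sigma_psf > 0)
  u <- x - x_c
  I_BG + 0.5 * I_lattice * erfc_(u / (sqrt(2) * sigma)) +
    I_peak * exp(-0.5 * ((u - x_peak) / sigma_psf)^2)
}

#' Hill sigmoid for seed-outgrowth probability
#'
#' \deqn{p(c) = p_{max}\, c^h / (c_{50}^h + c^h)}
#'
#' @param c tubulin concentration (uM).
#' @param p_max saturating outgrowth probability.
#' @param c50 concentration of half-maximal outgrowth (uM).
#' @param h Hill slope.
#' @return outgrowth probabilities.
#' @export
hill_sigmoid <- function(c, p_max, c50, h) {
  stopifnot(c50 > 0, h > 0)
  # p_max * c^h / (c50^h + c^h), evaluated as a logistic in log c so that
  # steep slopes do not overflow
  out <- p_max * stats::plogis(h * (log(c) - log(c50)))
  out[c == 0] <- 0
  out
}
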