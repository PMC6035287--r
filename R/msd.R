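# Drift-diffusion analysis of growth variability by ensemble
# mean-squared displacement of length increments.

#' Ensemble MSD of length increments
#'
#' For each delay tau = k dt (k = 1..kmax), averages the squared length
#' increment over all overlapping start points of all trajectories.
#'
#' @param trajs list of `mt_trajectory` objects (equal `dt` assumed).
#' @param tau_max maximal delay (s).
#' @param use `"observed_lengths"` (default) or `"true_lengths"`.
#' @return data frame with `tau`, `msd`, `n_pairs`.
#' @export
ensemble_msd <- function(trajs, tau_max, use = "observed_lengths") {
  stopifnot(length(trajs) > 0)
  dt <- trajs[[1]]$times[2] - trajs[[1]]$times[1]
  kmax <- floor(tau_max / dt)
  stopifnot(kmax >= 3)
  sums <- numeric(kmax); cnts <- numeric(kmax)
  for (tr in trajs) {
    L <- tr[[use]]
    n <- length(L)
    for (k in seq_len(min(kmax, n - 1))) {
      d <- L[(1 + k):n] - L[1:(n - k)]
      sums[k] <- sums[k] + sum(d * d)
      cnts[k] <- cnts[k] + length(d)
    }
  }
  data.frame(tau = seq_len(kmax) * dt, msd = sums / cnts, n_pairs = cnts)
}

#' Fit the drift-diffusion MSD model
#'
#' Fits \deqn{\langle \Delta L^2\rangle(\tau) = v_g^2 \tau^2 + 2 D_p \tau + \sigma_{err}^2}
#' to the ensemble MSD of length increments by least squares. By default
#' generalized least squares weights \eqn{1/(\mathrm{MSD}_k^2\, k)} are used,
#' the standard approximation to the variance of an overlapping-increment
#' MSD estimator; `weights = "none"` gives the unweighted fit. The constant
#' term absorbs the measurement-noise floor (for independent per-frame noise
#' of SD \eqn{\sigma}, the increment floor is \eqn{2\sigma^2}) and is
#' reported as fitted. A negative diffusion coefficient is clamped to zero
#' and flagged.
#'
#' @param trajs list of `mt_trajectory` objects.
#' @param tau_max_fraction delays up to this fraction of the trajectory
#'   duration enter the fit (default 0.25).
#' @param tau_max optional explicit delay cap (s), overrides the fraction.
#' @param weights `"gls"` (default) or `"none"`.
#' @param per_trajectory also fit a per-trajectory D_p with the ensemble
#'   drift speed shared (default `FALSE`).
#' @return an `msd_fit`: `v_g` (nm/s), `D_p` (nm^2/s), `sigma_err_sq`
#'   (nm^2), `tau_max` (s), `rss`, `msd` (the ensemble curve), `flagged`,
#'   optionally `D_p_per_trajectory`.
#' @export
fit_msd <- function(trajs, tau_max_fraction = 0.25, tau_max = NULL,
                    weights = c("gls", "none"), per_trajectory = FALSE) {
  weights <- match.arg(weights)
  if (inherits(trajs, "mt_trajectory")) trajs <- list(trajs)
  duration <- max(trajs[[1]]$times) - min(trajs[[1]]$times)
  if (is.null(tau_max)) tau_max <- tau_max_fraction * duration
  m <- ensemble_msd(trajs, tau_max)
  k <- seq_len(nrow(m))
  w <- if (weights == "gls") 1 / (m$msd^2 * k) else rep(1, nrow(m))
  fit <- lm(msd ~ I(tau^2) + tau, data = m, weights = w)
  cf <- coef(fit)
  a <- cf[["I(tau^2)"]]; b <- cf[["tau"]]; cc <- cf[["(Intercept)"]]
  flagged <- FALSE
  if (a < 0) { a <- 0; flagged <- TRUE }
  D <- b / 2
  if (D < 0) { D <- 0; flagged <- TRUE }
  out <- structure(list(v_g = sqrt(a), D_p = D, sigma_err_sq = cc,
                        tau_max = tau_max, rss = sum(residuals(fit)^2),
                        msd = m, weights = weights, flagged = flagged),
                   class = "msd_fit")
  if (per_trajectory) {
    v2 <- a
    out$D_p_per_trajectory <- vapply(trajs, function(tr) {
      mi <- ensemble_msd(list(tr), tau_max)
      ki <- seq_len(nrow(mi))
      wi <- if (weights == "gls") 1 / (mi$msd^2 * ki) else rep(1, nrow(mi))
      yi <- mi$msd - v2 * mi$tau^2
      cfi <- coef(lm(yi ~ mi$tau, weights = wi))
      max(cfi[2] / 2, 0)
    }, 0)
  }
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf(
    "msd_fit: v_g = %.3g nm/s, D_p = %.4g nm^2/s, const = %.3g nm^2 (tau <= %.3g s%s)\n",
    x$v_g, x$D_p, x$sigma_err_sq, x$tau_max,
    if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(v_g = object$v_g, D_p = object$D_p, sigma_err_sq = object$sigma_err_sq)
}

#' @export
predict.msd_fit <- function(object, tau = object$msd$tau, ...) {
  object$v_g^2 * tau^2 + 2 * object$D_p * tau + object$sigma_err_sq
}

#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(x$msd$tau, x$msd$msd, xlab = "delay tau (s)",
                 ylab = expression(MSD ~ (nm^2)), ...)
  graphics::lines(x$msd$tau, predict(x), col = 2)
  invisible(x)
}
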