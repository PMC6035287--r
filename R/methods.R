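# print / coef / predict methods for the profile-fit classes.

#' @export
print.tip_fit <- function(x, ...) {
  cat(sprintf(
    "tip_fit (%s): x_c = %.1f nm, sigma = %.1f nm, I_AMP = %.3g, I_BG = %.3g, rss = %.3g%s\n",
    x$direction, x$x_c, x$sigma, x$I_AMP, x$I_BG, x$rss,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
coef.tip_fit <- function(object, ...) {
  c(I_BG = object$I_BG, I_AMP = object$I_AMP, x_c = object$x_c,
    sigma = object$sigma)
}

#' @export
predict.tip_fit <- function(object, x, ...) {
  erf_edge(x, object$I_BG, object$I_AMP, object$x_c, object$sigma,
           direction = object$direction)
}

#' @export
print.comet_fit <- function(x, ...) {
  cat(sprintf(
    "comet_fit: x_c = %.1f nm, lambda = %.1f nm, sigma = %.1f nm, I_EB = %.3g, I_lattice = %.3g, rss = %.3g%s\n",
    x$x_c, x$lambda, x$sigma, x$I_EB, x$I_lattice, x$rss,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
coef.comet_fit <- function(object, ...) {
  c(I_BG = object$I_BG, I_lattice = object$I_lattice, I_EB = object$I_EB,
    x_c = object$x_c, sigma = object$sigma, lambda = object$lambda)
}

#' @export
predict.comet_fit <- function(object, x, ...) {
  comet_emg(x, object$I_BG, object$I_lattice, object$I_EB, object$x_c,
            object$sigma, object$lambda)
}

#' @export
print.tog2_fit <- function(x, ...) {
  cat(sprintf(
    "tog2_fit: x_c = %.1f nm, x_peak = %.1f nm, I_peak = %.3g, I_lattice = %.3g, sigma = %.1f nm, rss = %.3g%s\n",
    x$x_c, x$x_peak, x$I_peak, x$I_lattice, x$sigma, x$rss,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
coef.tog2_fit <- function(object, ...) {
  c(I_BG = object$I_BG, I_lattice = object$I_lattice,
    I_peak = object$I_peak, x_c = object$x_c, x_peak = object$x_peak,
    sigma = object$sigma)
}

#' @export
predict.tog2_fit <- function(object, x, ...) {
  tog2_step_peak(x, object$I_BG, object$I_lattice, object$I_peak,
                 object$x_c, object$x_peak, object$sigma, object$sigma_psf)
}
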