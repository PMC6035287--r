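# Hill-sigmoid fit of seed-outgrowth dose-response tables.

#' Fit the Hill sigmoid to an outgrowth table
#'
#' Least-squares fit of [hill_sigmoid()] to outgrowth fractions. Weights are
#' iterated binomial-variance GLS weights \eqn{n_i / (p_i (1 - p_i))} (the
#' efficient least-squares analogue of the binomial likelihood), starting
#' from seed-count weights. `p_max` can be fixed (e.g. at 1) or fitted with
#' an upper bound of 1.
#'
#' @param table an `outgrowth_table` from [simulate_outgrowth()] or a data
#'   frame with `concentration`, `n_seeds`, `n_outgrown`.
#' @param p_max_fixed optional fixed saturating probability; `NULL` (default)
#'   fits it.
#' @param gls_iterations reweighting iterations (default 3).
#' @return a `sigmoid_fit`: `p_max`, `c50`, `h`, standard errors `se`,
#'   covariance `vcov`, `rss`, `fitted`, `table`.
#' @export
fit_outgrowth_sigmoid <- function(table, p_max_fixed = NULL,
                                  gls_iterations = 3) {
  tb <- as.data.frame(table)
  stopifnot(all(c("concentration", "n_seeds", "n_outgrown") %in% names(tb)))
  if (nrow(tb) < 4) stop("need at least 4 concentrations")
  stopifnot(all(tb$n_outgrown >= 0), all(tb$n_outgrown <= tb$n_seeds))
  conc <- tb$concentration
  fr <- tb$n_outgrown / tb$n_seeds
  if (all(fr <= 0) || all(fr >= 1))
    stop("all fractions 0 or all 1: sigmoid parameters not identifiable")
  c50_0 <- conc[which.min(abs(fr - max(fr) / 2))]
  fit_once <- function(w) {
    if (is.null(p_max_fixed)) {
      minpack.lm::nlsLM(
        fr ~ p_max * conc^h / (c50^h + conc^h),
        start = list(p_max = min(max(fr) + 0.05, 1), c50 = c50_0, h = 3),
        lower = c(p_max = 0.01, c50 = 1e-3, h = 0.1),
        upper = c(p_max = 1, c50 = 1e4, h = 100),
        weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      p_max <- p_max_fixed
      minpack.lm::nlsLM(
        fr ~ p_max * conc^h / (c50^h + conc^h),
        start = list(c50 = c50_0, h = 3),
        lower = c(c50 = 1e-3, h = 0.1), upper = c(c50 = 1e4, h = 100),
        weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  f <- fit_once(tb$n_seeds)
  for (i in seq_len(gls_iterations)) {
    p <- pmin(pmax(predict(f), 1e-4), 1 - 1e-4)
    f <- fit_once(tb$n_seeds / (p * (1 - p)))
  }
  cf <- as.list(coef(f))
  if (!is.null(p_max_fixed)) cf$p_max <- p_max_fixed
  V <- tryCatch(vcov(f), error = function(e) NULL)
  se <- if (!is.null(V)) sqrt(diag(V)) else
    setNames(rep(NA_real_, length(coef(f))), names(coef(f)))
  structure(list(p_max = cf$p_max, c50 = cf$c50, h = cf$h,
                 se = se, vcov = V, rss = sum(residuals(f)^2),
                 fitted = predict(f), table = tb),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  se <- function(nm) if (nm %in% names(x$se)) sprintf(" +/- %.3g", x$se[[nm]]) else ""
  cat(sprintf("sigmoid_fit: c50 = %.4g%s uM, h = %.3g%s, p_max = %.3g%s\n",
              x$c50, se("c50"), x$h, se("h"), x$p_max, se("p_max")))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(p_max = object$p_max, c50 = object$c50, h = object$h)
}

#' @export
predict.sigmoid_fit <- function(object, concentration = object$table$concentration, ...) {
  hill_sigmoid(concentration, object$p_max, object$c50, object$h)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  tb <- x$table
  graphics::plot(tb$concentration, tb$n_outgrown / tb$n_seeds, log = "x",
                 xlab = "tubulin (uM)", ylab = "fraction outgrown", ...)
  cs <- exp(seq(log(min(tb$concentration)), log(max(tb$concentration)),
                length.out = 100))
  graphics::lines(cs, predict(x, cs), col = 2)
  invisible(x)
}
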