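# Synthetic tip trajectories: drift-diffusion growth and two-state
# (telegraph) dynamic instability.

new_trajectory <- function(times, true_lengths, observed_lengths,
                           phases = NULL) {
  stopifnot(length(times) == length(true_lengths),
            length(times) == length(observed_lengths),
            all(diff(times) > 0))
  structure(list(times = times, true_lengths = true_lengths,
                 observed_lengths = observed_lengths, phases = phases),
            class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf("mt_trajectory: %d samples, dt = %g s, duration = %g s\n",
              length(x$times), x$times[2] - x$times[1],
              x$times[length(x$times)] - x$times[1]))
  if (!is.null(x$phases))
    cat("  phases:", paste(sprintf("%s=%d", names(table(x$phases)),
                                   as.integer(table(x$phases))),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a drift-diffusion growth trajectory
#'
#' Tip length increments per frame are \eqn{v_g dt + \sqrt{2 D_p dt}\,\xi}
#' with standard normal \eqn{\xi}; independent Gaussian measurement noise of
#' SD `sigma_err` is added to every frame. The observed increment between two
#' frames separated by \eqn{\tau} therefore has variance
#' \eqn{2 D_p \tau + 2\sigma_{err}^2}.
#'
#' @param params a [trajectory_params()] object.
#' @param seed optional integer seed.
#' @return an `mt_trajectory` with `times`, `true_lengths`,
#'   `observed_lengths` (all phases `"growth"`).
#' @export
simulate_length_trajectory <- function(params, seed = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- floor(params$duration / params$dt) + 1L
  times <- (seq_len(n) - 1L) * params$dt
  inc <- params$v_g * params$dt +
    sqrt(2 * params$D_p * params$dt) * rnorm(n - 1L)
  true_lengths <- c(0, cumsum(inc))
  observed <- true_lengths +
    if (params$sigma_err > 0) rnorm(n, 0, params$sigma_err) else 0
  new_trajectory(times, true_lengths, observed,
                 phases = rep("growth", n))
}

#' Simulate a two-state dynamic-instability trajectory
#'
#' Continuous-time telegraph process: growth phases end in catastrophe at
#' rate `f_cat`, shrinkage phases end in rescue at rate `f_res` or by
#' reaching the stable seed (`seed_length`), which reflects the tip back into
#' growth. Lengths are sampled on a regular grid of spacing `dt`.
#'
#' @param params an [instability_params()] object.
#' @param duration total simulated time (s).
#' @param dt sampling interval (s).
#' @param seed optional integer seed.
#' @return an `mt_trajectory` with per-sample `phases` in
#'   `c("growth", "shrink")` and attributes `catastrophe_times`,
#'   `rescue_times` (s; rescues include seed reflections) recording the true
#'   switch times.
#' @export
simulate_dynamic_instability <- function(params, duration, dt, seed = NULL) {
  stopifnot(inherits(params, "instability_params"), duration >= dt, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  rate_cat <- params$f_cat / 60   # s^-1
  rate_res <- params$f_res / 60
  t <- 0; L <- params$seed_length; state <- "growth"
  seg_t0 <- numeric(0); seg_t1 <- numeric(0); seg_L0 <- numeric(0)
  seg_v <- numeric(0); seg_phase <- character(0)
  cat_times <- numeric(0); res_times <- numeric(0)
  while (t < duration) {
    if (state == "growth") {
      dur <- if (rate_cat > 0) rexp(1, rate_cat) else Inf
      t1 <- min(t + dur, duration)
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t1)
      seg_L0 <- c(seg_L0, L); seg_v <- c(seg_v, params$v_g)
      seg_phase <- c(seg_phase, "growth")
      L <- L + params$v_g * (t1 - t)
      if (t1 < duration) cat_times <- c(cat_times, t1)
      t <- t1; state <- "shrink"
    } else {
      t_res <- if (rate_res > 0) rexp(1, rate_res) else Inf
      t_floor <- (L - params$seed_length) / params$v_s
      dur <- min(t_res, t_floor)
      t1 <- min(t + dur, duration)
      seg_t0 <- c(seg_t0, t); seg_t1 <- c(seg_t1, t1)
      seg_L0 <- c(seg_L0, L); seg_v <- c(seg_v, -params$v_s)
      seg_phase <- c(seg_phase, "shrink")
      L <- L - params$v_s * (t1 - t)
      if (t1 < duration) res_times <- c(res_times, t1)
      t <- t1; state <- "growth"
    }
  }
  times <- seq(0, duration, by = dt)
  idx <- findInterval(times, seg_t0, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  lengths <- seg_L0[idx] + seg_v[idx] * (times - seg_t0[idx])
  phases <- seg_phase[idx]
  tr <- new_trajectory(times, lengths, lengths, phases = phases)
  attr(tr, "catastrophe_times") <- cat_times
  attr(tr, "rescue_times") <- res_times
  tr
}

#' Simulate a seed-outgrowth dose-response table
#'
#' For each tubulin concentration, the number of seeds showing outgrowth is
#' Binomial(`n_seeds`, p) with p from the Hill sigmoid [hill_sigmoid()].
#'
#' @param c50 half-maximal concentration (uM).
#' @param h Hill slope.
#' @param p_max saturating probability (0 < p_max <= 1).
#' @param concentrations tubulin concentrations (uM).
#' @param n_seeds integer seed counts per concentration.
#' @param seed optional integer seed.
#' @return an `outgrowth_table` data frame with columns `concentration`,
#'   `n_seeds`, `n_outgrown`, `fraction`.
#' @export
simulate_outgrowth <- function(c50, h, p_max, concentrations, n_seeds,
                               seed = NULL) {
  check_finite(c50 = c50, h = h, p_max = p_max,
               concentrations = concentrations, n_seeds = n_seeds)
  stopifnot(c50 > 0, h > 0, p_max > 0, p_max <= 1,
            length(concentrations) == length(n_seeds), all(n_seeds >= 0))
  if (!is.null(seed)) set.seed(seed)
  p <- hill_sigmoid(concentrations, p_max, c50, h)
  k <- rbinom(length(n_seeds), size = n_seeds, prob = p)
  out <- data.frame(concentration = concentrations,
                    n_seeds = as.integer(n_seeds),
                    n_outgrown = as.integer(k),
                    fraction = k / pmax(n_seeds, 1L))
  class(out) <- c("outgrowth_table", class(out))
  out
}
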