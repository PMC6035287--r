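# Trajectory segmentation, event classification, and frequency estimators
# with ratio-based and Poisson standard errors.

# Piecewise-linear segmentation by penalized least squares: dynamic
# programming over breakpoints with per-segment OLS cost, followed by a
# continuous piecewise-linear refit (hinge basis) at the selected
# breakpoints.

seg_cost_vec <- function(St, Sy, Stt, Sty, Syy, a, b) {
  # SSE of OLS lines on points (a+1)..b for a vector of a values
  n <- b - a
  st <- St[b + 1] - St[a + 1]; sy <- Sy[b + 1] - Sy[a + 1]
  stt <- Stt[b + 1] - Stt[a + 1]; sty <- Sty[b + 1] - Sty[a + 1]
  syy <- Syy[b + 1] - Syy[a + 1]
  ctt <- stt - st^2 / n; cty <- sty - st * sy / n; cyy <- syy - sy^2 / n
  sse <- cyy - ifelse(ctt > 1e-12, cty^2 / ctt, 0)
  pmax(sse, 0)
}

#' Segment a trajectory into phases of constant speed
#'
#' Decomposes a tip trajectory into a piecewise-linear approximation:
#' breakpoints are chosen by exact dynamic programming minimizing
#' SSD + penalty * (number of segments), then a continuous piecewise-linear
#' model is refit at those breakpoints and per-segment slopes extracted.
#'
#' @param traj an `mt_trajectory` (or list with `times`,
#'   `observed_lengths`).
#' @param penalty positive penalty per additional segment; `NULL` (default)
#'   uses a BIC-style `2 * sigma^2 * log(n)` with the noise variance
#'   estimated from second differences.
#' @param min_size minimal samples per segment (default 5).
#' @return a `phase_segments` data frame: `t_start`, `t_end`, `slope`
#'   (nm/s), `phase` (`NA`, filled by [classify_events()]).
#' @export
segment_piecewise_linear <- function(traj, penalty = NULL, min_size = 5L) {
  t <- traj$times; y <- traj$observed_lengths
  n <- length(t)
  if (n < 10) stop("need at least 10 samples")
  if (is.null(penalty)) {
    sig <- mad(diff(y, differences = 2)) / sqrt(6)
    penalty <- max(2 * sig^2 * log(n), 1e-8)
  }
  if (!is.numeric(penalty) || penalty <= 0) stop("penalty must be > 0")
  St <- c(0, cumsum(t)); Sy <- c(0, cumsum(y))
  Stt <- c(0, cumsum(t^2)); Sty <- c(0, cumsum(t * y))
  Syy <- c(0, cumsum(y^2))
  F <- rep(Inf, n + 1); F[1] <- 0
  prev <- integer(n + 1)
  for (b in seq_len(n)) {
    if (b < min_size) next
    a <- 0:(b - min_size)
    a <- a[a == 0 | a >= min_size]      # segments tile: previous end valid
    if (!length(a)) next
    cand <- F[a + 1] + seg_cost_vec(St, Sy, Stt, Sty, Syy, a, b) + penalty
    k <- which.min(cand)
    F[b + 1] <- cand[k]; prev[b + 1] <- a[k]
  }
  # backtrack breakpoints (segment boundaries as sample indices)
  bounds <- integer(0); b <- n
  while (b > 0) { bounds <- c(b, bounds); b <- prev[b + 1] }
  ends <- bounds

  hinge_sse <- function(ends_try) {
    knots <- t[head(ends_try, -1)]
    X <- cbind(1, t, vapply(knots, function(k) pmax(t - k, 0), numeric(n)))
    beta <- qr.solve(qr(X), y)
    list(sse = sum((y - X %*% beta)^2), slopes = cumsum(beta[-1]))
  }
  # refine each interior breakpoint locally under the continuous
  # piecewise-linear model (the DP cost uses per-segment lines, which is
  # slightly less efficient at localizing the kink)
  if (length(ends) > 1) {
    for (pass in 1:2) {
      for (j in seq_len(length(ends) - 1)) {
        lo <- if (j == 1) min_size else ends[j - 1] + 2L
        hi <- ends[j + 1] - 2L
        cand <- max(lo, ends[j] - 4L):min(hi, ends[j] + 4L)
        sses <- vapply(cand, function(e) {
          et <- ends; et[j] <- e; hinge_sse(et)$sse
        }, 0)
        ends[j] <- cand[which.min(sses)]
      }
    }
    fitc <- hinge_sse(ends)
    slopes <- fitc$slopes
  } else {
    slopes <- coef(lm(y ~ t))[2]
  }
  # contiguous segment boundaries at inter-sample midpoints
  mid <- (t[head(ends, -1)] + t[head(ends, -1) + 1L]) / 2
  out <- data.frame(t_start = c(t[1], mid), t_end = c(mid, t[n]),
                    slope = as.numeric(slopes), phase = NA_character_)
  class(out) <- c("phase_segments", class(out))
  out
}

#' Classify phases and count catastrophe / rescue / repair events
#'
#' Segments are labeled growth (slope >= `v_growth_min`), shrinkage
#' (slope <= -`v_shrink_min`), or pause. A catastrophe is a transition from
#' growth or pause into shrinkage; a rescue is a transition from shrinkage
#' into growth or pause. Tip-repair events are episodes with a lagging,
#' catching-up comet and must be supplied as split/merge intervals from a
#' paired track.
#'
#' @param segments a `phase_segments` data frame (slopes in nm/s).
#' @param v_growth_min,v_shrink_min phase thresholds (nm/s); default
#'   8.3 nm/s (~0.5 um/min).
#' @param repair_intervals optional two-column matrix/data frame of
#'   (split, merge) times (s) defining tip-repair events.
#' @return an `event_table` list: counts, `total_growth_time` /
#'   `total_shrink_time` / `total_pause_time` (minutes), per-event records.
#' @export
classify_events <- function(segments, v_growth_min = 8.3, v_shrink_min = 8.3,
                            repair_intervals = NULL) {
  stopifnot(v_growth_min > 0, v_shrink_min > 0)
  seg <- as.data.frame(segments)
  if (any(seg$t_end <= seg$t_start)) stop("segment times must increase")
  if (nrow(seg) > 1 &&
      any(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)]) > 1e-9))
    stop("segments must tile the trajectory without overlap")
  phase <- ifelse(seg$slope >= v_growth_min, "growth",
                  ifelse(seg$slope <= -v_shrink_min, "shrink", "pause"))
  seg$phase <- phase
  dur <- seg$t_end - seg$t_start
  trans_from <- phase[-length(phase)]
  trans_to <- phase[-1]
  trans_t <- seg$t_start[-1]
  is_cat <- trans_from %in% c("growth", "pause") & trans_to == "shrink"
  is_res <- trans_from == "shrink" & trans_to %in% c("growth", "pause")
  shrink_dur <- dur[phase == "shrink"]
  n_rep <- if (is.null(repair_intervals)) 0L else nrow(repair_intervals)
  structure(list(
    segments = seg,
    n_catastrophes = sum(is_cat),
    n_rescues = sum(is_res),
    n_repair_events = n_rep,
    catastrophe_times = trans_t[is_cat],
    rescue_times = trans_t[is_res],
    repair_intervals = repair_intervals,
    total_growth_time = sum(dur[phase == "growth"]) / 60,
    total_shrink_time = sum(dur[phase == "shrink"]) / 60,
    total_pause_time = sum(dur[phase == "pause"]) / 60,
    shrink_durations = shrink_dur / 60), class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf(
    "event_table: %d catastrophes, %d rescues, %d repair events\n",
    x$n_catastrophes, x$n_rescues, x$n_repair_events))
  cat(sprintf("  growth %.2f min, shrink %.2f min, pause %.2f min\n",
              x$total_growth_time, x$total_shrink_time, x$total_pause_time))
  invisible(x)
}

#' Merge event tables from several trajectories
#'
#' Sums counts and phase times across per-trajectory [classify_events()]
#' results so that ensemble frequencies can be estimated.
#'
#' @param tables list of `event_table` objects.
#' @return a pooled `event_table`.
#' @export
pool_events <- function(tables) {
  stopifnot(all(vapply(tables, inherits, TRUE, "event_table")))
  structure(list(
    segments = do.call(rbind, lapply(tables, `[[`, "segments")),
    n_catastrophes = sum(vapply(tables, `[[`, 0L, "n_catastrophes")),
    n_rescues = sum(vapply(tables, `[[`, 0L, "n_rescues")),
    n_repair_events = sum(vapply(tables, `[[`, 0L, "n_repair_events")),
    catastrophe_times = unlist(lapply(tables, `[[`, "catastrophe_times")),
    rescue_times = unlist(lapply(tables, `[[`, "rescue_times")),
    repair_intervals = NULL,
    total_growth_time = sum(vapply(tables, `[[`, 0, "total_growth_time")),
    total_shrink_time = sum(vapply(tables, `[[`, 0, "total_shrink_time")),
    total_pause_time = sum(vapply(tables, `[[`, 0, "total_pause_time")),
    shrink_durations = unlist(lapply(tables, `[[`, "shrink_durations"))),
    class = "event_table")
}

freq_estimate <- function(value, se, n_events, method, flagged = FALSE) {
  structure(list(value = value, se = se, n_events = n_events,
                 method = method, flagged = flagged),
            class = "freq_estimate")
}

#' @export
print.freq_estimate <- function(x, ...) {
  cat(sprintf("%.4g +/- %.3g min^-1 (n = %d, %s%s)\n", x$value, x$se,
              x$n_events, x$method, if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' Catastrophe, rescue, and tip-repair frequencies with standard errors
#'
#' Frequencies are event counts divided by the time spent in the relevant
#' phase (catastrophes and repair events per growth time, rescues per
#' shrinkage time), in events per minute. The catastrophe and repair SE is
#' the frequency divided by the square root of the event count. The rescue
#' SE is ratio-based, propagating the standard error of the mean shortening
#' time (`SE = f * SE_tsh / tbar_sh`); with 10 or fewer rescues the counts
#' are treated as Poisson and `SE = f / sqrt(N_r)` is used instead.
#'
#' @param events an `event_table` (possibly pooled with [pool_events()]).
#' @return list with `f_cat`, `f_res`, `f_repair` as `freq_estimate`
#'   objects; zero observation time yields a flagged `NA` estimate.
#' @export
frequency_estimates <- function(events) {
  stopifnot(inherits(events, "event_table"))
  per_time <- function(n, t) {
    if (t <= 0) return(freq_estimate(NA_real_, NA_real_, n,
                                     "undefined", flagged = TRUE))
    f <- n / t
    se <- if (n > 0) f / sqrt(n) else 0
    freq_estimate(f, se, n, "ratio_se", flagged = n == 0)
  }
  f_cat <- per_time(events$n_catastrophes, events$total_growth_time)
  f_rep <- per_time(events$n_repair_events, events$total_growth_time)
  nr <- events$n_rescues
  if (events$total_shrink_time <= 0) {
    f_res <- freq_estimate(NA_real_, NA_real_, nr, "undefined",
                           flagged = TRUE)
  } else {
    f <- nr / events$total_shrink_time
    if (nr == 0) {
      f_res <- freq_estimate(0, 0, 0L, "poisson_se", flagged = TRUE)
    } else if (nr <= 10) {
      f_res <- freq_estimate(f, f / sqrt(nr), nr, "poisson_se")
    } else {
      tsh <- events$shrink_durations
      se_t <- sd(tsh) / sqrt(length(tsh))
      f_res <- freq_estimate(f, f * se_t / mean(tsh), nr, "ratio_se")
    }
  }
  list(f_cat = f_cat, f_res = f_res, f_repair = f_rep)
}
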