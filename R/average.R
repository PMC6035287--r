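# Tip-aligned profile normalization and two-level averaging on the
# half-pixel (32.5 nm) grid.

new_avg_profile <- function(grid, mean, sem, n_profiles, n_kymographs,
                            coverage = NULL) {
  structure(list(grid = grid, mean = mean, sem = sem,
                 n_profiles = n_profiles, n_kymographs = n_kymographs,
                 coverage = if (is.null(coverage)) !is.na(mean) else coverage),
            class = "avg_profile")
}

#' @export
print.avg_profile <- function(x, ...) {
  cov <- x$coverage
  cat(sprintf(
    "avg_profile: %d grid points (%.1f nm step), covered [%g, %g] nm, %d profiles / %d kymographs\n",
    length(x$grid), if (length(x$grid) > 1) x$grid[2] - x$grid[1] else NA,
    suppressWarnings(min(x$grid[cov])), suppressWarnings(max(x$grid[cov])),
    x$n_profiles, x$n_kymographs))
  invisible(x)
}

#' @export
plot.avg_profile <- function(x, ...) {
  cov <- x$coverage
  graphics::plot(x$grid[cov], x$mean[cov], type = "l",
                 xlab = "position relative to tip (nm)",
                 ylab = "normalized intensity", ...)
  if (!all(is.na(x$sem[cov]))) {
    graphics::lines(x$grid[cov], x$mean[cov] + x$sem[cov], lty = 3)
    graphics::lines(x$grid[cov], x$mean[cov] - x$sem[cov], lty = 3)
  }
  invisible(x)
}

norm_constant <- function(fit, profile, normalize_by) {
  switch(normalize_by,
         I_AMP = fit$I_AMP,
         I_lattice = fit$I_lattice,
         max = max(profile$intensity) - fit$I_BG,
         stop("unknown normalization"))
}

#' Align, normalize, and average profiles on the half-pixel grid
#'
#' Each accepted profile is shifted by a tip position (its own fitted `x_c`
#' or, for two-color data, the partner channel's), background subtracted
#' with its fitted `I_BG`, normalized (`I_AMP`, `I_lattice`, or the profile
#' maximum), and linearly interpolated onto a common grid with half-pixel
#' (default 32.5 nm) spacing. Profiles are first averaged per kymograph,
#' then the mean and SEM are taken across kymographs. No extrapolation is
#' performed: a grid point enters a kymograph average only where all of that
#' kymograph's profiles cover it, and the final average keeps points covered
#' by every kymograph.
#'
#' @param profiles list of [intensity_profile()] objects.
#' @param fits list of accepted fits (`tip_fit`, `comet_fit` or `tog2_fit`),
#'   one per profile, providing `I_BG` and `x_c`.
#' @param kymo_ids vector grouping profiles into kymographs (default: all
#'   one kymograph).
#' @param normalize_by `"I_AMP"`, `"I_lattice"`, or `"max"`.
#' @param shift_by `"own_xc"` or `"partner_xc"` (then supply `partner_xc`).
#' @param partner_xc numeric vector of partner-channel tip positions (nm).
#' @param grid_step grid spacing (nm), default 32.5 (half of a 65 nm pixel).
#' @param drop_flagged drop flagged fits (default `TRUE`); if all fits of a
#'   kymograph are flagged the kymograph is dropped with a warning.
#' @return an `avg_profile` with `grid`, `mean`, `sem`, `n_profiles`,
#'   `n_kymographs`.
#' @export
align_and_average <- function(profiles, fits, kymo_ids = NULL,
                              normalize_by = c("I_AMP", "I_lattice", "max"),
                              shift_by = c("own_xc", "partner_xc"),
                              partner_xc = NULL, grid_step = 32.5,
                              drop_flagged = TRUE) {
  normalize_by <- match.arg(normalize_by)
  shift_by <- match.arg(shift_by)
  stopifnot(length(profiles) == length(fits))
  if (is.null(kymo_ids)) kymo_ids <- rep(1L, length(profiles))
  stopifnot(length(kymo_ids) == length(profiles))
  if (shift_by == "partner_xc") {
    stopifnot(!is.null(partner_xc), length(partner_xc) == length(profiles))
  }
  keep <- if (drop_flagged)
    !vapply(fits, function(f) isTRUE(f$flagged), TRUE)
  else rep(TRUE, length(fits))
  if (!any(keep)) stop("no accepted fits to average")

  shifts <- vapply(seq_along(profiles), function(i) {
    if (shift_by == "own_xc") fits[[i]]$x_c else partner_xc[i]
  }, 0)
  lo <- min(vapply(seq_along(profiles), function(i)
    min(profiles[[i]]$x) - shifts[i], 0)[keep])
  hi <- max(vapply(seq_along(profiles), function(i)
    max(profiles[[i]]$x) - shifts[i], 0)[keep])
  grid <- seq(ceiling(lo / grid_step), floor(hi / grid_step)) * grid_step

  kymo_means <- list()
  n_used <- 0L
  for (kid in unique(kymo_ids[keep])) {
    ii <- which(kymo_ids == kid & keep)
    acc <- matrix(NA_real_, nrow = length(ii), ncol = length(grid))
    for (r in seq_along(ii)) {
      i <- ii[r]
      xs <- profiles[[i]]$x - shifts[i]
      ys <- (profiles[[i]]$intensity - fits[[i]]$I_BG) /
        norm_constant(fits[[i]], profiles[[i]], normalize_by)
      acc[r, ] <- approx(xs, ys, xout = grid, rule = 1)$y
    }
    m <- colMeans(acc)              # NA wherever any profile lacks coverage
    kymo_means[[as.character(kid)]] <- m
    n_used <- n_used + length(ii)
  }
  km <- do.call(rbind, kymo_means)
  cover <- colSums(!is.na(km)) == nrow(km)
  mean_out <- ifelse(cover, colMeans(km), NA_real_)
  sem_out <- rep(NA_real_, length(grid))
  if (nrow(km) > 1)
    sem_out[cover] <- apply(km[, cover, drop = FALSE], 2, sd) / sqrt(nrow(km))
  else sem_out[cover] <- 0
  new_avg_profile(grid, mean_out, sem_out, n_profiles = n_used,
                  n_kymographs = nrow(km), coverage = cover)
}
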