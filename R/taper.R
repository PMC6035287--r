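# Monte-Carlo inference of protofilament tip tapering: simulate averaged
# profiles under erosion Models A/B, compare to a reference averaged
# profile by sum-of-squared differences over the common support, and
# grid-search (N, d) for the minimal residual.

default_taper_grid_d <- function() seq(50, 1500, by = 50)

#' Grid of taper-model parameters
#'
#' @param N_values integers in 0..13 (number of eroded protofilaments).
#' @param d_values characteristic missing lengths (nm).
#' @param iterations Monte-Carlo iterations per grid cell (default 50).
#' @return a `taper_grid` list.
#' @export
taper_grid <- function(N_values = 0:13, d_values = default_taper_grid_d(),
                       iterations = 50) {
  stopifnot(length(N_values) > 0, length(d_values) > 0, iterations >= 1,
            all(N_values == round(N_values)), all(N_values >= 0),
            all(N_values <= 13), all(d_values >= 0),
            !is.unsorted(N_values), !is.unsorted(d_values))
  structure(list(N_values = as.integer(N_values), d_values = d_values,
                 iterations = as.integer(iterations)), class = "taper_grid")
}

default_profile_grid <- function(window = 1000, grid_step = 32.5) {
  seq(-floor(1.3 * window / grid_step), floor(1.3 * window / grid_step)) *
    grid_step
}

#' Simulate the Monte-Carlo averaged profile of a taper model
#'
#' Each iteration renders one noisy profile per entry of `mt_lengths`
#' (lengths resampled with replacement), fits every profile with the same
#' falling-edge error-function fit used for experimental data, shifts it by
#' its fitted tip position, background-subtracts, normalizes by the fitted
#' amplitude, and averages on the half-pixel grid over the pixels covered by
#' all profiles. The returned profile is the mean over iterations (SEM
#' across iterations attached).
#'
#' @param spec a [taper_model_spec()].
#' @param mt_lengths microtubule lengths (nm), as fitted in the experiment.
#' @param rp a [render_params()].
#' @param iterations Monte-Carlo iterations (default 50).
#' @param seed optional integer seed.
#' @param window profile halfwidth (nm) around the tip (default 1000,
#'   matching the +/- 1 um experimental extraction window).
#' @param grid_step averaging grid step (nm), default 32.5.
#' @return an `avg_profile` (grid relative to the fitted tip) with attribute
#'   `n_flagged` counting rejected fits.
#' @export
simulate_averaged_model_profile <- function(spec, mt_lengths,
                                            rp = render_params(),
                                            iterations = 50, seed = NULL,
                                            window = 1000, grid_step = 32.5) {
  stopifnot(inherits(spec, "taper_model_spec"), inherits(rp, "render_params"),
            length(mt_lengths) > 0, all(mt_lengths > 0))
  if (!is.null(seed)) set.seed(seed)
  grid <- default_profile_grid(window, grid_step)
  res <- cpp_sim_avg_profile(as.integer(spec$model == "B"), spec$N, spec$d,
                             as.numeric(mt_lengths), rp$label_fraction,
                             rp$psf_sigma, rp$pixel_size, rp$snr,
                             as.integer(iterations), grid, window)
  out <- new_avg_profile(res$grid, res$mean, res$sem,
                         n_profiles = length(mt_lengths) * iterations,
                         n_kymographs = iterations,
                         coverage = res$coverage)
  attr(out, "n_flagged") <- res$n_flagged
  out
}

#' Sum-of-squared-differences residual between two averaged profiles
#'
#' With `support = "common"` (the default) the SSD runs over the grid
#' points covered by both profiles and is symmetric in its arguments. With
#' `support = "reference"` it runs over all points covered by `ref`, and
#' `sim` must cover every one of them. The grid search uses a rescaled
#' variant (common-support SSD scaled to the reference support size, with
#' a minimum 80% overlap), because raw SSDs computed on supports of
#' different sizes are not comparable across grid cells - a simulation
#' covering only a sliver of the data would otherwise score a spuriously
#' small residual.
#'
#' @param sim,ref `avg_profile` objects on commensurate grids.
#' @param support `"common"` or `"reference"`.
#' @return the SSD residual (scalar).
#' @export
profile_residual <- function(sim, ref, support = c("common", "reference")) {
  stopifnot(inherits(sim, "avg_profile"), inherits(ref, "avg_profile"))
  support <- match.arg(support)
  step <- sim$grid[2] - sim$grid[1]
  if (abs(step - (ref$grid[2] - ref$grid[1])) > 1e-9)
    stop("profiles are on different grid steps")
  ks <- round(sim$grid[sim$coverage] / step)
  kr <- round(ref$grid[ref$coverage] / step)
  if (support == "reference") {
    if (!all(kr %in% ks))
      stop("simulated profile does not cover the reference support")
    common <- kr
  } else {
    common <- intersect(ks, kr)
  }
  if (!length(common)) stop("profiles have no overlapping support")
  is <- match(common, round(sim$grid / step))
  ir <- match(common, round(ref$grid / step))
  sum((sim$mean[is] - ref$mean[ir])^2)
}

cell_seed <- function(master, i) {
  as.integer((as.double(master) * 7919 + i * 104729) %% 2147483647)
}

# Residual used by the grid search: SSD over the common support, rescaled
# to the size of the reference support so that cells whose simulations
# cover slightly different ranges remain comparable. A cell covering less
# than `min_overlap` of the reference support cannot explain the data and
# scores Inf.
cell_residual <- function(sim, ref, min_overlap = 0.8) {
  step <- sim$grid[2] - sim$grid[1]
  ks <- round(sim$grid[sim$coverage] / step)
  kr <- round(ref$grid[ref$coverage] / step)
  common <- intersect(ks, kr)
  if (length(common) < min_overlap * length(kr)) return(Inf)
  is <- match(common, round(sim$grid / step))
  ir <- match(common, round(ref$grid / step))
  sum((sim$mean[is] - ref$mean[ir])^2) * length(kr) / length(common)
}

#' Exhaustive (N, d) residual grid search for one taper model
#'
#' For every grid cell, simulates the Monte-Carlo averaged profile under the
#' model and computes the SSD residual against the reference profile. Each
#' cell uses an RNG stream derived deterministically from the master seed
#' and the cell's (N, d) index, so the surface is reproducible and cells are
#' comparable across grids.
#'
#' @param ref reference `avg_profile` (experimental or synthetic).
#' @param model `"A"` or `"B"`.
#' @param grid a [taper_grid()].
#' @param mt_lengths lengths (nm) used for the simulations.
#' @param rp a [render_params()].
#' @param seed master integer seed.
#' @param window,grid_step passed to [simulate_averaged_model_profile()].
#' @param verbose print progress every N row? Default `FALSE`.
#' @return a `taper_fit`: `model`, `best_N`, `best_d`, `min_residual`,
#'   `residual_surface` (matrix N x d), `n_mts_emulated`, `seed`.
#' @export
grid_search_taper <- function(ref, model = c("A", "B"), grid = taper_grid(),
                              mt_lengths, rp = render_params(), seed = 1,
                              window = 1000, grid_step = 32.5,
                              verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(ref, "avg_profile"), inherits(grid, "taper_grid"))
  surf <- matrix(NA_real_, length(grid$N_values), length(grid$d_values),
                 dimnames = list(N = grid$N_values, d = grid$d_values))
  cell <- 0L
  for (i in seq_along(grid$N_values)) {
    for (j in seq_along(grid$d_values)) {
      cell <- cell + 1L
      set.seed(cell_seed(seed, grid$N_values[i] * 100000 +
                           round(grid$d_values[j])))
      # a cell that cannot produce comparable profiles (all fits rejected,
      # or no support overlap with the reference) cannot describe the
      # data: infinite residual
      surf[i, j] <- tryCatch({
        sim <- simulate_averaged_model_profile(
          taper_model_spec(model, grid$N_values[i], grid$d_values[j]),
          mt_lengths, rp, iterations = grid$iterations, seed = NULL,
          window = window, grid_step = grid_step)
        cell_residual(sim, ref)
      }, error = function(e) Inf)
    }
    if (verbose)
      message(sprintf("N = %d done (min so far %.4g)",
                      grid$N_values[i], min(surf, na.rm = TRUE)))
  }
  k <- arrayInd(which.min(surf), dim(surf))
  structure(list(model = model, best_N = grid$N_values[k[1]],
                 best_d = grid$d_values[k[2]],
                 min_residual = surf[k[1], k[2]],
                 residual_surface = surf,
                 n_mts_emulated = length(mt_lengths), seed = seed),
            class = "taper_fit")
}

#' @export
print.taper_fit <- function(x, ...) {
  cat(sprintf(
    "taper_fit (Model %s): best N = %d, best d = %g nm, min residual = %.4g\n",
    x$model, x$best_N, x$best_d, x$min_residual))
  cat(sprintf("  grid: %d N-values x %d d-values, %d MTs emulated, seed %d\n",
              nrow(x$residual_surface), ncol(x$residual_surface),
              x$n_mts_emulated, x$seed))
  invisible(x)
}

#' Select between taper Models A and B from repeated grid searches
#'
#' Takes the grid-search results of both models (single fits or lists of
#' repeated fits), summarizes the minimal residual per model as mean and SD
#' over repeats, and selects the model with the lower mean. Ties are broken
#' toward Model A (the structurally simpler, sharp-drop model) and flagged.
#'
#' @param resA,resB a `taper_fit` or a list of `taper_fit` objects for
#'   Models A and B respectively (same reference profile).
#' @return a `model_selection` list: `selected`, `tie`, `summary` data frame
#'   with per-model mean/SD of the minimal residual and modal (N, d).
#' @export
compare_models <- function(resA, resB) {
  as_list <- function(r) if (inherits(r, "taper_fit")) list(r) else r
  resA <- as_list(resA); resB <- as_list(resB)
  stopifnot(all(vapply(resA, inherits, TRUE, "taper_fit")),
            all(vapply(resB, inherits, TRUE, "taper_fit")))
  summ <- function(rs, lab) {
    mins <- vapply(rs, function(r) r$min_residual, 0)
    data.frame(model = lab, mean_min_residual = mean(mins),
               sd_min_residual = if (length(mins) > 1) sd(mins) else NA_real_,
               n_repeats = length(mins),
               best_N = round(median(vapply(rs, function(r) r$best_N, 0))),
               best_d = median(vapply(rs, function(r) r$best_d, 0)))
  }
  s <- rbind(summ(resA, "A"), summ(resB, "B"))
  tie <- isTRUE(all.equal(s$mean_min_residual[1], s$mean_min_residual[2]))
  selected <- if (tie) "A" else s$model[which.min(s$mean_min_residual)]
  structure(list(selected = selected, tie = tie, summary = s),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model_selection: Model %s%s\n", x$selected,
              if (x$tie) " (tie, broken toward A)" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
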