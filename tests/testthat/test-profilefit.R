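test_that("erf edge fit recovers noiseless parameters to < 1e-4 relative error", {
  pr <- make_edge_profile(I_BG = 5, I_AMP = 100, x_c = 1300, sigma = 122,
                          direction = "rising")
  f <- fit_tip_erf(pr, "rising", window = NULL)
  expect_false(f$flagged)
  expect_equal(coef(f),
               c(I_BG = 5, I_AMP = 100, x_c = 1300, sigma = 122),
               tolerance = 1e-4)
  # falling orientation and auto-detection
  pf <- make_edge_profile(direction = "falling", x_c = 2000, n_px = 60)
  fa <- fit_tip_erf(pf, "auto")
  expect_identical(fa$direction, "falling")
  expect_equal(fa$x_c, 2000, tolerance = 1e-3)
})

test_that("erf fit agrees with nlsLM as an independent oracle", {
  set.seed(11)
  for (i in 1:10) {
    pr <- make_edge_profile(I_BG = runif(1, 0, 10), I_AMP = runif(1, 50, 150),
                            x_c = runif(1, 1100, 1500),
                            sigma = runif(1, 90, 250),
                            direction = "rising", noise_sd = 3)
    f <- fit_tip_erf(pr, "rising", window = NULL)
    o <- minpack.lm::nlsLM(
      y ~ erf_edge(x, I_BG, I_AMP, x_c, sigma, "rising"),
      data = list(x = pr$x, y = pr$intensity),
      start = list(I_BG = 5, I_AMP = 100, x_c = 1300, sigma = 120),
      lower = c(-Inf, 0, 500, 15), upper = c(Inf, Inf, 3000, 2000))
    expect_equal(f$x_c, coef(o)[["x_c"]], tolerance = 1e-3)
    expect_equal(f$sigma, coef(o)[["sigma"]], tolerance = 1e-3)
    expect_lte(f$rss, sum(residuals(o)^2) * (1 + 1e-6))
  }
})

test_that("fitted sigma on a noiseless fully-labeled blunt tip is the PSF width", {
  cfg <- sample_taper_config(taper_model_spec("A", 0, 0), 2500,
                             label_fraction = 1, seed = 1)
  pr <- render_profile(cfg, render_params(label_fraction = 1, snr = Inf))
  f <- fit_tip_erf(pr, "falling", init = list(x_c = attr(pr, "tip_position")))
  # pixel integration broadens the 122 nm PSF by < 2%
  expect_lt(abs(f$sigma - 122) / 122, 0.02)
})

test_that("sub-pixel tip localization at SNR 7 is unbiased", {
  spec <- taper_model_spec("A", 0, 0)
  rp <- render_params()
  set.seed(12)
  xcs <- vapply(seq_len(300), function(i) {
    cfg <- sample_taper_config(spec, 2500)
    pr <- render_profile(cfg, rp)
    f <- fit_tip_erf(pr, "falling", init = list(x_c = 2988))
    if (f$flagged) NA_real_ else f$x_c
  }, 0)
  xcs <- xcs[!is.na(xcs)]
  # the density edge of the dimer grid sits at 2984 nm absolute
  bias <- mean(xcs) - 2984
  prec <- sd(xcs)
  expect_lt(abs(bias), 3 * prec / sqrt(length(xcs)) + 2)
  expect_lt(prec, 65)   # sub-pixel localization
})

test_that("fits are invariant to intensity offsets and translations", {
  pr <- make_edge_profile(direction = "falling", x_c = 2000, noise_sd = 0)
  f0 <- fit_tip_erf(pr, "falling")
  f1 <- fit_tip_erf(intensity_profile(pr$x, pr$intensity + 37, 65), "falling")
  expect_equal(f1$I_BG, f0$I_BG + 37, tolerance = 1e-6)
  expect_equal(f1$x_c, f0$x_c, tolerance = 1e-6)
  f2 <- fit_tip_erf(intensity_profile(pr$x + 130, pr$intensity, 65), "falling")
  expect_equal(f2$x_c, f0$x_c + 130, tolerance = 1e-6)

  pc <- synth_comet_profile(list(I_BG = 3, I_lattice = 40, I_EB = 120,
                                 x_c = 2000, sigma = 122, lambda = 300),
                            noiseless_rp(), noise = FALSE)
  c0 <- fit_comet_emg(pc)
  c1 <- fit_comet_emg(intensity_profile(pc$x, pc$intensity + 11, 65))
  expect_equal(c1$I_BG, c0$I_BG + 11, tolerance = 1e-4)
  expect_equal(c1$x_c, c0$x_c, tolerance = 1e-3)
})

test_that("EMG comet fit is self-consistent and nests the edge fit", {
  pc <- synth_comet_profile(list(I_BG = 3, I_lattice = 40, I_EB = 120,
                                 x_c = 2000, sigma = 122, lambda = 300),
                            noiseless_rp(), noise = FALSE)
  f <- fit_comet_emg(pc)
  expect_false(f$flagged)
  expect_equal(coef(f)[c("x_c", "sigma", "lambda")],
               c(x_c = 2000, sigma = 122, lambda = 300), tolerance = 1e-4)

  # I_EB = 0: equivalent to the falling erf fit (flagged as degenerate)
  pe <- synth_comet_profile(list(I_BG = 3, I_lattice = 40, I_EB = 0,
                                 x_c = 2000, sigma = 122, lambda = 300),
                            noiseless_rp(), noise = FALSE)
  fe <- fit_comet_emg(pe)
  ft <- fit_tip_erf(pe, "falling")
  expect_equal(fe$x_c, ft$x_c, tolerance = 1e-4)
  expect_equal(fe$sigma, ft$sigma, tolerance = 1e-4)
  expect_lt(abs(fe$I_EB), 1e-3 * 40)
})

test_that("comet parameters are recovered at SNR 7 (500 replicates)", {
  rp <- render_params(fov = 4000)
  set.seed(13)
  pars <- t(vapply(seq_len(500), function(i) {
    pc <- synth_comet_profile(list(I_BG = 3, I_lattice = 40, I_EB = 120,
                                   x_c = 2000, sigma = 122, lambda = 300), rp)
    f <- fit_comet_emg(pc, init = list(x_c = 2000))
    if (f$flagged) return(rep(NA_real_, 4))
    c(f$I_lattice, f$I_EB, f$sigma, f$lambda)
  }, numeric(4)))
  meds <- apply(pars, 2, median, na.rm = TRUE)
  # median fitted decay length within 5% of truth
  expect_lt(abs(meds[4] - 300) / 300, 0.05)
  # median relative error of every parameter below 10%
  rel <- abs(meds / c(40, 120, 122, 300) - 1)
  expect_true(all(rel < 0.10))
})

test_that("step+peak fit recovers the canonical offset and flags no-peak fits", {
  pt <- synth_tog2_profile(list(I_BG = 3, I_lattice = 90, I_peak = 55,
                                x_c = 2000, x_peak = -92.9, sigma = 122),
                           noiseless_rp(), noise = FALSE)
  f <- fit_tog2_step_peak(pt)
  expect_false(f$flagged)
  expect_lt(abs(f$x_peak - (-92.9)), 1)
  expect_lt(abs(f$x_c - 2000), 1)

  p0 <- synth_tog2_profile(list(I_BG = 3, I_lattice = 90, I_peak = 0,
                                x_c = 2000, x_peak = 0, sigma = 122),
                           noiseless_rp(), noise = FALSE)
  f0 <- fit_tog2_step_peak(p0)
  expect_true(f0$flagged)
  expect_match(f0$flag_reason, "no peak")
})

test_that("step+peak fit lands in the same basin as a brute-force grid oracle", {
  rp <- render_params(fov = 4000)
  set.seed(14)
  for (i in 1:5) {
    pt <- synth_tog2_profile(list(I_BG = 5, I_lattice = 100, I_peak = 70,
                                  x_c = 2000, x_peak = -92.9, sigma = 122), rp)
    f <- fit_tog2_step_peak(pt, init = list(x_c = 2000))
    # coarse grid over the nonlinear parameters, linear ones solved exactly
    idx <- which(pt$x >= 1000 & pt$x <= 3000)
    x <- pt$x[idx]; y <- pt$intensity[idx]
    grid <- expand.grid(x_c = seq(1700, 2300, by = 100),
                        x_peak = seq(-400, 200, by = 100),
                        sigma = c(90, 122, 170, 240))
    rss <- vapply(seq_len(nrow(grid)), function(j) {
      b1 <- erf_edge(x, 0, 1, grid$x_c[j], grid$sigma[j], "falling")
      b2 <- exp(-0.5 * ((x - grid$x_c[j] - grid$x_peak[j]) / 97.5)^2)
      sum(residuals(lm(y ~ b1 + b2))^2)
    }, 0)
    k <- which.min(rss)
    # the continuous fit beats every oracle cell and sits within one
    # coarse grid cell of the oracle optimum
    expect_lte(f$rss, rss[k] + 1e-6)
    expect_lte(abs(f$x_c - grid$x_c[k]), 100)
    expect_lte(abs(f$x_peak - grid$x_peak[k]), 100)
  }
})

test_that("peak-to-lattice ratio implements the delta/step convolution correction", {
  pt <- synth_tog2_profile(list(I_BG = 0, I_lattice = 80, I_peak = 40,
                                x_c = 2000, x_peak = -90, sigma = 122),
                           noiseless_rp(), noise = FALSE)
  f <- fit_tog2_step_peak(pt)
  # ratio = (area of peak Gaussian) / (lattice intensity per pixel)
  W <- stats::integrate(function(xx)
    tog2_step_peak(xx, 0, 0, f$I_peak, f$x_c, f$x_peak, f$sigma, 97.5),
    1000, 3000)$value
  expect_equal(peak_to_lattice_ratio(f), W / (f$I_lattice * 65),
               tolerance = 1e-6)
  # no peak -> ratio 0; undefined lattice flagged
  f$I_peak <- 0
  expect_equal(peak_to_lattice_ratio(f), 0)
  f$I_lattice <- 0
  expect_warning(r <- peak_to_lattice_ratio(f), "undefined")
  expect_true(is.na(r))
})

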