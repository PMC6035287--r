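test_that("drift-diffusion trajectories have the stated sampling and moments", {
  # noise-free drift is exactly linear
  tr <- simulate_length_trajectory(
    trajectory_params(v_g = 10, D_p = 0, sigma_err = 0, dt = 0.7,
                      duration = 300), seed = 1)
  expect_length(tr$times, 429)
  expect_equal(tr$observed_lengths, tr$times * 10, tolerance = 1e-10)

  # pure diffusion: Var(dL(tau = 7 s)) = 2 * D * tau
  p <- trajectory_params(v_g = 0, D_p = 500, sigma_err = 0, dt = 0.7,
                         duration = 7)
  set.seed(2)
  dL <- vapply(seq_len(10000), function(i) {
    tr <- simulate_length_trajectory(p)
    tr$observed_lengths[11] - tr$observed_lengths[1]
  }, 0)
  v <- var(dL)
  se_v <- 7000 * sqrt(2 / (length(dL) - 1))
  expect_lt(abs(v - 2 * 500 * 7), 3 * se_v)

  # MSD of observed increments: v^2 tau^2 + 2 D tau + 2 sigma_err^2
  p2 <- trajectory_params(v_g = 25, D_p = 300, sigma_err = 20)
  set.seed(3)
  trajs <- lapply(1:80, function(i) simulate_length_trajectory(p2))
  m <- ensemble_msd(trajs, tau_max = 75)
  ref <- 25^2 * m$tau^2 + 2 * 300 * m$tau + 2 * 20^2
  expect_lt(max(abs(m$msd / ref - 1)[m$tau <= 75]), 0.1)

  # bit reproducibility
  a <- simulate_length_trajectory(p2, seed = 7)
  b <- simulate_length_trajectory(p2, seed = 7)
  expect_identical(a, b)

  expect_error(trajectory_params(v_g = NaN), "finite")
  expect_error(trajectory_params(v_g = 1, dt = 0))
})

test_that("telegraph process obeys its rates and reflecting floor", {
  ip <- instability_params(v_g = 30, v_s = 100, f_cat = 0, f_res = 0)
  tr <- simulate_dynamic_instability(ip, duration = 300, dt = 0.7, seed = 1)
  expect_true(all(tr$phases == "growth"))
  expect_equal(max(tr$true_lengths), 30 * 299.6, tolerance = 1e-6)

  # empirical catastrophe frequency within its 95% CI
  ip2 <- instability_params(v_g = 30, v_s = 60, f_cat = 0.5, f_res = 3,
                            seed_length = 0)
  set.seed(4)
  n_cat <- 0; t_growth <- 0
  for (i in 1:200) {
    tr <- simulate_dynamic_instability(ip2, duration = 600, dt = 0.7)
    n_cat <- n_cat + length(attr(tr, "catastrophe_times"))
    t_growth <- t_growth + sum(tr$phases == "growth") * 0.7 / 60
  }
  f_hat <- n_cat / t_growth
  expect_lt(abs(f_hat - 0.5), 1.96 * f_hat / sqrt(n_cat))

  # mean shrink excursion ~ v_s / rate when the floor is rarely reached
  ip3 <- instability_params(v_g = 50, v_s = 50, f_cat = 6, f_res = 60,
                            seed_length = 0)
  set.seed(5)
  tr <- simulate_dynamic_instability(ip3, duration = 50000, dt = 0.5)
  res <- attr(tr, "rescue_times"); cats <- attr(tr, "catastrophe_times")
  n <- min(length(res), length(cats))
  durs <- res[seq_len(n)] - cats[seq_len(n)]
  expect_lt(abs(mean(durs * 50) - 50 / 1), 3 * sd(durs * 50) / sqrt(n))
})

test_that("taper configurations follow Models A and B on the dimer grid", {
  blunt <- sample_taper_config(taper_model_spec("A", 0, 500), 2400, seed = 1)
  expect_true(all(blunt$missing_per_pf == 0))

  cfgA <- sample_taper_config(taper_model_spec("A", 10, 240), 2400, seed = 2)
  expect_equal(sum(cfgA$missing_per_pf > 0), 10)
  expect_true(all(cfgA$missing_per_pf[cfgA$missing_per_pf > 0] == 240))
  expect_true(all(cfgA$missing_per_pf %% 8 == 0))

  # Model B eroded lengths ~ Exp(mean 400), rounded to the dimer grid
  set.seed(3)
  vals <- unlist(lapply(seq_len(2000), function(i) {
    cfg <- sample_taper_config(taper_model_spec("B", 5, 400), 6000)
    cfg$missing_per_pf[cfg$missing_per_pf > 0]
  }))
  expect_lt(abs(mean(vals) - 400), 3 * sd(vals) / sqrt(length(vals)) + 4)

  expect_error(taper_model_spec("A", 14, 100), "0..13")
  expect_error(sample_taper_config(taper_model_spec("A", 3, 3000), 2400),
               "lattice_length")
  # labeled positions sit on the 8 nm grid inside the lattice
  expect_true(all(cfgA$labeled_positions %% 8 == 4))
  expect_true(all(cfgA$labeled_positions < 2400))
})

test_that("rendered profiles have the expected plateau and ensemble mean", {
  # deterministic full labeling: plateau = 13 * pixel / dimer masses per px
  cfg <- sample_taper_config(taper_model_spec("A", 0, 0), 3000,
                             label_fraction = 1, seed = 1)
  pr <- render_profile(cfg, render_params(label_fraction = 1, snr = Inf))
  expect_equal(attr(pr, "plateau"), 13 * 65 / 8, tolerance = 1e-3)

  # ensemble mean over Bernoulli labeling matches the deterministic
  # PSF-convolved labeled-density profile to < 1% RMS of the plateau
  spec <- taper_model_spec("A", 0, 0)
  rp <- render_params(snr = Inf)
  set.seed(6)
  acc <- NULL
  for (i in 1:500) {
    cfg_i <- sample_taper_config(spec, 2400)
    pr_i <- render_profile(cfg_i, rp)
    acc <- if (is.null(acc)) pr_i$intensity else acc + pr_i$intensity
  }
  mean_prof <- acc / 500
  n_dimers <- floor(2400 / 8)
  sites <- (seq_len(n_dimers) - 0.5) * 8 + 4 * 122  # lattice offset 4 sigma
  oracle <- 0.09 * 13 *
    mtkymo:::cpp_render_positions(sites, length(pr_i$x), 65, 122)
  plateau <- 0.09 * 13 * 65 / 8
  expect_lt(sqrt(mean((mean_prof - oracle)^2)) / plateau, 0.01)

  expect_error(render_profile(cfg, render_params(fov = 1000)), "fov")
})

test_that("synthetic comet and step+peak profiles are exact model evaluations", {
  rp <- noiseless_rp()
  pc <- synth_comet_profile(list(I_BG = 3, I_lattice = 40, I_EB = 120,
                                 x_c = 2000, sigma = 122, lambda = 300),
                            rp, noise = FALSE)
  expect_equal(pc$intensity,
               comet_emg(pc$x, 3, 40, 120, 2000, 122, 300), tolerance = 1e-12)
  pt <- synth_tog2_profile(list(I_BG = 3, I_lattice = 90, I_peak = 55,
                                x_c = 2000, x_peak = -92.9, sigma = 122),
                           rp, noise = FALSE)
  expect_equal(pt$intensity,
               tog2_step_peak(pt$x, 3, 90, 55, 2000, -92.9, 122, 97.5),
               tolerance = 1e-12)
  expect_error(synth_comet_profile(list(I_BG = 0, I_lattice = 1, I_EB = 1,
                                        x_c = 0, sigma = 100, lambda = 0),
                                   rp), "lambda")
})

test_that("outgrowth tables are binomial draws from the Hill sigmoid", {
  conc <- exp(seq(log(1), log(12), length.out = 8))
  ns <- c(92, 96, 105, 82, 97, 87, 161, 127)
  tb <- simulate_outgrowth(7.28, 5.99, 1, conc, ns, seed = 1)
  expect_true(all(tb$n_outgrown >= 0 & tb$n_outgrown <= tb$n_seeds))
  # at c = c50 the expected fraction is 1/2
  set.seed(2)
  k <- replicate(3000, simulate_outgrowth(5, 4, 1, 5, 100)$n_outgrown)
  expect_lt(abs(mean(k) / 100 - 0.5), 3 * 0.05 / sqrt(3000) * 10)
  # near-step behavior for a very steep slope
  tb2 <- simulate_outgrowth(5, 400, 1, c(4.5, 5.5), c(500, 500), seed = 3)
  expect_equal(tb2$n_outgrown[1], 0)
  expect_equal(tb2$n_outgrown[2], 500)
})
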