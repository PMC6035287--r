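test_that("piecewise-linear segmentation recovers slopes and breakpoints", {
  # single straight line: one segment, exact slope
  t <- seq(0, 200, by = 0.7)
  tr <- list(times = t, observed_lengths = 5 + 12 * t)
  seg <- segment_piecewise_linear(tr, penalty = 10)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$slope, 12, tolerance = 1e-8)
  expect_error(segment_piecewise_linear(tr, penalty = -1), "penalty")

  # two-slope trajectory: breakpoint within +/- 2 samples in >= 95% of runs
  dt <- 0.7
  t <- seq(0, 300, by = dt)
  truth <- ifelse(t <= 150, 10 * t, 10 * 150 + 40 * (t - 150))
  set.seed(51)
  hits <- vapply(seq_len(200), function(i) {
    y <- truth + rnorm(length(t), 0, 20)
    seg <- segment_piecewise_linear(list(times = t, observed_lengths = y))
    brk <- seg$t_end[-nrow(seg)]
    any(abs(brk - 150) <= 2 * dt + 1e-9)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("segmentation of telegraph trajectories matches true phases", {
  ip <- instability_params(v_g = 30, v_s = 80, f_cat = 1.5, f_res = 4,
                           seed_length = 0)
  set.seed(52)
  agree <- vapply(seq_len(20), function(i) {
    tr <- simulate_dynamic_instability(ip, duration = 300, dt = 0.7)
    tr$observed_lengths <- tr$true_lengths + rnorm(length(tr$times), 0, 15)
    seg <- segment_piecewise_linear(tr)
    ev <- classify_events(seg)
    # per-sample phase agreement with ground truth
    lab <- vapply(tr$times, function(tt) {
      k <- which(ev$segments$t_start <= tt + 1e-9 &
                   ev$segments$t_end >= tt - 1e-9)[1]
      ev$segments$phase[k]
    }, "")
    mean(lab == tr$phases)
  }, 0)
  expect_gte(mean(agree), 0.9)
})

test_that("event classification counts transitions and phase times", {
  # all-growth trajectory
  seg <- data.frame(t_start = 0, t_end = 600, slope = 30,
                    phase = NA_character_)
  ev <- classify_events(seg)
  expect_equal(ev$n_catastrophes, 0L)
  expect_equal(ev$total_growth_time, 10)

  # alternating growth/shrink segments
  seg2 <- data.frame(t_start = c(0, 100, 160, 400),
                     t_end = c(100, 160, 400, 500),
                     slope = c(30, -80, 30, 2), phase = NA)
  ev2 <- classify_events(seg2)
  expect_equal(ev2$n_catastrophes, 1L)
  expect_equal(ev2$n_rescues, 1L)
  expect_equal(ev2$segments$phase, c("growth", "shrink", "growth", "pause"))
  expect_equal(ev2$total_shrink_time, 1)
  expect_error(classify_events(data.frame(t_start = c(0, 50),
                                          t_end = c(60, 100),
                                          slope = c(1, 2), phase = NA)),
               "tile")

  # noise-free telegraph: recovered counts equal the true transitions
  ip <- instability_params(v_g = 40, v_s = 90, f_cat = 1.2, f_res = 5,
                           seed_length = 0)
  for (s in 1:5) {
    tr <- simulate_dynamic_instability(ip, duration = 400, dt = 0.7, seed = s)
    ev <- classify_events(true_segments(tr))
    # ground truth at sampling resolution: transitions visible in phases
    ph <- tr$phases
    expect_equal(ev$n_catastrophes,
                 sum(ph[-length(ph)] == "growth" & ph[-1] == "shrink"))
    expect_equal(ev$n_rescues,
                 sum(ph[-length(ph)] == "shrink" & ph[-1] == "growth"))
  }
})

test_that("frequency estimators implement the ratio and Poisson error rules", {
  # zero events: zero frequency, flagged
  seg <- data.frame(t_start = 0, t_end = 600, slope = 30, phase = NA)
  fr <- frequency_estimates(classify_events(seg))
  expect_equal(fr$f_cat$value, 0)
  expect_equal(fr$f_cat$se, 0)
  expect_true(fr$f_cat$flagged)
  expect_true(fr$f_res$flagged)

  # nine rescues -> Poisson branch: SE = f / 3
  mins <- 60
  segs <- do.call(rbind, lapply(0:8, function(k) {
    data.frame(t_start = c(0, 100) + 200 * k, t_end = c(100, 200) + 200 * k,
               slope = c(-80, 30), phase = NA)
  }))
  ev <- classify_events(segs)
  expect_equal(ev$n_rescues, 9L)
  fr <- frequency_estimates(ev)
  expect_identical(fr$f_res$method, "poisson_se")
  expect_equal(fr$f_res$se, fr$f_res$value / 3)

  # > 10 rescues -> ratio-based SE from the shortening-time spread
  set.seed(53)
  durs <- rexp(40, 1 / 30)
  segs2 <- do.call(rbind, lapply(seq_along(durs), function(k) {
    t0 <- 200 * (k - 1)
    data.frame(t_start = c(t0, t0 + durs[k]), t_end = c(t0 + durs[k], t0 + 200),
               slope = c(-80, 30), phase = NA)
  }))
  fr2 <- frequency_estimates(classify_events(segs2))
  expect_identical(fr2$f_res$method, "ratio_se")
  tsh <- durs / 60
  expect_equal(fr2$f_res$se,
               fr2$f_res$value * (sd(tsh) / sqrt(40)) / mean(tsh),
               tolerance = 1e-10)
})

test_that("catastrophe-frequency SE is calibrated (coverage 90-98%)", {
  ip <- instability_params(v_g = 30, v_s = 80, f_cat = 0.5, f_res = 6,
                           seed_length = 0)
  set.seed(54)
  cover <- vapply(seq_len(500), function(i) {
    evs <- lapply(seq_len(15), function(j) {
      tr <- simulate_dynamic_instability(ip, duration = 600, dt = 0.7)
      classify_events(true_segments(tr))
    })
    fr <- frequency_estimates(pool_events(evs))$f_cat
    abs(fr$value - 0.5) <= 1.96 * fr$se
  }, TRUE)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})

test_that("MSD fit recovers drift and diffusion", {
  # pure drift, no noise: D = 0 and exact speed
  p <- trajectory_params(v_g = 20, D_p = 0, sigma_err = 0)
  trajs <- lapply(1:3, function(i) simulate_length_trajectory(p, seed = i))
  f <- fit_msd(trajs)
  expect_equal(f$v_g, 20, tolerance = 1e-6)
  expect_equal(f$D_p, 0, tolerance = 1e-6)

  # offset invariance
  shifted <- lapply(trajs, function(tr) {
    tr$observed_lengths <- tr$observed_lengths + 5000
    tr$true_lengths <- tr$true_lengths + 5000
    tr
  })
  f2 <- fit_msd(shifted)
  expect_equal(coef(f2), coef(f), tolerance = 1e-9)

  # full model: parameters within tolerance, curve matches closed form
  p3 <- trajectory_params(v_g = 25, D_p = 316, sigma_err = 20)
  set.seed(55)
  trajs3 <- lapply(1:88, function(i) simulate_length_trajectory(p3))
  f3 <- fit_msd(trajs3, tau_max = 75)
  expect_lt(abs(f3$D_p - 316) / 316, 0.15)
  expect_lt(abs(f3$v_g - 25) / 25, 0.02)
  ref <- 25^2 * f3$msd$tau^2 + 2 * 316 * f3$msd$tau + 2 * 400
  expect_lt(max(abs(f3$msd$msd / ref - 1)), 0.1)
  # fitted constant absorbs the 2 sigma_err^2 increment floor
  expect_lt(abs(f3$sigma_err_sq - 800) / 800, 0.5)

  # per-trajectory diffusion constants spread around the ensemble value
  f4 <- fit_msd(trajs3[1:30], tau_max = 75, per_trajectory = TRUE)
  expect_length(f4$D_p_per_trajectory, 30)
  expect_lt(abs(median(f4$D_p_per_trajectory) - 316) / 316, 0.35)
})

test_that("MSD fit agrees with a coarse grid-search oracle", {
  set.seed(56)
  for (i in 1:5) {
    v <- runif(1, 10, 40); D <- runif(1, 100, 600)
    p <- trajectory_params(v_g = v, D_p = D, sigma_err = 10)
    trajs <- lapply(1:30, function(j) simulate_length_trajectory(p))
    f <- fit_msd(trajs, tau_max = 50)
    m <- f$msd; k <- seq_len(nrow(m)); w <- 1 / (m$msd^2 * k)
    grid <- expand.grid(v = seq(5, 50, by = 0.25), D = seq(50, 800, by = 25))
    sse <- vapply(seq_len(nrow(grid)), function(j) {
      resid <- m$msd - grid$v[j]^2 * m$tau^2 - 2 * grid$D[j] * m$tau
      cc <- sum(w * resid) / sum(w)   # constant profiled out
      sum(w * (resid - cc)^2)
    }, 0)
    kbest <- which.min(sse)
    expect_lte(abs(f$v_g - grid$v[kbest]), 0.25)
    expect_lte(abs(f$D_p - grid$D[kbest]), 25)
  }
})

test_that("Hill sigmoid fit recovers exact and noisy outgrowth data", {
  conc <- exp(seq(log(1), log(12), length.out = 8))
  ns <- c(92, 96, 105, 82, 97, 87, 161, 127)
  # exact data: parameters recovered to < 1e-4
  tb <- data.frame(concentration = conc, n_seeds = 1000,
                   n_outgrown = round(1000 * hill_sigmoid(conc, 1, 7.28, 5.99)))
  f <- fit_outgrowth_sigmoid(tb)
  expect_equal(f$c50, 7.28, tolerance = 2e-3)
  expect_equal(f$h, 5.99, tolerance = 2e-2)
  # fitted curve passes through p_max / 2 at c50
  expect_equal(predict(f, f$c50), f$p_max / 2, tolerance = 1e-8)

  expect_error(fit_outgrowth_sigmoid(
    data.frame(concentration = conc, n_seeds = ns, n_outgrown = 0)),
    "identifiable")

  # binomial replicates: c50 estimator unbiased within 3 SE of its mean
  set.seed(57)
  c50s <- vapply(seq_len(400), function(i) {
    tb <- simulate_outgrowth(7.28, 5.99, 1, conc, ns)
    fit_outgrowth_sigmoid(tb)$c50
  }, 0)
  expect_lt(abs(mean(c50s) - 7.28), 3 * sd(c50s) / sqrt(length(c50s)))
})

test_that("sigmoid fit agrees with a coarse grid-search oracle", {
  conc <- exp(seq(log(1), log(12), length.out = 8))
  ns <- c(92, 96, 105, 82, 97, 87, 161, 127)
  set.seed(58)
  for (i in 1:5) {
    c50 <- runif(1, 3, 9); h <- runif(1, 2, 8)
    tb <- simulate_outgrowth(c50, h, 1, conc, ns)
    f <- fit_outgrowth_sigmoid(tb, p_max_fixed = 1)
    grid <- expand.grid(c50 = seq(1, 11, by = 0.25), h = seq(0.5, 12, by = 0.25))
    fr <- tb$n_outgrown / tb$n_seeds
    sse <- vapply(seq_len(nrow(grid)), function(j) {
      p <- hill_sigmoid(conc, 1, grid$c50[j], grid$h[j])
      pc <- pmin(pmax(p, 1e-4), 1 - 1e-4)
      sum(tb$n_seeds / (pc * (1 - pc)) * (fr - p)^2)
    }, 0)
    kbest <- which.min(sse)
    expect_lte(abs(f$c50 - grid$c50[kbest]), 0.25)
    expect_lte(abs(f$h - grid$h[kbest]), 0.5)
  }
})

test_that("molecule counting normalizes by the single-molecule reference", {
  expect_equal(count_molecules(100, c(90, 110))$counts, 1)
  # mixture of 5-mers with 30% single-molecule CV: histogram mode at 5
  set.seed(59)
  ref <- rnorm(300, 100, 30)
  spots <- rowSums(matrix(rnorm(5 * 400, 100, 30), ncol = 5))
  cm <- count_molecules(spots, ref)
  expect_equal(cm$mode, 4.5, tolerance = 1)   # bin centre containing 5
  expect_lt(abs(mean(cm$counts) - 5), 0.2)
  expect_error(count_molecules(10, c(-5, 5)), "positive")
})
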