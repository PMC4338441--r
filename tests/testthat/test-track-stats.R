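test_that("track velocity is the least-squares slope with exclusion rules", {
  expect_equal(track_velocity(line_track(v = 77)), 77)
  expect_equal(track_velocity(line_track(v = 0)), 0)
  short <- line_track(v = 10, n = 3)
  v <- track_velocity(short)
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "short_track")
  tab <- track_velocities(rbind(line_track(v = 50, id = 1),
                                line_track(v = 10, n = 3, id = 2)))
  expect_equal(tab$included, c(TRUE, FALSE))
})

test_that("censored exponential MLE matches closed forms and the likelihood", {
  expect_equal(fit_exponential(c(1, 2, 3))$mean, 2)
  expect_equal(fit_exponential(c(1, 2, 3), c(FALSE, FALSE, TRUE))$mean, 3)
  expect_error(fit_exponential(c(1, 2), c(TRUE, TRUE)), "censored")
  # closed form maximizes the likelihood (brute-force grid oracle)
  set.seed(10)
  for (rep in 1:5) {
    x <- rexp(40, 1 / 3)
    cen <- x > 4
    x[cen] <- 4
    mle <- fit_exponential(x, cen)$mean
    grid <- seq(0.5 * mle, 2 * mle, length.out = 4001)
    ll <- vapply(grid, cens_exp_loglik, numeric(1), values = x,
                 censored = cen)
    expect_lt(abs(grid[which.max(ll)] - mle) / mle, 1e-3)
  }
})

test_that("MSD of exact trajectories matches closed forms", {
  # pure drift: MSD(tau) = v^2 tau^2 at every lag
  m <- compute_msd(line_track(v = 20, n = 40, dt = 0.5), min_support = 0)
  expect_equal(m$msd_nm2, 400 * m$lag_s^2, tolerance = 1e-10)
  # static + noise: MSD = 2 sigma^2 in expectation
  set.seed(11)
  tracks <- do.call(rbind, lapply(1:200, function(i)
    line_track(v = 0, n = 100, dt = 0.1, id = i, noise_sd = 40)))
  m2 <- compute_msd(tracks)
  expect_lt(abs(mean(m2$msd_nm2) - 2 * 40^2) / (2 * 40^2), 0.05)
  # time-reversal symmetry
  tr <- line_track(v = 15, n = 30, noise_sd = 25)
  rev_tr <- tr
  rev_tr$position_nm <- rev(tr$position_nm)
  expect_equal(compute_msd(tr, min_support = 0),
               compute_msd(rev_tr, min_support = 0))
  # mixed frame intervals are rejected
  bad <- rbind(line_track(v = 1, dt = 1, id = 1),
               line_track(v = 1, dt = 2, id = 2))
  expect_error(compute_msd(bad), "mixed frame intervals")
})

test_that("Brownian ensembles recover D from the linear MSD fit", {
  p <- motion_preset("custom", state = "diffusive", D = 0.02,
                     residence_tau = 2, localization_sd = 0)
  g <- generate_tracks(p, n_tracks = 600, frame_interval = 0.03, seed = 12)
  D <- msd_diffusion_coefficient(compute_msd(g$tracks), n_lags = 4)
  expect_lt(abs(D - 0.02) / 0.02, 0.05)
})

test_that("power-law fit inverts exact data and flags the diffusive regime", {
  lag <- seq(0.1, 2, by = 0.1)
  exact <- data.frame(lag_s = lag, msd_nm2 = 100 * lag^1.5,
                      n_pairs = rep(50, length(lag)))
  f <- fit_power_law(exact)
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$n, 1.5, tolerance = 1e-6)
  expect_true(is.na(f$D_um2_s))  # n outside [0.8, 1.2]
  lin <- data.frame(lag_s = lag, msd_nm2 = 2 * 0.05e6 * lag,
                    n_pairs = rep(50, length(lag)))
  fl <- fit_power_law(lin)
  expect_equal(fl$n, 1, tolerance = 1e-6)
  expect_equal(fl$D_um2_s, 0.05, tolerance = 1e-6)
  expect_error(fit_power_law(exact[1:3, ]), ">= 4")
})

test_that("diffusion table reports states and fold ratios", {
  tab <- diffusion_table(list(apo = list(wt = 0.00045, mutant = 0.01),
                              adp = list(wt = 0.05, mutant = 0.05),
                              amppnp = list(wt = 0.00011)))
  expect_equal(tab$fold_ratio[tab$state == "apo"], 0.01 / 0.00045)
  expect_equal(tab$fold_ratio[tab$state == "adp"], 1)
  expect_true(is.na(tab$fold_ratio[tab$state == "amppnp"]))
})

test_that("bleach step counting handles noiseless and noisy staircases", {
  one <- c(rep(1000, 15), rep(0, 15))
  expect_equal(count_bleach_steps(one)$n_steps, 1)
  two <- c(rep(2000, 10), rep(1000, 10), rep(0, 10))
  f2 <- count_bleach_steps(two)
  expect_equal(f2$n_steps, 2)
  expect_equal(f2$levels, c(2000, 1000, 0))
  flat <- rep(500, 20)
  expect_equal(count_bleach_steps(flat)$n_steps, 0)
  expect_error(count_bleach_steps(c(1, NA, rep(1, 10))), "non-finite")
  # SNR 5: most single-fluorophore traces classified single-step
  g <- generate_intensity_traces(20, 1, bleach_rate = 0.2, noise_sd = 200,
                                 seed = 13)
  ns <- vapply(1:20, function(i) count_bleach_steps(g$traces[i, ])$n_steps,
               numeric(1))
  expect_gte(sum(ns == 1), 17)
})

test_that("constrained mixture fit recovers sizes, weights and scale", {
  set.seed(14)
  sizes <- sample(1:4, 1500, replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05))
  vals <- rnorm(1500, sizes * 1000, sqrt(sizes) * 150)
  fit <- fit_brightness_mixture(vals, K = 4)
  expect_lt(abs(fit$mu1 - 1000) / 1000, 0.05)
  expect_true(all(abs(fit$weights - c(0.55, 0.3, 0.1, 0.05)) < 0.05))
  # scale equivariance
  fit2 <- fit_brightness_mixture(vals * 3, K = 4)
  expect_equal(fit2$mu1 / fit$mu1, 3, tolerance = 1e-3)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-3)
  # size assignment recovers the generating component for clear cases
  expect_equal(assign_size(1000, fit), 1)
  expect_equal(assign_size(4000, fit), 4)
  acc <- mean(assign_size(vals, fit) == sizes)
  expect_gt(acc, 0.8)
  # single-component data -> weight concentrates on k = 1
  vals1 <- rnorm(500, 1000, 100)
  f1 <- fit_brightness_mixture(vals1, K = 4)
  expect_gt(f1$weights[1], 0.95)
})

test_that("track brightness is the mean of the first three frames", {
  tr <- line_track(v = 0, n = 10)
  tr$intensity <- c(900, 1000, 1100, rep(0, 7))
  expect_equal(track_brightness(tr)$brightness, 1000)
})

test_that("dwell times fit a censored exponential", {
  tr3 <- do.call(rbind, lapply(1:3, function(i) {
    d <- line_track(v = 0, n = 7, dt = 0.1, id = i)
    d  # duration 0.6 s each
  }))
  expect_equal(dwell_times(tr3)$mean, 0.6)
  # all-censored selection errors out
  expect_error(dwell_times(tr3, movie_end = 0.65), "censored")
  # adp-like recovery
  g <- generate_tracks("adp", n_tracks = 500, frame_interval = 0.0286,
                       seed = 15)
  fit <- dwell_times(g$tracks)
  expect_lt(abs(fit$mean - 0.6) / 0.6, 0.1)
})
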