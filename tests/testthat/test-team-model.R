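p_legend <- team_params()

test_that("force_velocity follows the linear clamped relation", {
  # unloaded, at stall, half-way (hand-derived), assisting clamp
  expect_equal(force_velocity(0, 50, p_legend), 50)
  expect_equal(force_velocity(-1, 50, p_legend), 0)     # load = F_stall
  expect_equal(force_velocity(-0.5, 50, p_legend), 25)
  expect_equal(force_velocity(-2, 50, p_legend), 0)     # beyond stall
  expect_equal(force_velocity(0.7, 50, p_legend), 50)   # assisting: clamped
  simp <- team_params(force_dependent = FALSE)
  expect_equal(force_velocity(-0.9, 50, simp), 50)
  expect_error(force_velocity(0, -5, p_legend), "nu_i")
})

test_that("unbinding_rate is the capped Bell exponential", {
  expect_equal(unbinding_rate(0, p_legend), 0.08)
  expect_equal(unbinding_rate(100, p_legend), 4)
  # default F_detach puts the cap exactly at stall
  expect_equal(unbinding_rate(p_legend$f_stall, p_legend), 4)
  f <- seq(0, 3, by = 0.1)
  expect_true(all(diff(unbinding_rate(f, p_legend)) >= 0))
  simp <- team_params(force_dependent = FALSE)
  expect_equal(unbinding_rate(c(0, 1, 10), simp), rep(0.08, 3))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(team_params(n_dimers = 0), "n_dimers")
  expect_error(team_params(k_off_max = 0.01), "k_off_max")
  expect_error(team_params(dt = -1), "dt")
  # dt too large for the fastest rate
  expect_error(simulate_run(team_params(dt = 0.1), seed = 1), "dt")
})

test_that("single motor matches the analytic exponential-detachment oracle", {
  # N = 1: no spring force ever, so run time ~ Exp(k_off0):
  # mean run time 1/0.08 = 12.5 s, mean run length 50/0.08 = 625 nm
  runs <- simulate_runs(team_params(), 4000, seed = 101)
  expect_lt(abs(mean(runs$run_time_s) - 12.5) / 12.5, 0.05)
  expect_lt(abs(mean(runs$run_length_nm) - 625) / 625, 0.06)
  # run-time distribution: KS against Exp(0.08) (simplified mode, no
  # rebinding effect at N = 1 anyway)
  ks <- suppressWarnings(ks.test(runs$run_time_s, pexp, rate = 0.08))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero velocity spread with all dimers bound gives exact V", {
  p <- team_params(v_sd = 0, n_dimers = 3)
  r <- simulate_run(p, seed = 5, all_bound = TRUE)
  # springs never stretch: node moves at exactly V until the run ends
  expect_equal(r$velocity_nm_s, 50, tolerance = 1e-9)
  expect_equal(r$run_length_nm, 50 * r$run_time_s, tolerance = 1e-6)
})

test_that("zero stiffness decouples: full model equals simplified model", {
  pf <- team_params(k_stiff = 0, n_dimers = 3)
  ps <- team_params(k_stiff = 0, n_dimers = 3, force_dependent = FALSE)
  rf <- simulate_run(pf, seed = 9)
  rs <- simulate_run(ps, seed = 9)
  expect_equal(rf$trajectory, rs$trajectory, tolerance = 1e-12)
  expect_equal(rf$run_length_nm, rs$run_length_nm)
})

test_that("node force balance holds at every recorded step", {
  r <- simulate_run(team_params(n_dimers = 3), seed = 11,
                    keep_states = TRUE)
  x_node <- r$trajectory$x_node_nm
  for (i in seq_along(x_node)) {
    b <- r$states$bound[i, ]
    if (!any(b)) next
    f <- 0.03 * (x_node[i] - r$states$x[i, b])
    expect_lt(abs(sum(f)), 1e-9 * max(1, max(abs(f))))
  }
})

test_that("node never moves backward between binding-configuration changes", {
  p <- team_params(n_dimers = 3, k_on = 0)  # configs only shrink
  r <- simulate_run(p, seed = 13, all_bound = TRUE)
  tr <- r$trajectory
  same_cfg <- diff(tr$n_bound) == 0
  expect_true(all(diff(tr$x_node_nm)[same_cfg] >= -1e-9))
})

test_that("size sweep reproduces the team-size trends", {
  ss <- size_sweep(team_params(dt = 0.002), sizes = 1:3, n_runs = 250,
                   seed = 21, max_time = 500)
  expect_true(all(abs(ss$mean_velocity - 50) / 50 < 0.1))
  expect_true(all(diff(ss$sd_velocity) < 0))
  expect_true(all(diff(ss$mean_run_length) > 0))
  # reproducibility under a fixed seed
  ss2 <- size_sweep(team_params(dt = 0.002), sizes = 1:3, n_runs = 250,
                    seed = 21, max_time = 500)
  expect_identical(as.data.frame(ss), as.data.frame(ss2))
})

test_that("rebinding disabled reduces N = 1 to the single-run law", {
  p <- team_params(k_on = 0)
  runs <- simulate_runs(p, 3000, seed = 23)
  expect_lt(abs(mean(runs$run_length_nm) - 625) / 625, 0.06)
})

test_that("mean run length grows with k_on (monotone trend)", {
  means <- vapply(c(0, 0.55, 2), function(kon) {
    p <- team_params(k_on = kon, n_dimers = 2, dt = 0.002)
    mean(simulate_runs(p, 400, seed = 29, max_time = 500)$run_length_nm)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("halving dt leaves N = 2 statistics stable (scaled-down check)", {
  # spec-scale is 1e4 runs / 2%; run 2500 at a matching 4% band to stay
  # inside the suite's time budget
  st <- lapply(c(0.002, 0.001), function(dt) {
    p <- team_params(dt = dt, n_dimers = 2)
    r <- simulate_runs(p, 2500, seed = 31, max_time = 1000)
    c(v = mean(r$velocity_nm_s), rl = mean(r$run_length_nm))
  })
  expect_lt(abs(st[[1]]["v"] - st[[2]]["v"]) / st[[2]]["v"], 0.04)
  expect_lt(abs(st[[1]]["rl"] - st[[2]]["rl"]) / st[[2]]["rl"], 0.08)
})

test_that("fit_team_params handles degenerate grids and ranks legend sets", {
  pg <- team_params(dt = 0.002)
  obs <- size_sweep(pg, sizes = 1:2, n_runs = 150, seed = 42,
                    max_time = 300)
  one <- fit_team_params(obs, grid = list(f_stall = 1, k_on = 0.55,
                                          k_off_max = 4),
                         fixed = pg, n_runs = 80, seed = 42,
                         max_time = 300)
  expect_equal(nrow(one$surface), 1L)
  expect_equal(one$best$f_stall, 1)
  # the three published parameter sets give distinct objective values
  legend_sets <- list(c(0.2, 0.57, 3.7), c(1, 0.55, 4), c(4, 0.49, 5.3))
  fits <- fit_team_params(obs, grid = list(
    f_stall = sapply(legend_sets, `[`, 1),
    k_on = sapply(legend_sets, `[`, 2),
    k_off_max = sapply(legend_sets, `[`, 3)),
    fixed = pg, n_runs = 80, seed = 43, max_time = 300)
  on_sets <- apply(fits$surface[, 1:3], 1, function(r)
    any(vapply(legend_sets, function(s) all(abs(s - r) < 1e-9), TRUE)))
  objs <- fits$surface$objective[on_sets]
  expect_equal(length(objs), 3L)
  expect_equal(length(unique(round(objs, 10))), 3L)
})
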