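#' Parameters of the coupled motor-team model
#'
#' Constructs the parameter set of the stochastic team simulator: `n_dimers`
#' motor dimers, each walking toward the microtubule minus end with an
#' intrinsic velocity drawn once per run from Normal(`v_mean`, `v_sd`)
#' truncated at zero, all coupled by equal springs of stiffness `k_stiff`
#' to a shared massless tail node. A bound dimer feels the spring force
#' `f = k_stiff * (x_node - x)`; opposing load slows it linearly to zero at
#' the stall force, and raises its detachment rate exponentially (capped
#' Bell model) from `k_off0` up to `k_off_max`. Unbound dimers rebind at
#' the node position with rate `k_on`.
#'
#' Defaults are the parameter set used for the published size-resolved
#' motility comparison: V = 50 nm/s, sigma_v = 20 nm/s, F_stall = 1 pN,
#' k_on = 0.55 /s, k_off0 = 0.08 /s, k_off_max = 4 /s,
#' k_stiff = 0.03 pN/nm.
#'
#' @param v_mean unloaded velocity mean (nm/s)
#' @param v_sd per-dimer intrinsic velocity SD (nm/s)
#' @param f_stall stall force (pN)
#' @param k_on binding rate of an unbound dimer (1/s)
#' @param k_off0 unloaded unbinding rate (1/s)
#' @param k_off_max saturated unbinding rate under load (1/s)
#' @param k_stiff linker spring stiffness (pN/nm)
#' @param f_detach force scale of the detachment exponential (pN); default
#'   `f_stall / log(k_off_max / k_off0)` so the cap is reached exactly at
#'   stall
#' @param dt integration time step (s)
#' @param force_dependent if `FALSE`, the simplified model: velocities and
#'   unbinding rates ignore spring forces
#' @param n_dimers team size N (>= 1)
#' @return an object of class `team_params`
#' @examples
#' p <- team_params(n_dimers = 2)
#' unbinding_rate(0, p)      # 0.08 /s unloaded
#' unbinding_rate(10, p)     # capped at 4 /s
#' @export
team_params <- function(v_mean = 50, v_sd = 20, f_stall = 1, k_on = 0.55,
                        k_off0 = 0.08, k_off_max = 4, k_stiff = 0.03,
                        f_detach = NULL, dt = 0.001, force_dependent = TRUE,
                        n_dimers = 1L) {
  stop_if_not_scalar_pos(v_mean, "v_mean")
  stop_if_not_scalar_pos(v_sd, "v_sd", strict = FALSE)
  stop_if_not_scalar_pos(f_stall, "f_stall")
  stop_if_not_scalar_pos(k_on, "k_on", strict = FALSE)
  stop_if_not_scalar_pos(k_off0, "k_off0")
  stop_if_not_scalar_pos(k_off_max, "k_off_max")
  stop_if_not_scalar_pos(k_stiff, "k_stiff", strict = FALSE)
  stop_if_not_scalar_pos(dt, "dt")
  if (k_off_max < k_off0) stop("k_off_max must be >= k_off0")
  if (is.null(f_detach)) {
    f_detach <- if (k_off_max > k_off0)
      f_stall / log(k_off_max / k_off0) else Inf
  } else stop_if_not_scalar_pos(f_detach, "f_detach")
  n_dimers <- as.integer(n_dimers)
  if (is.na(n_dimers) || n_dimers < 1L) stop("n_dimers must be >= 1")
  structure(list(v_mean = v_mean, v_sd = v_sd, f_stall = f_stall,
                 k_on = k_on, k_off0 = k_off0, k_off_max = k_off_max,
                 k_stiff = k_stiff, f_detach = f_detach, dt = dt,
                 force_dependent = isTRUE(force_dependent),
                 n_dimers = n_dimers),
            class = "team_params")
}

#' @export
print.team_params <- function(x, ...) {
  cat("Motor-team parameters (", if (x$force_dependent) "full" else
      "simplified, force-independent", " model)\n", sep = "")
  cat(sprintf("  N = %d dimers; V = %g +/- %g nm/s\n", x$n_dimers,
              x$v_mean, x$v_sd))
  cat(sprintf("  F_stall = %g pN; k_on = %g /s; k_off: %g -> %g /s (F_detach = %.3g pN)\n",
              x$f_stall, x$k_on, x$k_off0, x$k_off_max, x$f_detach))
  cat(sprintf("  k_stiff = %g pN/nm; dt = %g s\n", x$k_stiff, x$dt))
  invisible(x)
}

check_dt <- function(params) {
  kmax <- if (params$force_dependent) params$k_off_max else params$k_off0
  pmax_step <- max(params$k_on, kmax) * params$dt
  if (pmax_step >= 0.1)
    stop(sprintf(
      "dt = %g too large: per-step event probability %.3g >= 0.1; reduce dt",
      params$dt, pmax_step))
  invisible(TRUE)
}

#' Force-velocity relation of a single dimer
#'
#' Linear load dependence: an opposing load L slows the dimer to
#' `nu_i * (1 - L / F_stall)`, clamped to `[0, nu_i]`; assisting force never
#' speeds it beyond its intrinsic velocity and there is no backward
#' stepping. Only the opposing component of the signed spring force acts as
#' load (`L = max(0, -f_load)` with positive displacement toward the minus
#' end). In the simplified model the intrinsic velocity is returned
#' unconditionally.
#'
#' @param f_load signed spring force on the dimer (pN)
#' @param nu_i intrinsic (unloaded) velocity of the dimer (nm/s), >= 0
#' @param params a [team_params()] object
#' @return velocity in nm/s (vectorised over `f_load` and `nu_i`)
#' @export
force_velocity <- function(f_load, nu_i, params) {
  stopifnot(inherits(params, "team_params"))
  if (any(!is.finite(f_load)) || any(!is.finite(nu_i)))
    stop("non-finite inputs")
  if (any(nu_i < 0)) stop("nu_i must be >= 0 (velocities are truncated draws)")
  if (!params$force_dependent) return(rep_len(nu_i, max(length(f_load), length(nu_i))))
  load <- pmax(0, -f_load)
  pmin(pmax(nu_i * (1 - load / params$f_stall), 0), nu_i)
}

#' Force-dependent unbinding rate
#'
#' Capped Bell model: `min(k_off0 * exp(f / F_detach), k_off_max)`. With the
#' default `F_detach = F_stall / log(k_off_max / k_off0)` the cap is reached
#' exactly at the stall force. The simplified model returns `k_off0` for any
#' force.
#'
#' @param f_mag magnitude of the spring force (pN), >= 0
#' @param params a [team_params()] object
#' @return detachment rate in 1/s (vectorised)
#' @export
unbinding_rate <- function(f_mag, params) {
  stopifnot(inherits(params, "team_params"))
  if (any(f_mag < 0)) stop("f_mag must be >= 0")
  if (!params$force_dependent) return(rep_len(params$k_off0, length(f_mag)))
  pmin(params$k_off0 * exp(f_mag / params$f_detach), params$k_off_max)
}

#' Simulate a single run of a motor team
#'
#' Fixed-step scheme: one dimer starts bound at x = 0 with a relaxed spring
#' (all bound if `all_bound`), the others unbound. Each step the node is
#' placed at the mean of bound head positions, spring forces are computed,
#' bound heads advance by [force_velocity()] * dt, then unbind with
#' probability [unbinding_rate()] * dt, and unbound heads rebind at the node
#' with probability `k_on * dt`. The run ends when no dimer is bound (or at
#' `max_time`, flagged as censored).
#'
#' @param params a [team_params()] object
#' @param seed integer fixing all randomness; `NULL` uses the session RNG
#' @param record_stride record the node trajectory every this many steps
#' @param max_time hard cap on simulated time (s)
#' @param all_bound start with every dimer engaged
#' @param keep_states also record per-dimer positions and bound flags at
#'   every recorded time (for diagnostics / invariant checks)
#' @return an object of class `team_run`: list with `trajectory`
#'   (data.frame time_s, x_node_nm, n_bound), `run_length_nm`, `run_time_s`,
#'   `velocity_nm_s` (least-squares slope over the whole run), `censored`,
#'   and optionally `states`
#' @examples
#' r <- simulate_run(team_params(n_dimers = 3), seed = 1)
#' r$run_length_nm
#' @export
simulate_run <- function(params, seed = NULL, record_stride = 1L,
                         max_time = 2000, all_bound = FALSE,
                         keep_states = FALSE) {
  stopifnot(inherits(params, "team_params"))
  check_dt(params)
  stop_if_not_scalar_pos(max_time, "max_time")
  record_stride <- max(1L, as.integer(record_stride))
  res <- with_seed(seed, simulate_run_cpp(
    params$n_dimers, params$v_mean, params$v_sd, params$f_stall, params$k_on,
    params$k_off0, params$k_off_max, params$k_stiff,
    min(params$f_detach, 1e300), params$dt, params$force_dependent,
    all_bound, max_time, record_stride, keep_states))
  out <- list(
    trajectory = data.frame(time_s = res$time_s, x_node_nm = res$x_node_nm,
                            n_bound = res$n_bound),
    run_length_nm = res$run_length_nm, run_time_s = res$run_time_s,
    velocity_nm_s = res$velocity_nm_s, censored = res$censored,
    params = params)
  if (keep_states) {
    n <- params$n_dimers
    out$states <- list(
      x = matrix(res$state_x, ncol = n, byrow = TRUE),
      bound = matrix(res$state_bound, ncol = n, byrow = TRUE) == 1L)
  }
  class(out) <- "team_run"
  out
}

#' @export
print.team_run <- function(x, ...) {
  cat(sprintf(
    "Team run (N = %d): %.0f nm in %.1f s (%.1f nm/s)%s\n",
    x$params$n_dimers, x$run_length_nm, x$run_time_s, x$velocity_nm_s,
    if (x$censored) " [censored at max_time]" else ""))
  invisible(x)
}

#' Simulate many runs and return per-run summaries
#'
#' Fast path without trajectory recording; used by [size_sweep()] and
#' [fit_team_params()].
#'
#' @inheritParams simulate_run
#' @param n_runs number of independent runs
#' @return data.frame with `run_length_nm`, `run_time_s`, `velocity_nm_s`,
#'   `censored`, one row per run
#' @export
simulate_runs <- function(params, n_runs, seed = NULL, max_time = 2000,
                          all_bound = FALSE) {
  stopifnot(inherits(params, "team_params"))
  check_dt(params)
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1L) stop("n_runs must be >= 1")
  with_seed(seed, simulate_runs_cpp(
    n_runs, params$n_dimers, params$v_mean, params$v_sd, params$f_stall,
    params$k_on, params$k_off0, params$k_off_max, params$k_stiff,
    min(params$f_detach, 1e300), params$dt, params$force_dependent,
    all_bound, max_time))
}

#' Size-resolved motility statistics of the team model
#'
#' Runs `n_runs` simulations per team size and summarises mean and SD of
#' run velocity and run length, mirroring size-resolved single-molecule
#' motility tables.
#'
#' @inheritParams simulate_runs
#' @param sizes integer vector of team sizes N
#' @return data.frame of class `size_stats`: `n_dimers`, `mean_velocity`,
#'   `sd_velocity`, `mean_run_length`, `sd_run_length`, `n_runs`
#' @examples
#' \donttest{
#' size_sweep(team_params(), sizes = 1:4, n_runs = 200, seed = 7)
#' }
#' @export
size_sweep <- function(params, sizes, n_runs = 500, seed = NULL,
                       max_time = 2000) {
  stopifnot(inherits(params, "team_params"))
  if (length(sizes) == 0) stop("`sizes` must be non-empty")
  sizes <- as.integer(sizes)
  if (any(is.na(sizes) | sizes < 1L)) stop("sizes must be integers >= 1")
  run_one_size <- function(n) {
    p <- params
    p$n_dimers <- n
    runs <- simulate_runs(p, n_runs, seed = NULL, max_time = max_time)
    data.frame(n_dimers = n,
               mean_velocity = mean(runs$velocity_nm_s),
               sd_velocity = sd(runs$velocity_nm_s),
               mean_run_length = mean(runs$run_length_nm),
               sd_run_length = sd(runs$run_length_nm),
               n_runs = n_runs)
  }
  out <- with_seed(seed, do.call(rbind, lapply(sizes, run_one_size)))
  class(out) <- c("size_stats", "data.frame")
  out
}

#' Fit team-model parameters to size-resolved motility data
#'
#' Grid search over (`f_stall`, `k_on`, `k_off_max`). For each grid point
#' the model is simulated at the observed team sizes (with common random
#' numbers: the same seed at every grid point) and compared to the observed
#' table through the relative squared-error objective
#' `sum over sizes and over {mean, SD} x {velocity, run length} of
#' ((sim - obs) / obs)^2` (observed zeros guarded by machine epsilon).
#'
#' @param observed a `size_stats` data.frame (>= 2 sizes) with columns
#'   `n_dimers`, `mean_velocity`, `sd_velocity`, `mean_run_length`,
#'   `sd_run_length`
#' @param grid named list with numeric vectors `f_stall`, `k_on`,
#'   `k_off_max` defining the search grid
#' @param fixed a [team_params()] object providing all remaining parameters
#' @param n_runs simulated runs per size per grid point
#' @param seed seed reused at every grid point (common random numbers)
#' @param max_time per-run time cap (s)
#' @return list with `best` (a [team_params()] object at the optimum),
#'   `best_objective`, and `surface` (data.frame of the full objective
#'   surface)
#' @export
fit_team_params <- function(observed, grid, fixed = team_params(),
                            n_runs = 200, seed = 1, max_time = 2000) {
  req <- c("n_dimers", "mean_velocity", "sd_velocity", "mean_run_length",
           "sd_run_length")
  if (!all(req %in% names(observed)))
    stop("observed must have columns: ", paste(req, collapse = ", "))
  if (nrow(observed) < 2) stop("observed must contain >= 2 team sizes")
  if (!all(c("f_stall", "k_on", "k_off_max") %in% names(grid)) ||
      any(lengths(grid[c("f_stall", "k_on", "k_off_max")]) == 0))
    stop("grid must be a list with non-empty f_stall, k_on, k_off_max")
  pts <- expand.grid(f_stall = grid$f_stall, k_on = grid$k_on,
                     k_off_max = grid$k_off_max, KEEP.OUT.ATTRS = FALSE)
  eps <- .Machine$double.eps
  obs <- observed[order(observed$n_dimers), ]
  objective <- vapply(seq_len(nrow(pts)), function(i) {
    p <- team_params(v_mean = fixed$v_mean, v_sd = fixed$v_sd,
                     f_stall = pts$f_stall[i], k_on = pts$k_on[i],
                     k_off0 = fixed$k_off0, k_off_max = pts$k_off_max[i],
                     k_stiff = fixed$k_stiff, dt = fixed$dt,
                     force_dependent = fixed$force_dependent)
    sim <- size_sweep(p, sizes = obs$n_dimers, n_runs = n_runs, seed = seed,
                      max_time = max_time)
    stats_cols <- c("mean_velocity", "sd_velocity", "mean_run_length",
                    "sd_run_length")
    d <- 0
    for (s in stats_cols) {
      o <- obs[[s]]
      if (any(!is.finite(sim[[s]]))) stop("NaN statistic in simulation")
      d <- d + sum(((sim[[s]] - o) / (o + eps))^2)
    }
    d
  }, numeric(1))
  pts$objective <- objective
  best_i <- which.min(objective)
  best <- team_params(v_mean = fixed$v_mean, v_sd = fixed$v_sd,
                      f_stall = pts$f_stall[best_i], k_on = pts$k_on[best_i],
                      k_off0 = fixed$k_off0,
                      k_off_max = pts$k_off_max[best_i],
                      k_stiff = fixed$k_stiff, dt = fixed$dt,
                      force_dependent = fixed$force_dependent)
  list(best = best, best_objective = objective[best_i], surface = pts)
}
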