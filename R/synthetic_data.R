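#' Motility presets for the synthetic track generator
#'
#' Returns a named preset describing one of the experimentally observed
#' single-molecule behaviours. Directed presets carry a Gaussian per-track
#' velocity law and an exponential run-length law; diffusive presets carry
#' a 1-D diffusion coefficient and an exponential residence time; static
#' presets carry only a residence time. All presets include a localization
#' (measurement) noise SD, 30 nm by default.
#'
#' Shipped presets (values as reported for the corresponding constructs and
#' nucleotide states):
#' \describe{
#'   \item{wt_atp}{directed, 77 +/- 23 nm/s, mean run length 5200 nm}
#'   \item{vik1_atp}{directed, 234 +/- 29 nm/s}
#'   \item{chimera_atp}{directed, 188 nm/s}
#'   \item{adp}{diffusive, D = 0.061 um^2/s, tau = 0.6 s}
#'   \item{mutant_atp}{diffusive, D = 0.03 um^2/s, tau = 2 s (tail-only
#'     mutant: unconstrained lattice diffusion)}
#'   \item{apo_wt / apo_mutant}{no-nucleotide state, diffusive with
#'     D = 0.00045 / 0.01 um^2/s}
#'   \item{amppnp_wt / amppnp_mutant}{AMP-PNP state, diffusive with
#'     D = 0.00011 / 0.0036 um^2/s}
#'   \item{static}{immobile spot (photobleaching / detection fixtures)}
#' }
#'
#' @param name preset name, or a custom preset via the other arguments
#' @param state one of "directed", "diffusive", "static" (custom presets)
#' @param velocity_mean,velocity_sd directed: velocity law (nm/s)
#' @param run_length_mean directed: mean exponential run length (nm)
#' @param D diffusive: diffusion coefficient (um^2/s)
#' @param residence_tau diffusive/static: mean exponential lifetime (s)
#' @param localization_sd localization noise SD (nm)
#' @return object of class `motion_preset`
#' @examples
#' motion_preset("wt_atp")
#' motion_preset("custom", state = "diffusive", D = 0.03,
#'               residence_tau = 2, localization_sd = 0)
#' @export
motion_preset <- function(name = "wt_atp", state = NULL,
                          velocity_mean = NULL, velocity_sd = NULL,
                          run_length_mean = NULL, D = NULL,
                          residence_tau = NULL, localization_sd = 30) {
  shipped <- list(
    wt_atp = list(state = "directed", velocity_mean = 77, velocity_sd = 23,
                  run_length_mean = 5200),
    vik1_atp = list(state = "directed", velocity_mean = 234,
                    velocity_sd = 29, run_length_mean = 5200),
    chimera_atp = list(state = "directed", velocity_mean = 188,
                       velocity_sd = 25, run_length_mean = 5200),
    adp = list(state = "diffusive", D = 0.061, residence_tau = 0.6),
    mutant_atp = list(state = "diffusive", D = 0.03, residence_tau = 2),
    apo_wt = list(state = "diffusive", D = 0.00045, residence_tau = 2),
    apo_mutant = list(state = "diffusive", D = 0.01, residence_tau = 2),
    amppnp_wt = list(state = "diffusive", D = 0.00011, residence_tau = 2),
    amppnp_mutant = list(state = "diffusive", D = 0.0036,
                         residence_tau = 2),
    static = list(state = "static", residence_tau = 10))
  if (name %in% names(shipped)) {
    p <- shipped[[name]]
    if (!is.null(state)) p$state <- state
  } else {
    if (is.null(state)) stop("unknown preset '", name,
                             "'; supply `state` for a custom preset")
    p <- list(state = state, velocity_mean = velocity_mean,
              velocity_sd = velocity_sd, run_length_mean = run_length_mean,
              D = D, residence_tau = residence_tau)
  }
  # explicit overrides win over shipped values
  for (f in c("velocity_mean", "velocity_sd", "run_length_mean", "D",
              "residence_tau")) {
    v <- get(f)
    if (!is.null(v)) p[[f]] <- v
  }
  p$name <- name
  p$localization_sd <- localization_sd
  if (!p$state %in% c("directed", "diffusive", "static"))
    stop("state must be directed, diffusive or static")
  if (p$state == "directed") {
    stop_if_not_scalar_pos(p$velocity_mean, "velocity_mean")
    stop_if_not_scalar_pos(p$velocity_sd, "velocity_sd", strict = FALSE)
    stop_if_not_scalar_pos(p$run_length_mean, "run_length_mean")
  }
  if (p$state == "diffusive") {
    stop_if_not_scalar_pos(p$D, "D")
    stop_if_not_scalar_pos(p$residence_tau, "residence_tau")
  }
  if (p$state == "static")
    stop_if_not_scalar_pos(p$residence_tau, "residence_tau")
  stop_if_not_scalar_pos(p$localization_sd, "localization_sd",
                         strict = FALSE)
  structure(p, class = "motion_preset")
}

#' @export
print.motion_preset <- function(x, ...) {
  cat("Motion preset '", x$name, "' (", x$state, ")\n", sep = "")
  if (x$state == "directed")
    cat(sprintf("  v = %g +/- %g nm/s; mean run length %g nm\n",
                x$velocity_mean, x$velocity_sd, x$run_length_mean))
  if (x$state == "diffusive")
    cat(sprintf("  D = %g um^2/s; tau = %g s\n", x$D, x$residence_tau))
  if (x$state == "static")
    cat(sprintf("  tau = %g s\n", x$residence_tau))
  cat(sprintf("  localization SD %g nm\n", x$localization_sd))
  invisible(x)
}

#' Generate ground-truthed single-molecule tracks
#'
#' Simulates `n_tracks` 1-D trajectories along the microtubule axis
#' (minus-end-positive coordinate, nm) according to a [motion_preset()].
#' Directed molecules move at a per-track velocity drawn from the preset's
#' truncated Gaussian until an exponentially distributed run length is
#' exhausted; diffusive molecules take Normal(0, sqrt(2 D dt)) steps for an
#' exponentially distributed lifetime; static molecules hold position.
#' Localization noise is added independently per frame. Runs cut short by
#' the observation window (`duration`) are flagged as censored in the truth
#' table.
#'
#' @param preset a [motion_preset()] (or preset name)
#' @param n_tracks number of molecules
#' @param frame_interval frame interval (s)
#' @param duration observation window (s); `NULL` = until detachment
#' @param intensity mean spot intensity (arbitrary units)
#' @param intensity_sd per-frame intensity noise SD
#' @param seed RNG seed
#' @return list with `tracks` (data.frame `track_id`, `time_s`,
#'   `position_nm`, `intensity`) and `truth` (per-track data.frame with the
#'   generating state, velocity / D, true run length or lifetime, and
#'   censoring flag)
#' @examples
#' g <- generate_tracks("wt_atp", n_tracks = 5, frame_interval = 3, seed = 1)
#' head(g$tracks); g$truth
#' @export
generate_tracks <- function(preset, n_tracks, frame_interval = 3,
                            duration = NULL, intensity = 1000,
                            intensity_sd = 0, seed = NULL) {
  if (is.character(preset)) preset <- motion_preset(preset)
  stopifnot(inherits(preset, "motion_preset"))
  n_tracks <- as.integer(n_tracks)
  if (is.na(n_tracks) || n_tracks < 1L) stop("n_tracks must be >= 1")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  dt <- frame_interval
  if (preset$state == "diffusive" && dt >= preset$residence_tau / 2)
    warning("frame interval >= tau/2: diffusive motion is undersampled")
  with_seed(seed, {
    track_list <- vector("list", n_tracks)
    truth_list <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      censored <- FALSE
      if (preset$state == "directed") {
        v <- -1
        while (v < 0) v <- rnorm(1, preset$velocity_mean, preset$velocity_sd)
        run_len <- rexp(1, 1 / preset$run_length_mean)
        life <- if (v > 0) run_len / v else Inf
      } else {
        v <- NA_real_
        run_len <- NA_real_
        life <- rexp(1, 1 / preset$residence_tau)
      }
      if (!is.null(duration) && life > duration) {
        life <- duration
        censored <- TRUE
      }
      n_frames <- max(2L, floor(life / dt) + 1L)
      tt <- (seq_len(n_frames) - 1L) * dt
      x_true <- switch(preset$state,
        directed = v * tt,
        diffusive = cumsum(c(0, rnorm(n_frames - 1L, 0,
                             sqrt(2 * preset$D * 1e6 * dt)))),
        static = rep(0, n_frames))
      x_obs <- x_true + if (preset$localization_sd > 0)
        rnorm(n_frames, 0, preset$localization_sd) else 0
      inten <- pmax(0, intensity + if (intensity_sd > 0)
        rnorm(n_frames, 0, intensity_sd) else 0)
      track_list[[i]] <- data.frame(track_id = i, time_s = tt,
                                    position_nm = x_obs, intensity = inten)
      truth_list[[i]] <- data.frame(
        track_id = i, state = preset$state, velocity_nm_s = v,
        D_um2_s = if (preset$state == "diffusive") preset$D else NA_real_,
        run_length_nm = run_len, lifetime_s = life, n_frames = n_frames,
        censored = censored)
    }
    list(tracks = do.call(rbind, track_list),
         truth = do.call(rbind, truth_list))
  })
}

#' Generate photobleaching intensity traces
#'
#' Each molecule carries `fluors_per_molecule` fluorophores of unit
#' brightness `unit_intensity`; every fluorophore bleaches at an independent
#' exponential time with rate `bleach_rate`, giving a piecewise-constant
#' staircase to background, plus additive Gaussian read noise.
#'
#' @param n_molecules number of traces
#' @param fluors_per_molecule fluorophores per molecule (>= 1)
#' @param bleach_rate per-fluorophore bleaching rate (1/s)
#' @param noise_sd additive Gaussian noise SD (same units as intensity)
#' @param unit_intensity brightness of one fluorophore
#' @param frame_interval frame interval (s)
#' @param duration trace duration (s); default covers ~5 mean lifetimes
#' @param seed RNG seed
#' @return list with `traces` (matrix, one row per molecule) and `truth`
#'   (data.frame `molecule`, `n_steps`, and a list-column of step times)
#' @export
generate_intensity_traces <- function(n_molecules, fluors_per_molecule = 1,
                                      bleach_rate = 0.2, noise_sd = 0,
                                      unit_intensity = 1000,
                                      frame_interval = 0.1, duration = NULL,
                                      seed = NULL) {
  k <- as.integer(fluors_per_molecule)
  if (is.na(k) || k < 1L) stop("fluors_per_molecule must be >= 1")
  stop_if_not_scalar_pos(bleach_rate, "bleach_rate")
  if (is.null(duration)) duration <- 5 / bleach_rate
  n_frames <- max(10L, ceiling(duration / frame_interval))
  tt <- (seq_len(n_frames) - 1L) * frame_interval
  with_seed(seed, {
    traces <- matrix(0, nrow = n_molecules, ncol = n_frames)
    n_steps <- integer(n_molecules)
    step_times <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      bt <- sort(rexp(k, bleach_rate))
      sig <- vapply(tt, function(t0) sum(bt > t0) * unit_intensity,
                    numeric(1))
      if (noise_sd > 0) sig <- sig + rnorm(n_frames, 0, noise_sd)
      traces[i, ] <- sig
      visible <- bt[bt < max(tt)]
      n_steps[i] <- length(visible)
      step_times[[i]] <- visible
    }
    truth <- data.frame(molecule = seq_len(n_molecules), n_steps = n_steps)
    truth$step_times <- step_times
    list(traces = traces, time_s = tt, truth = truth)
  })
}

#' Specification of a rendered TIRF-like movie
#'
#' @param n_row,n_col image size in pixels
#' @param n_frames number of frames
#' @param pixel_size_nm pixel size (nm), default 133
#' @param frame_interval_s frame interval (s); experiment presets are 3,
#'   0.273 and 0.0286 s
#' @param psf_sigma_nm Gaussian PSF standard deviation (nm)
#' @param background mean background level (counts)
#' @param read_noise_sd Gaussian read noise SD (counts)
#' @param shot_noise apply Poisson shot noise
#' @param shading optional multiplicative shading field (matrix
#'   `n_row` x `n_col`), or `NULL` for a flat field
#' @param axis_origin_px (row, col) pixel position of the axis origin
#'   (position_nm = 0)
#' @param axis_angle_deg direction of increasing (minus-end-positive)
#'   position, degrees; 0 = along columns
#' @return object of class `movie_spec`
#' @export
movie_spec <- function(n_row = 64, n_col = 64, n_frames = 20,
                       pixel_size_nm = 133, frame_interval_s = 3,
                       psf_sigma_nm = 150, background = 100,
                       read_noise_sd = 3, shot_noise = TRUE, shading = NULL,
                       axis_origin_px = c(n_row / 2, 2),
                       axis_angle_deg = 0) {
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  stop_if_not_scalar_pos(psf_sigma_nm, "psf_sigma_nm")
  if (psf_sigma_nm < pixel_size_nm)
    warning("PSF sigma below one pixel: rendering is undersampled")
  if (!is.null(shading))
    stopifnot(is.matrix(shading), nrow(shading) == n_row,
              ncol(shading) == n_col, all(shading > 0))
  structure(list(n_row = as.integer(n_row), n_col = as.integer(n_col),
                 n_frames = as.integer(n_frames),
                 pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s,
                 psf_sigma_nm = psf_sigma_nm, background = background,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise), shading = shading,
                 axis_origin_px = axis_origin_px,
                 axis_angle_deg = axis_angle_deg),
            class = "movie_spec")
}

# integrated Gaussian PSF over pixel areas: photon-conserving rendering
render_psf_add <- function(frame, row_c, col_c, sigma_px, total) {
  h <- ceiling(4 * sigma_px)
  r0 <- max(0, floor(row_c - h)); r1 <- min(nrow(frame) - 1, ceiling(row_c + h))
  c0 <- max(0, floor(col_c - h)); c1 <- min(ncol(frame) - 1, ceiling(col_c + h))
  if (r0 > r1 || c0 > c1) return(frame)
  rows <- r0:r1
  cols <- c0:c1
  # pixel i covers [i, i+1) in continuous coordinates; centre at i + 0.5
  wr <- pnorm(rows + 1, row_c, sigma_px) - pnorm(rows, row_c, sigma_px)
  wc <- pnorm(cols + 1, col_c, sigma_px) - pnorm(cols, col_c, sigma_px)
  frame[rows + 1, cols + 1] <- frame[rows + 1, cols + 1] +
    total * outer(wr, wc)
  frame
}

#' Render tracks into a TIRF-like image stack
#'
#' Maps each molecule's 1-D position onto the movie's microtubule axis and
#' renders it as an integrated 2-D Gaussian PSF scaled by its intensity,
#' on a constant background, with optional multiplicative shading, Poisson
#' shot noise and Gaussian read noise. Continuous pixel coordinates follow
#' the convention that pixel (i, j) covers [i, i+1) x [j, j+1), so physical
#' position = (index + 0.5) * pixel size.
#'
#' @param tracks track data.frame (`track_id`, `time_s`, `position_nm`,
#'   `intensity`) as produced by [generate_tracks()]
#' @param spec a [movie_spec()]
#' @param seed RNG seed for the noise draws
#' @return object of class `movie_stack`: list with `frames` (array
#'   n_row x n_col x n_frames), `spec`, and `truth` (data.frame `track_id`,
#'   `frame`, `row_px`, `col_px`, `position_nm`, `intensity`, `clipped`)
#' @export
render_movie <- function(tracks, spec = movie_spec(), seed = NULL) {
  stopifnot(inherits(spec, "movie_spec"))
  req <- c("track_id", "time_s", "position_nm", "intensity")
  if (!all(req %in% names(tracks)))
    stop("tracks must have columns: ", paste(req, collapse = ", "))
  px <- spec$pixel_size_nm
  ang <- spec$axis_angle_deg * pi / 180
  u <- c(sin(ang), cos(ang))  # (d_row, d_col) per unit position
  sigma_px <- spec$psf_sigma_nm / px
  frame_of <- function(t) as.integer(round(t / spec$frame_interval_s)) + 1L
  tr <- tracks
  tr$frame <- frame_of(tr$time_s)
  tr <- tr[tr$frame >= 1L & tr$frame <= spec$n_frames, , drop = FALSE]
  tr$row_px <- spec$axis_origin_px[1] + u[1] * tr$position_nm / px
  tr$col_px <- spec$axis_origin_px[2] + u[2] * tr$position_nm / px
  inside <- tr$row_px >= 0 & tr$row_px < spec$n_row &
    tr$col_px >= 0 & tr$col_px < spec$n_col
  if (any(!inside))
    warning(sum(!inside), " track points fall outside the field; clipped")
  tr$clipped <- !inside
  with_seed(seed, {
    frames <- array(0, dim = c(spec$n_row, spec$n_col, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      img <- matrix(spec$background, spec$n_row, spec$n_col)
      sel <- which(tr$frame == f & !tr$clipped)
      for (i in sel)
        img <- render_psf_add(img, tr$row_px[i], tr$col_px[i], sigma_px,
                              tr$intensity[i])
      if (!is.null(spec$shading)) img <- img * spec$shading
      if (spec$shot_noise)
        img <- matrix(rpois(length(img), lambda = pmax(img, 0)),
                      spec$n_row, spec$n_col)
      if (spec$read_noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, spec$read_noise_sd),
                            spec$n_row, spec$n_col)
      frames[, , f] <- pmin(pmax(round(img), 0), 65535)
    }
    structure(list(frames = frames, spec = spec,
                   truth = tr[, c("track_id", "frame", "row_px", "col_px",
                                  "position_nm", "intensity", "clipped")]),
              class = "movie_stack")
  })
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf(
    "Movie stack: %d x %d px, %d frames, %g nm/px, %g s/frame\n",
    x$spec$n_row, x$spec$n_col, x$spec$n_frames, x$spec$pixel_size_nm,
    x$spec$frame_interval_s))
  invisible(x)
}
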