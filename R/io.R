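#' Read a 1-D track table from CSV
#'
#' Expects the track schema `track_id, time_s, position_nm, intensity`
#' (optional `censored`). Within each track times must be strictly
#' increasing with a constant interval.
#'
#' @param path CSV path
#' @return data.frame in the track schema (possibly zero rows)
#' @export
read_tracks <- function(path) {
  df <- read.csv(path)
  req <- c("track_id", "time_s", "position_nm", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    bad <- !vapply(df[req[-1]], is.numeric, logical(1))
    if (any(bad))
      stop("non-numeric columns: ", paste(req[-1][bad], collapse = ", "))
  }
  for (id in unique(df$track_id)) {
    tt <- df$time_s[df$track_id == id]
    if (length(tt) >= 2) {
      d <- diff(tt)
      if (any(d <= 0))
        stop("non-monotone times in track ", id)
      if (any(abs(d - d[1]) > 1e-6 * max(d[1], 1e-12)))
        stop("non-constant frame interval in track ", id)
    }
  }
  df
}

#' Write a track table to CSV
#'
#' @param tracks track data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tracks <- function(tracks, path) {
  req <- c("track_id", "time_s", "position_nm", "intensity")
  miss <- setdiff(req, names(tracks))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' A [run_pipeline()] configuration with every stage enabled at a scale
#' that finishes in about a minute. All stage seeds are derived from the
#' single global seed; no stage consumes OS entropy.
#'
#' @param seed global seed
#' @param out_dir output directory (`NULL`: no artifacts written)
#' @param n_tracks_directed,n_runs_team,n_tracks_diffusive scale knobs
#' @param tracking run the render-and-track stage
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1, out_dir = NULL, n_tracks_directed = 699,
                       n_runs_team = 500, n_tracks_diffusive = 300,
                       tracking = TRUE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_tracks_directed = as.integer(n_tracks_directed),
                 n_runs_team = as.integer(n_runs_team),
                 n_tracks_diffusive = as.integer(n_tracks_diffusive),
                 tracking = isTRUE(tracking)),
            class = "run_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON path
#' @return a `run_config` (read) or `path` invisibly (write)
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_config
#' @param config a `run_config`
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the staged demonstration pipeline
#'
#' Executes simulate -> generate -> render -> track -> stats on synthetic
#' data and collects every headline statistic into one report: velocity
#' Gaussian mean, censored run-length mean, MSD power-law exponents for
#' directed and diffusive ensembles, nucleotide-state diffusion fold
#' ratios, ADP-state D, team-model size dependence, tracking recall and
#' the hydrodynamic native molecular weight. When `config$out_dir` is set,
#' intermediate CSV/TIFF artifacts and a JSON report are written there.
#'
#' @param config a [run_config()]
#' @return list of class `pipeline_report`
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_csv <- function(df, name) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  report <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- directed wild-type ensemble: velocity + run length ----------------
  report <- c(report, stage("velocity", {
    g <- generate_tracks("wt_atp", n_tracks = config$n_tracks_directed,
                         frame_interval = 0.273, seed = derive_seed(seed, 1))
    save_csv(g$tracks, "wt_atp_tracks.csv")
    v <- track_velocities(g$tracks)
    gf <- fit_gaussian(v$velocity_nm_s[v$included])
    # run lengths with censoring at a 12 um field
    cap <- 5200 * log(10)
    rl <- with_seed(derive_seed(seed, 2), rexp(209, 1 / 5200))
    ef <- fit_exponential(pmin(rl, cap), rl > cap)
    list(velocity_mean_nm_s = gf$mean, velocity_sd_nm_s = gf$sd,
         run_length_um = ef$mean / 1000)
  }))

  # --- MSD exponents ------------------------------------------------------
  report <- c(report, stage("msd", {
    gd <- generate_tracks("wt_atp", n_tracks = 250, frame_interval = 0.2,
                          seed = derive_seed(seed, 3))
    fit_d <- fit_power_law(compute_msd(gd$tracks))
    pb <- motion_preset("custom", state = "diffusive", D = 0.03,
                        residence_tau = 2, localization_sd = 0)
    gb <- generate_tracks(pb, n_tracks = config$n_tracks_diffusive,
                          frame_interval = 0.0286,
                          seed = derive_seed(seed, 4))
    fit_b <- fit_power_law(compute_msd(gb$tracks))
    list(msd_exponent_directed = fit_d$n, msd_exponent_diffusive = fit_b$n)
  }))

  # --- nucleotide-state diffusion table ----------------------------------
  report <- c(report, stage("diffusion", {
    est_D <- function(preset, off) {
      p <- motion_preset(preset, localization_sd = 0)
      g <- generate_tracks(p, n_tracks = config$n_tracks_diffusive,
                           frame_interval = 0.0286,
                           seed = derive_seed(seed, off))
      msd_diffusion_coefficient(compute_msd(g$tracks), n_lags = 4)
    }
    tab <- diffusion_table(list(
      apo = list(wt = est_D("apo_wt", 5), mutant = est_D("apo_mutant", 6)),
      amppnp = list(wt = est_D("amppnp_wt", 7),
                    mutant = est_D("amppnp_mutant", 8))))
    save_csv(tab, "diffusion_table.csv")
    gadp <- generate_tracks("adp", n_tracks = config$n_tracks_diffusive,
                            frame_interval = 0.0286,
                            seed = derive_seed(seed, 9))
    msd <- compute_msd(gadp$tracks, lifetime_filter = c(0.5, 5))
    list(apo_fold_ratio = tab$fold_ratio[tab$state == "apo"],
         amppnp_fold_ratio = tab$fold_ratio[tab$state == "amppnp"],
         adp_D_um2_s = msd_diffusion_coefficient(msd, n_lags = 4))
  }))

  # --- team model ---------------------------------------------------------
  report <- c(report, stage("team_model", {
    ss <- size_sweep(team_params(), sizes = 1:4,
                     n_runs = config$n_runs_team,
                     seed = derive_seed(seed, 10))
    save_csv(as.data.frame(ss), "team_size_stats.csv")
    list(team_size_stats = as.data.frame(ss))
  }))

  # --- tracking on a rendered movie --------------------------------------
  if (config$tracking) report <- c(report, stage("tracking", {
    g <- generate_tracks("wt_atp", n_tracks = 10, frame_interval = 3,
                         duration = 57, intensity = 600,
                         seed = derive_seed(seed, 11))
    tr <- g$tracks
    tr$position_nm <- tr$position_nm + ((0:9) * 10 * 133)[tr$track_id]
    spec <- movie_spec(n_row = 48, n_col = 96, n_frames = 20,
                       frame_interval_s = 3)
    mv <- suppressWarnings(render_movie(tr, spec,
                                        seed = derive_seed(seed, 13)))
    if (!is.null(out_dir))
      write_movie_tiff(mv, file.path(out_dir, "demo_movie.tif"),
                       metadata = list(seed = seed))
    res <- track_movie(mv)
    save_csv(res$tracks, "demo_tracked.csv")
    list(tracking_recall = tracking_recall(res$tracks_px, mv$truth))
  }))

  # --- hydrodynamic mass --------------------------------------------------
  report$native_mw_kda <- native_mw(9.1, 5.6)

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    r <- report
    r$team_size_stats <- NULL
    jsonlite::write_json(unclass(r), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10)
    write.csv(report$team_size_stats,
              file.path(out_dir, "team_size_stats.csv"), row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  velocity: %.1f +/- %.1f nm/s; run length %.2f um\n",
              x$velocity_mean_nm_s, x$velocity_sd_nm_s, x$run_length_um))
  cat(sprintf("  MSD exponents: directed %.3f, diffusive %.3f\n",
              x$msd_exponent_directed, x$msd_exponent_diffusive))
  cat(sprintf("  fold ratios: apo %.1f, AMP-PNP %.1f; ADP D = %.4f um^2/s\n",
              x$apo_fold_ratio, x$amppnp_fold_ratio, x$adp_D_um2_s))
  if (!is.null(x$tracking_recall))
    cat(sprintf("  tracking recall: %.1f%%\n", 100 * x$tracking_recall))
  cat(sprintf("  native MW: %.0f kDa\n", x$native_mw_kda))
  invisible(x)
}

#' Fraction of ground-truth time points recovered by tracking
#'
#' A truth point counts as recovered when some detection in the same frame
#' lies within `tol_px` pixels of it.
#'
#' @param tracks_px pixel-space tracks (`frame`, `row`, `col`)
#' @param truth truth table from [render_movie()] (`frame`, `row_px`,
#'   `col_px`, `clipped`)
#' @param tol_px matching tolerance (pixels)
#' @return recall in [0, 1]
#' @export
tracking_recall <- function(tracks_px, truth, tol_px = 1) {
  truth <- truth[!truth$clipped, , drop = FALSE]
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- tracks_px[tracks_px$frame == truth$frame[i], , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    any(sqrt((cand$row - truth$row_px[i])^2 +
               (cand$col - truth$col_px[i])^2) <= tol_px)
  }, logical(1))
  mean(hit)
}
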