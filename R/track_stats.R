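#' Per-track velocity by least-squares slope
#'
#' Velocity of one molecule as the least-squares slope of position vs time,
#' positive toward the microtubule minus end. Tracks shorter than
#' `min_frames` are excluded (returned as `NA` with a reason).
#'
#' @param track data.frame with `time_s` and `position_nm`
#' @param min_frames minimum track length (frames), default 5
#' @return velocity in nm/s, or `NA` with attribute `reason` when excluded
#' @export
track_velocity <- function(track, min_frames = 5L) {
  stopifnot(all(c("time_s", "position_nm") %in% names(track)))
  if (nrow(track) < min_frames) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("short_track (%d < %d frames)",
                                   nrow(track), min_frames)
    return(out)
  }
  tt <- track$time_s - mean(track$time_s)
  sum(tt * (track$position_nm - mean(track$position_nm))) / sum(tt^2)
}

#' Per-track velocities for a whole track table
#'
#' @param tracks data.frame with `track_id`, `time_s`, `position_nm`
#' @param min_frames minimum track length
#' @return data.frame `track_id`, `velocity_nm_s`, `n_frames`, `included`,
#'   `reason`
#' @export
track_velocities <- function(tracks, min_frames = 5L) {
  by_id <- split(tracks, tracks$track_id)
  res <- lapply(by_id, function(tr) {
    v <- track_velocity(tr, min_frames)
    data.frame(track_id = tr$track_id[1], velocity_nm_s = as.numeric(v),
               n_frames = nrow(tr), included = is.finite(v),
               reason = if (is.na(v)) attr(v, "reason") else "")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gaussian fit by maximum likelihood
#'
#' For a Gaussian the ML estimates are the sample mean and SD; the standard
#' error of the mean is `sd / sqrt(n)`.
#'
#' @param values numeric observations (>= 20 recommended for distribution
#'   fits)
#' @return object of class `gauss_fit`: `mean`, `sd`, `n`, `se_mean`,
#'   `loglik`
#' @export
fit_gaussian <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need >= 2 finite observations")
  m <- mean(values); s <- sd(values)
  structure(list(mean = m, sd = s, n = n, se_mean = s / sqrt(n),
                 loglik = sum(dnorm(values, m, s, log = TRUE))),
            class = "gauss_fit")
}

#' Exponential fit with right-censoring
#'
#' Maximum-likelihood estimate of the mean of an exponential distribution
#' when some observations are right-censored (the molecule left the
#' observation window rather than detaching): `mean = sum(all values) /
#' number uncensored`. The standard error is `mean / sqrt(n_uncensored)`.
#'
#' @param values observed run lengths (nm) or dwell times (s)
#' @param censored logical flags, `TRUE` where the value is a lower bound
#' @return object of class `exp_fit`: `mean`, `se`, `n_obs`, `n_censored`
#' @examples
#' fit_exponential(c(1, 2, 3))                        # mean 2
#' fit_exponential(c(1, 2, 3), c(FALSE, FALSE, TRUE)) # mean 3
#' @export
fit_exponential <- function(values, censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(values))
  stopifnot(length(values) == length(censored))
  keep <- is.finite(values)
  values <- values[keep]; censored <- as.logical(censored)[keep]
  if (length(values) < 1) stop("need >= 1 observation")
  if (any(values < 0)) stop("exponential data must be non-negative")
  n_unc <- sum(!censored)
  if (n_unc == 0) stop("all observations censored: mean not identifiable")
  m <- sum(values) / n_unc
  structure(list(mean = m, se = m / sqrt(n_unc), n_obs = length(values),
                 n_censored = sum(censored)), class = "exp_fit")
}

#' Ensemble mean-squared displacement
#'
#' Per-track time-averaged MSD over all pair offsets, then ensemble-averaged
#' across tracks weighted by pair counts. Lags are limited to
#' `max_lag_fraction` of the longest track's duration and, more
#' restrictively, to lags whose pair support is at least `min_support` of
#' the maximal pair count (but never fewer than 4 lags). The support rule
#' keeps the curve in the regime where most tracks still contribute:
#' beyond it the ensemble value is carried by the few longest-lived
#' molecules, which both inflates the variance and, for detachment-limited
#' directed runs (duration ~ run length / velocity), biases the curve
#' toward slow survivors. All tracks must share one frame interval. An
#' optional lifetime filter (e.g. the 0.5-5 s window used for diffusive
#' analyses) selects tracks by duration first.
#'
#' @param tracks data.frame `track_id`, `time_s`, `position_nm`
#' @param max_lag_fraction largest lag as a fraction of the longest track
#'   duration (default 0.25)
#' @param min_support keep lags with pair count >= this fraction of the
#'   maximal pair count (default 0.75); 0 disables the rule
#' @param lifetime_filter optional `c(min_s, max_s)` duration window
#' @return data.frame of class `msd_curve`: `lag_s`, `msd_nm2`, `n_pairs`
#' @export
compute_msd <- function(tracks, max_lag_fraction = 0.25, min_support = 0.75,
                        lifetime_filter = NULL) {
  by_id <- split(tracks[, c("time_s", "position_nm")], tracks$track_id)
  durations <- vapply(by_id, function(tr) diff(range(tr$time_s)), numeric(1))
  if (!is.null(lifetime_filter)) {
    keep <- durations >= lifetime_filter[1] & durations <= lifetime_filter[2]
    by_id <- by_id[keep]
    durations <- durations[keep]
    if (length(by_id) == 0) stop("no tracks pass the lifetime filter")
  }
  dts <- unlist(lapply(by_id, function(tr) diff(tr$time_s)))
  dt <- median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt))
    stop("mixed frame intervals across tracks")
  max_lag_s <- max_lag_fraction * max(durations)
  max_k <- max(1L, floor(max_lag_s / dt))
  sums <- numeric(max_k)
  counts <- numeric(max_k)
  for (tr in by_id) {
    x <- tr$position_nm
    n <- length(x)
    for (k in seq_len(min(max_k, n - 1L))) {
      d <- x[(1 + k):n] - x[1:(n - k)]
      sums[k] <- sums[k] + sum(d * d)
      counts[k] <- counts[k] + (n - k)
    }
  }
  keep <- counts > 0
  if (min_support > 0 && any(keep)) {
    supported <- counts >= min_support * max(counts)
    supported[seq_len(min(4L, max_k))] <- TRUE  # never fewer than 4 lags
    keep <- keep & supported
  }
  out <- data.frame(lag_s = (seq_len(max_k) * dt)[keep],
                    msd_nm2 = (sums / pmax(counts, 1))[keep],
                    n_pairs = counts[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a power law to an MSD curve
#'
#' Weighted nonlinear least squares of `<x^2> = a * t^n` (weights = pair
#' counts). `n = 1` indicates standard diffusion, in which case `a = 2D`;
#' `n = 2` indicates directed transport. When the fitted exponent lies in
#' [0.8, 1.2] the diffusion coefficient `D = a / 2` is also reported in
#' um^2/s.
#'
#' @param msd an `msd_curve` from [compute_msd()] (>= 4 positive-lag points)
#' @return object of class `power_law_fit`: `a` (nm^2/s^n), `n`, `se_a`,
#'   `se_n`, `D_um2_s` (or `NA`), `n_points`
#' @export
fit_power_law <- function(msd) {
  stopifnot(all(c("lag_s", "msd_nm2", "n_pairs") %in% names(msd)))
  d <- msd[msd$msd_nm2 > 0 & msd$lag_s > 0, ]
  if (nrow(d) < 4) stop("need >= 4 positive MSD points")
  # log-log weighted regression for starting values
  lf <- lm(log(msd_nm2) ~ log(lag_s), data = d, weights = d$n_pairs)
  start <- list(a = exp(coef(lf)[[1]]), n = coef(lf)[[2]])
  # scaleOffset keeps the convergence test meaningful on zero-residual
  # (exact power-law) inputs
  fit <- nls(msd_nm2 ~ a * lag_s^n, data = d, weights = d$n_pairs,
             start = start,
             control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                          warnOnly = TRUE))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  n_hat <- cf[["n"]]
  a_hat <- cf[["a"]]
  if (a_hat <= 0 || n_hat < 0 || n_hat > 2.5)
    warning(sprintf("fit outside sanity band: a = %.3g, n = %.3g",
                    a_hat, n_hat))
  structure(list(a = a_hat, n = n_hat, se_a = se[[1]], se_n = se[[2]],
                 D_um2_s = if (n_hat >= 0.8 && n_hat <= 1.2)
                   a_hat / 2 * 1e-6 else NA_real_,
                 n_points = nrow(d)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("MSD power law: a = %.4g nm^2/s^n, n = %.3f (SE %.3f)\n",
              x$a, x$n, x$se_n))
  if (is.finite(x$D_um2_s))
    cat(sprintf("  diffusive regime: D = a/2 = %.4g um^2/s\n", x$D_um2_s))
  invisible(x)
}

#' Estimate a diffusion coefficient from the early MSD
#'
#' Linear fit (with intercept, absorbing the localization-noise offset
#' 2*sigma^2) of MSD vs lag over the first `n_lags` lags; `D = slope / 2`.
#'
#' @param msd an `msd_curve`
#' @param n_lags number of initial lags used (default 4)
#' @return D in um^2/s
#' @export
msd_diffusion_coefficient <- function(msd, n_lags = 4L) {
  d <- head(msd, n_lags)
  if (nrow(d) < 2) stop("need >= 2 lags")
  slope <- coef(lm(msd_nm2 ~ lag_s, data = d, weights = d$n_pairs))[[2]]
  slope / 2 * 1e-6
}

#' Tabulate diffusion coefficients and mutant:wild-type fold ratios
#'
#' @param fits named list of lists: `fits[[state]]$wt` and
#'   `fits[[state]]$mutant`, each a D value (um^2/s) or a `power_law_fit`
#' @return data.frame `state`, `D_wt`, `D_mutant`, `fold_ratio`
#' @export
diffusion_table <- function(fits) {
  getD <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (inherits(x, "power_law_fit")) {
      if (is.finite(x$D_um2_s)) return(x$D_um2_s)
      return(x$a / 2 * 1e-6)
    }
    as.numeric(x)
  }
  rows <- lapply(names(fits), function(s) {
    dw <- getD(fits[[s]]$wt); dm <- getD(fits[[s]]$mutant)
    data.frame(state = s, D_wt = dw, D_mutant = dm,
               fold_ratio = dm / dw)
  })
  do.call(rbind, rows)
}

# squared-error of a constant fit
.sse <- function(x) {
  if (length(x) < 2) return(0)
  sum((x - mean(x))^2)
}

# best single change point of a segment: minimizes total SSE, split after
# index k (1 <= k < n), respecting a minimum segment length
.best_split <- function(x, min_seg = 2L) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ks <- min_seg:(n - min_seg)
  sse_l <- cs2[ks] - cs[ks]^2 / ks
  sse_r <- (cs2[n] - cs2[ks]) - (cs[n] - cs[ks])^2 / (n - ks)
  tot <- sse_l + sse_r
  k <- ks[which.min(tot)]
  list(k = k, sse = min(tot))
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant model by recursive binary segmentation: each
#' segment is split at the point minimizing the residual sum of squares,
#' and the split is accepted while it improves a BIC-type criterion
#' (`m * log(SSE0 / SSE1) > 2 * log(N)` for a segment of length m in a
#' trace of length N, two extra parameters per change point). Returns the
#' number of downward steps and their frame indices.
#'
#' @param trace numeric intensity trace (length >= 10)
#' @param min_seg minimum segment length (frames)
#' @return object of class `bleach_fit`: `n_steps` (downward), `step_index`
#'   (frame after which each downward step occurs), `changepoints` (all),
#'   `levels` (fitted segment means)
#' @export
count_bleach_steps <- function(trace, min_seg = 3L) {
  if (any(!is.finite(trace))) stop("non-finite intensities")
  n <- length(trace)
  if (n < 10) stop("trace must have >= 10 points")
  penalty <- 2 * log(n)
  tol <- 1e-12 * max(1, .sse(trace))
  cps <- integer(0)
  segment <- function(lo, hi) {
    x <- trace[lo:hi]
    sp <- .best_split(x, min_seg)
    if (is.null(sp)) return()
    sse0 <- .sse(x)
    improve <- if (sp$sse <= tol) Inf else length(x) * log(sse0 / sp$sse)
    if (sse0 <= tol || improve <= penalty) return()
    cp <- lo + sp$k - 1L
    cps <<- c(cps, cp)
    segment(lo, cp)
    segment(cp + 1L, hi)
  }
  segment(1L, n)
  cps <- sort(cps)
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  down <- which(diff(levels) < 0)
  structure(list(n_steps = length(down), step_index = cps[down],
                 changepoints = cps, levels = levels),
            class = "bleach_fit")
}

#' Constrained Gaussian-mixture fit of spot brightness
#'
#' Fits a K-component mixture in which component k (a complex of k
#' fluorophore-labelled dimers) has mean `k * mu1` and SD `sqrt(k) * sigma1`,
#' by expectation-maximization with closed-form M-steps. The default K = 4
#' mirrors a four-peak brightness histogram.
#'
#' @param values brightness values (>= 100 recommended)
#' @param K number of components
#' @param max_iter,tol EM stopping controls
#' @return object of class `mixture_fit`: `mu1`, `sigma1`, `weights`,
#'   `loglik`, `n_iter`, `converged`
#' @export
fit_brightness_mixture <- function(values, K = 4L, max_iter = 1000L,
                                   tol = 1e-10) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2 * K) stop("too few brightness values")
  ks <- seq_len(K)
  run_em <- function(mu1, sigma1, w) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(ks, function(k)
        w[k] * dnorm(values, k * mu1, sqrt(k) * sigma1), numeric(n))
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      r <- dens / tot
      w <- colMeans(r)
      # with component variance k*sigma1^2 the mu1 M-step collapses to
      # sum(x) / sum_{i,k} r_ik * k
      mu1 <- sum(values) / sum(r %*% ks)
      # weighted variance with per-component scaling k
      num <- sum(vapply(ks, function(k)
        sum(r[, k] * (values - k * mu1)^2 / k), numeric(1)))
      sigma1 <- sqrt(max(num / n, 1e-12))
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        return(list(mu1 = mu1, sigma1 = sigma1, weights = w, loglik = ll,
                    n_iter = it, converged = TRUE))
      }
      ll_old <- ll
    }
    list(mu1 = mu1, sigma1 = sigma1, weights = w, loglik = ll_old,
         n_iter = max_iter, converged = FALSE)
  }
  s0 <- sd(values)
  inits <- list(
    list(mu1 = median(values), sigma1 = s0 / 2),
    list(mu1 = mean(values) / 2, sigma1 = s0 / 2),
    list(mu1 = quantile(values, 0.25)[[1]], sigma1 = s0 / 3))
  fits <- lapply(inits, function(i)
    run_em(max(i$mu1, 1e-9), max(i$sigma1, 1e-9), rep(1 / K, K)))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(lls)]]
  # mu1 is identified only up to integer divisors when the data lack a
  # genuine unit-brightness population (brightness k*mu1 = (k*m)*(mu1/m)).
  # If essentially all weight sits on one component k0 > 1, report the
  # parsimonious reading: that population is size 1 at unit k0*mu1.
  k0 <- which.max(best$weights)
  if (k0 > 1 && best$weights[k0] > 0.95) {
    best$mu1 <- k0 * best$mu1
    best$sigma1 <- sqrt(k0) * best$sigma1
    w <- numeric(K)
    w[1] <- 1
    best$weights <- w
    best$loglik <- sum(dnorm(values, best$mu1, best$sigma1, log = TRUE))
  }
  if (!best$converged)
    stop(sprintf(
      "EM did not converge in %d iterations (loglik %.6g, mu1 %.4g)",
      max_iter, best$loglik, best$mu1))
  structure(c(best, list(K = K, n = n)), class = "mixture_fit")
}

#' Assign a complex size from its brightness
#'
#' Maximum-posterior component of a [fit_brightness_mixture()] fit.
#'
#' @param brightness one or more brightness values
#' @param fit a `mixture_fit`
#' @return integer size(s) in 1..K
#' @export
assign_size <- function(brightness, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  ks <- seq_len(fit$K)
  post <- vapply(ks, function(k)
    fit$weights[k] * dnorm(brightness, k * fit$mu1, sqrt(k) * fit$sigma1),
    numeric(length(brightness)))
  if (length(brightness) == 1) return(which.max(post))
  apply(post, 1, which.max)
}

#' Track brightness for stoichiometry analysis
#'
#' Brightness of a complex = mean background-subtracted intensity over its
#' first `n_first` frames, capturing the initial size before
#' photobleaching.
#'
#' @param tracks data.frame `track_id`, `time_s`, `intensity`
#' @param n_first frames averaged (default 3)
#' @return data.frame `track_id`, `brightness`
#' @export
track_brightness <- function(tracks, n_first = 3L) {
  by_id <- split(tracks, tracks$track_id)
  out <- lapply(by_id, function(tr) {
    tr <- tr[order(tr$time_s), ]
    data.frame(track_id = tr$track_id[1],
               brightness = mean(head(tr$intensity, n_first)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residence (dwell) times with censoring at the observation end
#'
#' Computes per-track durations and flags tracks whose last frame touches
#' the end of the observation window as right-censored, then fits the
#' censored exponential MLE.
#'
#' @param tracks data.frame `track_id`, `time_s`
#' @param movie_end end of the observation window (s); tracks reaching
#'   within one frame interval of it are censored. `NULL` disables
#'   censoring.
#' @return an `exp_fit` of the residence time tau (s), with the per-track
#'   table in attribute `durations`
#' @export
dwell_times <- function(tracks, movie_end = NULL) {
  by_id <- split(tracks$time_s, tracks$track_id)
  if (length(by_id) == 0) stop("no tracks selected")
  dur <- vapply(by_id, function(t) diff(range(t)), numeric(1))
  last <- vapply(by_id, max, numeric(1))
  dt <- median(unlist(lapply(by_id, diff)))
  cen <- if (is.null(movie_end)) rep(FALSE, length(dur)) else
    last >= movie_end - dt
  fit <- fit_exponential(dur, cen)
  attr(fit, "durations") <- data.frame(track_id = names(by_id),
                                       duration_s = dur, censored = cen)
  fit
}
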