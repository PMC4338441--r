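# shared fixtures, built in code at test time

# straight-line track in the 1-D schema
line_track <- function(v = 77, n = 20, dt = 1, id = 1L, noise_sd = 0,
                       intensity = 1000) {
  tt <- (seq_len(n) - 1) * dt
  x <- v * tt
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  data.frame(track_id = id, time_s = tt, position_nm = x,
             intensity = intensity)
}

# per-frame detection table for linking tests
det_table <- function(frame, row, col, intensity = 1, radius_px = 2.5) {
  data.frame(frame = frame, row = row, col = col, intensity = intensity,
             radius_px = radius_px)
}

# noiseless frame with integrated-Gaussian spots
spot_frame <- function(nr = 32, nc = 32, rows, cols, amp = 500, bg = 100,
                       sigma_px = 1.13) {
  f <- matrix(bg, nr, nc)
  for (i in seq_along(rows)) {
    rr <- 0:(nr - 1); cc <- 0:(nc - 1)
    wr <- pnorm(rr + 1, rows[i], sigma_px) - pnorm(rr, rows[i], sigma_px)
    wc <- pnorm(cc + 1, cols[i], sigma_px) - pnorm(cc, cols[i], sigma_px)
    f <- f + amp[min(i, length(amp))] * outer(wr, wc)
  }
  f
}

# brute-force censored-exponential log-likelihood (independent oracle)
cens_exp_loglik <- function(mean_par, values, censored) {
  rate <- 1 / mean_par
  sum(ifelse(censored, -rate * values, log(rate) - rate * values))
}
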