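test_that("shading correction: constant frames, impulses, gradients", {
  f <- matrix(7, 20, 20)
  expect_equal(shading_correct(f), matrix(1, 20, 20))
  expect_error(shading_correct(matrix(0, 20, 20)), "all-zero")
  expect_error(shading_correct(matrix(1, 5, 5)), "at least")
  # impulse on flat background: median of the 121-pixel window ignores it
  f2 <- matrix(10, 30, 30)
  f2[15, 15] <- 500
  expect_equal(shading_correct(f2)[15, 15], 50)
  # spot contrast independent of a smooth shading field's amplitude
  # (illumination-scale gradients; steep gradients interact with the
  # median window at the few-percent level)
  spot <- spot_frame(80, 80, rows = 39.5, cols = 39.5, amp = 300, bg = 100)
  grad1 <- outer(1 + 0.15 * seq(0, 1, length.out = 80), rep(1, 80))
  grad2 <- outer(1 + 0.30 * seq(0, 1, length.out = 80), rep(1, 80))
  c1 <- max(shading_correct(spot * grad1)) - 1
  c2 <- max(shading_correct(spot * grad2)) - 1
  expect_lt(abs(c1 - c2) / c1, 0.02)
})

test_that("3x3 Gaussian smoothing has unit DC gain and is linear", {
  f <- matrix(5, 16, 16)
  expect_equal(smooth_frame(f), f)
  imp <- matrix(0, 16, 16)
  imp[8, 8] <- 1
  s <- smooth_frame(imp)
  expect_equal(sum(s), 1)
  expect_true(all(s[-(7:9), ] == 0) && all(s[, -(7:9)] == 0))
  imp2 <- matrix(0, 16, 16)
  imp2[4, 4] <- 1
  expect_equal(smooth_frame(imp + imp2), smooth_frame(imp) + smooth_frame(imp2))
})

test_that("detection finds separated spots and merges close ones", {
  f <- spot_frame(32, 32, rows = c(10.5, 10.5), cols = c(8.5, 18.5),
                  amp = 400, bg = 100)
  set.seed(1)
  fn <- f + matrix(rnorm(length(f), 0, 2), nrow(f))
  d <- detect_spots(smooth_frame(fn))
  expect_equal(nrow(d), 2)
  d <- d[order(d$col), ]
  expect_lt(max(abs(d$row - 11)), 1)
  expect_lt(abs(d$col[1] - 9), 1)
  expect_lt(abs(d$col[2] - 19), 1)
  # two spots 2 px apart lie within the 532 nm suppression radius
  f2 <- spot_frame(32, 32, rows = c(10.5, 10.5), cols = c(15.5, 17.5),
                   amp = 400, bg = 100)
  d2 <- detect_spots(smooth_frame(f2 + matrix(rnorm(length(f2), 0, 2), 32)))
  expect_equal(nrow(d2), 1)
})

test_that("blank-noise false positives stay below one per frame", {
  spec <- movie_spec(n_row = 128, n_col = 128, n_frames = 30,
                     background = 100)
  empty <- data.frame(track_id = integer(0), time_s = numeric(0),
                      position_nm = numeric(0), intensity = numeric(0))
  mv <- render_movie(empty, spec, seed = 33)
  fp <- vapply(1:30, function(f) {
    cor <- shading_correct(mv$frames[, , f])
    nrow(detect_spots(smooth_frame(cor), noise_frame = cor))
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("linking: static, moving, and parallel spots", {
  # one static spot over 6 frames -> one track of length 6
  d <- det_table(frame = 1:6, row = 10, col = 10)
  tr <- link_detections(d)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 6)
  # 1 px/frame motion: circle overlap at distance 1 px is positive
  d2 <- det_table(frame = 1:6, row = 10, col = 10 + (0:5))
  expect_equal(length(unique(link_detections(d2)$track_id)), 1)
  # two parallel lanes 10 px apart: two tracks, no identity swap
  d3 <- rbind(det_table(1:6, row = 5, col = 10 + (0:5)),
              det_table(1:6, row = 15, col = 10 + (0:5)))
  t3 <- link_detections(d3)
  expect_equal(length(unique(t3$track_id)), 2)
  for (id in unique(t3$track_id))
    expect_equal(length(unique(t3$row[t3$track_id == id])), 1)
  # greedy result matches the exhaustive optimal-assignment oracle here
  t3o <- link_detections(d3, method = "optimal")
  expect_equal(t3[order(t3$frame, t3$row), c("frame", "row", "col")],
               t3o[order(t3o$frame, t3o$row), c("frame", "row", "col")],
               ignore_attr = TRUE)
})

test_that("linking is one-to-one and never joins non-overlapping circles", {
  set.seed(7)
  det <- do.call(rbind, lapply(1:8, function(f)
    det_table(f, row = runif(6, 3, 29), col = runif(6, 3, 29))))
  tr <- link_detections(det)
  # one-to-one: a (frame, track) pair appears at most once
  expect_false(any(duplicated(tr[, c("frame", "track_id")])))
  # no link spans >= 2*radius = 5 px
  for (id in unique(tr$track_id)) {
    seg <- tr[tr$track_id == id, ]
    if (nrow(seg) < 2) next
    steps <- sqrt(diff(seg$row)^2 + diff(seg$col)^2)
    expect_true(all(steps < 5))
  }
})

test_that("duplicate detections are deduplicated with a warning", {
  d <- rbind(det_table(1, 10, 10), det_table(1, 10, 10),
             det_table(2, 10, 10))
  expect_warning(tr <- link_detections(d), "dedup")
  expect_equal(nrow(tr), 2)
})

test_that("pipeline is translation-equivariant for whole-pixel shifts", {
  spec <- movie_spec(n_row = 40, n_col = 40, n_frames = 4,
                     frame_interval_s = 3, axis_origin_px = c(14, 12))
  tr <- data.frame(track_id = 1, time_s = c(0, 3, 6, 9),
                   position_nm = c(0, 230, 460, 690), intensity = 600)
  mv <- render_movie(tr, spec, seed = 44)
  shift <- function(m, dr, dc) m[((seq_len(nrow(m)) - dr - 1) %% nrow(m)) + 1,
                                 ((seq_len(ncol(m)) - dc - 1) %% ncol(m)) + 1]
  shifted <- mv$frames
  for (f in 1:4) shifted[, , f] <- shift(mv$frames[, , f], 5, 7)
  r1 <- track_movie(mv)
  r2 <- track_movie(shifted, frame_interval_s = 3,
                    axis_origin_px = spec$axis_origin_px)
  expect_equal(nrow(r1$tracks_px), nrow(r2$tracks_px))
  o1 <- r1$tracks_px[order(r1$tracks_px$frame, r1$tracks_px$row), ]
  o2 <- r2$tracks_px[order(r2$tracks_px$frame, r2$tracks_px$row), ]
  expect_equal(o2$row, o1$row + 5, tolerance = 1e-6)
  expect_equal(o2$col, o1$col + 7, tolerance = 1e-6)
})
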