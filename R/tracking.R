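#' Shading correction by median-filter division
#'
#' Divides the raw frame by its 11 x 11 (1463 x 1463 nm at 133 nm/px)
#' median-filtered version, flattening slowly varying illumination while
#' preserving point-source contrast. Borders are handled by reflection.
#'
#' @param frame numeric matrix (one movie frame)
#' @param kernel median-filter kernel size (odd), default 11
#' @return corrected frame (matrix, ~1 where flat)
#' @export
shading_correct <- function(frame, kernel = 11L) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (nrow(frame) < kernel || ncol(frame) < kernel)
    stop("frame must be at least ", kernel, " x ", kernel)
  if (all(frame == 0)) stop("all-zero frame: shading correction undefined")
  med <- median_filter_cpp(frame, as.integer(kernel))
  eps <- .Machine$double.eps
  frame / pmax(med, eps)
}

#' Gaussian smoothing with a 3 x 3 kernel
#'
#' Convolves with a unit-sum Gaussian kernel truncated to 3 x 3 support
#' (399 x 399 nm at 133 nm/px), sigma = 0.8 px. Reflected borders; DC gain
#' is exactly 1.
#'
#' @param frame numeric matrix
#' @param sigma Gaussian sigma in pixels
#' @return smoothed frame
#' @export
smooth_frame <- function(frame, sigma = 0.8) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  g <- dnorm(-1:1, 0, sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  nr <- nrow(frame); nc <- ncol(frame)
  # reflect-pad by one pixel, then 3x3 convolution as shifted sums
  pr <- c(1, seq_len(nr), nr)
  pc <- c(1, seq_len(nc), nc)
  p <- frame[pr, pc]
  out <- matrix(0, nr, nc)
  for (dr in 0:2)
    for (dc in 0:2)
      out <- out + k[dr + 1, dc + 1] * p[dr + seq_len(nr), dc + seq_len(nc)]
  out
}

#' Detect fluorescent spots in a processed frame
#'
#' On a shading-corrected, smoothed frame: segments pixels above
#' `median + k * 1.4826 * MAD`, keeps strict local intensity maxima within a
#' 532 nm search radius, and measures each spot in a circular ROI of radius
#' 332 nm. The noise MAD is estimated on `noise_frame` when given —
#' normally the shading-corrected frame *before* smoothing, so the
#' threshold reflects the data's noise rather than the (correlated,
#' reduced) noise of the smoothed image. Intensity is the ROI sum minus the local background (median of
#' an annulus out to twice the circle radius) times the ROI area; the
#' sub-pixel centroid is the background-subtracted intensity-weighted
#' centroid inside the circle.
#'
#' Pixel coordinates are 0-based (row, col); pixel (i, j) covers
#' [i, i+1) x [j, j+1), so physical position = (coordinate) * pixel size
#' with centroids living in continuous coordinates.
#'
#' @param frame processed frame (matrix)
#' @param pixel_size_nm pixel size (nm)
#' @param threshold_k MAD multiplier of the segmentation threshold
#' @param search_radius_nm local-maximum suppression radius (nm)
#' @param circle_radius_nm measurement circle radius (nm)
#' @param noise_frame frame used for the noise MAD (default: `frame`)
#' @return data.frame of class `detections`: `row`, `col` (0-based
#'   sub-pixel), `intensity`, `radius_px`
#' @export
detect_spots <- function(frame, pixel_size_nm = 133, threshold_k = 3,
                         search_radius_nm = 532, circle_radius_nm = 332,
                         noise_frame = NULL) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (is.null(noise_frame)) noise_frame <- frame
  bg <- median(frame)
  nbg <- median(noise_frame)
  thr <- bg + threshold_k * 1.4826 * median(abs(noise_frame - nbg))
  r_search <- search_radius_nm / pixel_size_nm
  r_circ <- circle_radius_nm / pixel_size_nm
  maxima <- local_maxima_cpp(frame, r_search, thr)
  n <- nrow(maxima)
  out <- data.frame(row = numeric(n), col = numeric(n),
                    intensity = numeric(n), radius_px = numeric(n))
  if (n == 0) {
    class(out) <- c("detections", "data.frame")
    return(out)
  }
  nr <- nrow(frame); nc <- ncol(frame)
  h <- ceiling(2 * r_circ)
  for (i in seq_len(n)) {
    r0 <- maxima[i, 1]; c0 <- maxima[i, 2]
    rows <- max(0, r0 - h):min(nr - 1, r0 + h)
    cols <- max(0, c0 - h):min(nc - 1, c0 + h)
    # distances from pixel centres to the maximum's pixel centre
    dr <- outer(rows - r0, rep(0, length(cols)), "+")
    dc <- outer(rep(0, length(rows)), cols - c0, "+")
    d <- sqrt(dr^2 + dc^2)
    sub <- frame[rows + 1, cols + 1]
    in_circ <- d <= r_circ
    in_ann <- d > r_circ & d <= 2 * r_circ
    local_bg <- if (any(in_ann)) median(sub[in_ann]) else bg
    vals <- sub - local_bg
    inten <- sum(vals[in_circ])
    w <- pmax(vals, 0) * in_circ
    sw <- sum(w)
    # centre-of-pixel convention: pixel index + 0.5
    if (sw > 0) {
      rc <- sum(w * (dr + r0 + 0.5)) / sw
      cc <- sum(w * (dc + c0 + 0.5)) / sw
    } else {
      rc <- r0 + 0.5; cc <- c0 + 0.5
    }
    out$row[i] <- rc; out$col[i] <- cc
    out$intensity[i] <- inten
    out$radius_px[i] <- r_circ
  }
  class(out) <- c("detections", "data.frame")
  out
}

# area of intersection of two circles of equal radius r at distance d
circle_overlap_area <- function(d, r) {
  ifelse(d >= 2 * r, 0,
         2 * r^2 * acos(pmin(1, d / (2 * r))) -
           (d / 2) * sqrt(pmax(0, 4 * r^2 - d^2)))
}

# one frame-to-frame assignment; method "greedy" (descending overlap) or
# "optimal" (exhaustive over one side's subsets; oracle for small cases)
match_frames <- function(prev, cur, r, method = "greedy") {
  np <- nrow(prev); ncur <- nrow(cur)
  if (np == 0 || ncur == 0) return(cbind(integer(0), integer(0)))
  d <- sqrt(outer(prev$row, cur$row, "-")^2 +
              outer(prev$col, cur$col, "-")^2)
  ov <- circle_overlap_area(d, r)
  if (method == "greedy") {
    pairs <- which(ov > 0, arr.ind = TRUE)
    if (nrow(pairs) == 0) return(cbind(integer(0), integer(0)))
    o <- order(-ov[pairs], d[pairs], pairs[, 1], pairs[, 2])
    pairs <- pairs[o, , drop = FALSE]
    used_p <- logical(np); used_c <- logical(ncur)
    keep <- matrix(0L, 0, 2)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_p[i] && !used_c[j]) {
        keep <- rbind(keep, c(i, j))
        used_p[i] <- TRUE; used_c[j] <- TRUE
      }
    }
    return(keep)
  }
  # optimal: maximize total overlap by recursion (small instances only)
  if (np > 10 || ncur > 10) stop("optimal assignment limited to <= 10 spots")
  best <- list(score = -1, pairs = NULL)
  recurse <- function(i, used_c, pairs, score) {
    if (i > np) {
      if (score > best$score) best <<- list(score = score, pairs = pairs)
      return()
    }
    recurse(i + 1L, used_c, pairs, score)  # leave i unmatched
    for (j in seq_len(ncur)) {
      if (!used_c[j] && ov[i, j] > 0) {
        used_c[j] <- TRUE
        recurse(i + 1L, used_c, rbind(pairs, c(i, j)), score + ov[i, j])
        used_c[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ncur), matrix(0L, 0, 2), 0)
  if (is.null(best$pairs)) cbind(integer(0), integer(0)) else best$pairs
}

#' Link per-frame detections into tracks by best circle overlap
#'
#' Greedy one-to-one assignment between consecutive frames maximizing the
#' overlap area of the detection circles; pairs whose circles do not
#' overlap (centroid distance >= 2 x radius) are never linked. Unmatched
#' detections start new tracks; a track with no match terminates (no gap
#' closing). Ties are broken by smaller centroid distance, then lower
#' (row, col). An exhaustive optimal-assignment mode is available for
#' validation on small instances.
#'
#' @param detections data.frame with columns `frame`, `row`, `col`,
#'   `intensity` (and `radius_px`), e.g. rows of [detect_spots()] results
#' @param radius_px circle radius in pixels (default from detections)
#' @param method "greedy" (default) or "optimal"
#' @return data.frame: `track_id`, `frame`, `row`, `col`, `intensity`
#' @export
link_detections <- function(detections, radius_px = NULL,
                            method = c("greedy", "optimal")) {
  method <- match.arg(method)
  req <- c("frame", "row", "col", "intensity")
  if (!all(req %in% names(detections)))
    stop("detections must have columns: ", paste(req, collapse = ", "))
  if (is.null(radius_px)) {
    if (!"radius_px" %in% names(detections))
      stop("radius_px not given and absent from detections")
    radius_px <- detections$radius_px[1]
  }
  # deduplicate identical coordinates within a frame
  key <- paste(detections$frame, detections$row, detections$col)
  if (anyDuplicated(key)) {
    warning("duplicate detections at identical coordinates; deduplicated")
    detections <- detections[!duplicated(key), , drop = FALSE]
  }
  frames <- sort(unique(detections$frame))
  det_by_frame <- split(detections, factor(detections$frame, levels = frames))
  next_id <- 1L
  out <- vector("list", length(frames))
  prev <- NULL
  prev_ids <- integer(0)
  for (fi in seq_along(frames)) {
    cur <- det_by_frame[[fi]]
    ids <- rep(NA_integer_, nrow(cur))
    contiguous <- fi > 1 && frames[fi] == frames[fi - 1] + 1
    if (contiguous && nrow(prev) > 0 && nrow(cur) > 0) {
      m <- match_frames(prev, cur, radius_px, method)
      if (nrow(m) > 0) ids[m[, 2]] <- prev_ids[m[, 1]]
    }
    for (j in which(is.na(ids))) {
      ids[j] <- next_id
      next_id <- next_id + 1L
    }
    out[[fi]] <- data.frame(track_id = ids, frame = cur$frame, row = cur$row,
                            col = cur$col, intensity = cur$intensity)
    prev <- cur
    prev_ids <- ids
  }
  res <- do.call(rbind, out)
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Run the full tracking pipeline on a movie stack
#'
#' Applies [shading_correct()], [smooth_frame()], [detect_spots()] and
#' [link_detections()] frame by frame, then converts pixel tracks to the
#' 1-D track schema by projecting centroids onto the movie's microtubule
#' axis (minus-end-positive position in nm).
#'
#' @param movie a `movie_stack` from [render_movie()], or a numeric array
#'   (rows x cols x frames)
#' @param pixel_size_nm,frame_interval_s metadata (taken from the
#'   `movie_stack` spec when available)
#' @param threshold_k segmentation MAD multiplier
#' @param axis_origin_px,axis_angle_deg axis mapping for the 1-D projection
#'   (defaults from the spec when available)
#' @param method linking method passed to [link_detections()]
#' @return list with `tracks` (1-D schema: `track_id`, `time_s`,
#'   `position_nm`, `intensity`), `tracks_px` (pixel-space tracks) and
#'   `detections`
#' @export
track_movie <- function(movie, pixel_size_nm = 133, frame_interval_s = NULL,
                        threshold_k = 3, axis_origin_px = NULL,
                        axis_angle_deg = NULL, method = "greedy") {
  if (inherits(movie, "movie_stack")) {
    spec <- movie$spec
    frames <- movie$frames
    pixel_size_nm <- spec$pixel_size_nm
    if (is.null(frame_interval_s)) frame_interval_s <- spec$frame_interval_s
    if (is.null(axis_origin_px)) axis_origin_px <- spec$axis_origin_px
    if (is.null(axis_angle_deg)) axis_angle_deg <- spec$axis_angle_deg
  } else {
    frames <- movie
    if (is.null(frame_interval_s)) stop("frame_interval_s required")
    if (is.null(axis_origin_px)) axis_origin_px <- c(dim(frames)[1] / 2, 2)
    if (is.null(axis_angle_deg)) axis_angle_deg <- 0
  }
  nf <- dim(frames)[3]
  det_list <- vector("list", nf)
  for (f in seq_len(nf)) {
    cor <- shading_correct(frames[, , f])
    img <- smooth_frame(cor)
    d <- detect_spots(img, pixel_size_nm = pixel_size_nm,
                      threshold_k = threshold_k, noise_frame = cor)
    if (nrow(d) > 0) d$frame <- f
    det_list[[f]] <- d
  }
  det <- do.call(rbind, det_list[vapply(det_list, nrow, 1L) > 0])
  if (is.null(det) || nrow(det) == 0)
    return(list(tracks = data.frame(track_id = integer(0),
                                    time_s = numeric(0),
                                    position_nm = numeric(0),
                                    intensity = numeric(0)),
                tracks_px = NULL, detections = det))
  tp <- link_detections(det, method = method)
  ang <- axis_angle_deg * pi / 180
  u <- c(sin(ang), cos(ang))
  pos <- ((tp$row - axis_origin_px[1]) * u[1] +
            (tp$col - axis_origin_px[2]) * u[2]) * pixel_size_nm
  tracks <- data.frame(track_id = tp$track_id,
                       time_s = (tp$frame - 1) * frame_interval_s,
                       position_nm = pos, intensity = tp$intensity)
  list(tracks = tracks, tracks_px = tp, detections = det)
}
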