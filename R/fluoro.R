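#' Build a square ROI grid over an imaging field
#'
#' Lays out `n_side x n_side` square regions of interest of physical size
#' `roi_um` (14 um by default, 2 px at 5.9 um/pixel), evenly spread over the
#' field. With the default 7.1 mm field this produces the standard 30 x 30 =
#' 900 ROI grid.
#'
#' @param dim_px field size in pixels: length-2 vector `(rows, cols)`, or a
#'   frame stack from [render_frames()].
#' @param px_um pixel size (um/pixel).
#' @param roi_um ROI side (um); must be at least one pixel.
#' @param n_side number of ROIs per side; default
#'   `min(30, floor(min(dim_px) / roi_px))`.
#' @return object of class `roi_grid`: list with `roi_px`, `n_side`,
#'   `dim_px`, and `rois` (data frame with grid row/col, pixel bounds
#'   `r0,r1,c0,c1`, and ROI center in um).
#' @export
build_roi_grid <- function(dim_px, px_um, roi_um = 14, n_side = NULL) {
  if (length(dim(dim_px)) == 3) dim_px <- dim(dim_px)[1:2]
  stopifnot(length(dim_px) == 2, all(dim_px >= 1), px_um > 0)
  if (roi_um < px_um) stop("roi_um must be at least one pixel", call. = FALSE)
  roi_px <- max(1L, as.integer(round(roi_um / px_um)))
  if (min(dim_px) < roi_px) {
    stop("field smaller than one ROI", call. = FALSE)
  }
  n_side <- as.integer(n_side %||% min(30L, floor(min(dim_px) / roi_px)))
  stopifnot(n_side >= 1, n_side * roi_px <= min(dim_px))
  stride <- as.integer(min(dim_px) %/% n_side)
  pad <- (stride - roi_px) %/% 2L
  idx <- expand.grid(row = seq_len(n_side), col = seq_len(n_side))
  r0 <- (idx$row - 1L) * stride + pad + 1L
  c0 <- (idx$col - 1L) * stride + pad + 1L
  rois <- data.frame(row = idx$row, col = idx$col,
                     r0 = r0, r1 = r0 + roi_px - 1L,
                     c0 = c0, c1 = c0 + roi_px - 1L)
  rois$cx_um <- (rois$c0 + rois$c1) / 2 * px_um - dim_px[2] * px_um / 2
  rois$cy_um <- (rois$r0 + rois$r1) / 2 * px_um - dim_px[1] * px_um / 2
  structure(list(roi_px = roi_px, roi_um = roi_um, px_um = px_um,
                 n_side = n_side, dim_px = as.integer(dim_px), rois = rois),
            class = "roi_grid")
}

#' Extract mean-fluorescence ROI traces from a frame stack
#'
#' The trace of ROI i at frame t is the mean pixel value inside the ROI.
#'
#' @param stack integer array `[rows, cols, frames]`.
#' @param grid an [build_roi_grid()] result matching the stack geometry.
#' @param frame_rate frames/s.
#' @return a [fluorescence_recording()].
#' @export
extract_roi_traces <- function(stack, grid, frame_rate = 33) {
  stopifnot(length(dim(stack)) == 3, inherits(grid, "roi_grid"))
  if (any(dim(stack)[1:2] < c(max(grid$rois$r1), max(grid$rois$c1)))) {
    stop("stack dimensions do not cover the ROI grid", call. = FALSE)
  }
  nf <- dim(stack)[3]
  nroi <- nrow(grid$rois)
  F <- matrix(0, nroi, nf)
  for (i in seq_len(nroi)) {
    r <- grid$rois[i, ]
    sub <- stack[r$r0:r$r1, r$c0:r$c1, , drop = FALSE]
    F[i, ] <- colMeans(matrix(sub, ncol = nf))
  }
  fluorescence_recording((seq_len(nf) - 1) / frame_rate, F, frame_rate,
                         roi_meta = grid$rois)
}

# Slow baseline estimate: block-wise running median (window_s wide overall),
# linearly interpolated back to frame resolution.
estimate_baseline <- function(x, frame_rate, window_s = 30) {
  nf <- length(x)
  block <- max(1L, as.integer(round(window_s / 3 * frame_rate)))
  nb <- max(1L, nf %/% block)
  starts <- (seq_len(nb) - 1L) * block + 1L
  ends <- c(starts[-1] - 1L, nf)
  med <- vapply(seq_len(nb), function(b) stats::median(x[starts[b]:ends[b]]),
                numeric(1))
  if (nb >= 3) {  # smooth over ~window_s (3 blocks)
    sm <- med
    sm[2:(nb - 1)] <- (med[1:(nb - 2)] + med[2:(nb - 1)] + med[3:nb]) / 3
    med <- sm
  }
  if (nb == 1) return(rep.int(med, nf))
  centers <- (starts + ends) / 2
  stats::approx(centers, med, xout = seq_len(nf), rule = 2)$y
}

#' Normalize traces to dF/F with drift correction
#'
#' Implements `dF/F_i(t) = (F_i(t) - F_{i,0} - drift_i(t)) / F_{i,0}`, where
#' the rest level `F_{i,0}` is the 10th percentile of the raw trace (robust
#' to sparse transients) and the drift is a slow running-median baseline
#' (default 30 s window) re-centered so the resting dF/F is zero. The
#' transformation is invertible given the stored `F0` and baseline.
#'
#' @param rec a [fluorescence_recording()].
#' @param window_s drift-estimation window (s); `Inf` or `NA` disables drift
#'   correction (a constant median baseline is used).
#' @param f0_quantile quantile defining the rest level (default 0.1).
#' @return object of class `normalized_traces`: `dff` (roi x frame), `F0`,
#'   `baseline` (the subtracted roi x frame drift term), `times`,
#'   `frame_rate`.
#' @export
normalize_traces <- function(rec, window_s = 30, f0_quantile = 0.1) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  n <- nrow(rec$F)
  nf <- ncol(rec$F)
  F0 <- apply(rec$F, 1, stats::quantile, probs = f0_quantile, names = FALSE)
  if (any(F0 <= 0)) {
    stop("nonpositive rest fluorescence F0; traces cannot be normalized",
         call. = FALSE)
  }
  base <- matrix(0, n, nf)
  for (i in seq_len(n)) {
    base[i, ] <- if (is.finite(window_s)) {
      estimate_baseline(rec$F[i, ], rec$frame_rate, window_s)
    } else rep.int(stats::median(rec$F[i, ]), nf)
  }
  dff <- (rec$F - base) / F0
  structure(list(dff = dff, F0 = F0, baseline = base, times = rec$times,
                 frame_rate = rec$frame_rate, roi_meta = rec$roi_meta),
            class = "normalized_traces")
}

# Per-trace robust noise statistics of a dF/F trace.
dff_noise_stats <- function(x) {
  mu <- stats::median(x)
  list(mu = mu, sigma = stats::mad(x, center = mu))
}

#' Hysteretic (Schmitt-trigger) event detection on dF/F traces
#'
#' An event opens at the first crossing above the high threshold and closes
#' when the signal falls back below the low threshold; the hysteresis
#' guarantees no retriggering between the two thresholds. Events shorter than
#' `min_frames` (time above the low threshold) are discarded. The reported
#' onset is refined by backtracking from the threshold run to the transient
#' foot: the last preceding frame at or below the noise floor (median + 0.5
#' MAD-sd), which compensates the indicator rise time.
#'
#' When `high`/`low` are `NULL` they default per trace to the noise floor
#' median + 4 and + 2 MAD-based noise sd, respectively. The foot search runs
#' on a 3-frame centered running mean of the trace, which sharpens the foot
#' localization without delaying it. A short post-event dead time
#' (`dead_time_s`) prevents the decaying tail of a transient from
#' re-triggering a second event.
#'
#' @param traces a [normalized_traces()] object.
#' @param high,low thresholds in dF/F units (`high > low > 0`), or `NULL`
#'   for the per-trace automatic rule.
#' @param min_frames minimum event duration in frames.
#' @param refine_onset backtrack the onset to the transient foot (default
#'   TRUE); if FALSE the onset is the first frame above the low threshold of
#'   the triggering run.
#' @param max_back_s backtracking horizon (s).
#' @param dead_time_s runs starting within this interval after the previous
#'   event's closure are treated as its continuation.
#' @return a [spike_raster()] of event onset times.
#' @export
schmitt_detect <- function(traces, high = NULL, low = NULL, min_frames = 3,
                           refine_onset = TRUE, max_back_s = 1,
                           dead_time_s = 0.3) {
  stopifnot(inherits(traces, "normalized_traces"), min_frames >= 1)
  if (!is.null(high) || !is.null(low)) {
    if (is.null(high) || is.null(low) || !(high > low) || !(low > 0)) {
      stop("thresholds must satisfy high > low > 0", call. = FALSE)
    }
  }
  n <- nrow(traces$dff)
  nf <- ncol(traces$dff)
  fr <- traces$frame_rate
  max_back <- as.integer(round(max_back_s * fr))
  dead_frames <- as.integer(round(dead_time_s * fr))
  events <- vector("list", n)
  for (i in seq_len(n)) {
    x <- traces$dff[i, ]
    xs <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
    xs[is.na(xs)] <- x[is.na(xs)]
    if (is.null(high)) {
      ns <- dff_noise_stats(x)
      if (ns$sigma <= 0) { events[[i]] <- numeric(0); next }
      hi <- ns$mu + 4 * ns$sigma
      lo <- ns$mu + 2 * ns$sigma
      foot <- ns$mu + 0.5 * ns$sigma
    } else {
      hi <- high
      lo <- low
      foot <- low / 2
    }
    above <- x > lo
    r <- rle(above)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_frames)
    onsets <- integer(0)
    prev_end <- 0L
    for (k in ok) {
      s <- run_start[k]
      e <- run_end[k]
      if (!any(x[s:e] > hi)) next
      if (length(onsets) && (s - prev_end) <= dead_frames) {
        prev_end <- e  # decay-tail retrigger: extend the previous event
        next
      }
      onset <- s
      if (refine_onset) {
        lo_idx <- max(1L, s - max_back, prev_end + 1L)
        back <- which(xs[lo_idx:(s - 1L)] <= foot)
        if (s > lo_idx && length(back)) onset <- lo_idx + back[length(back)] - 1L
      }
      onsets <- c(onsets, onset)
      prev_end <- e
    }
    events[[i]] <- (onsets - 1L) / fr
  }
  spike_raster(events, n, nf / fr)
}

#' Keep only ROIs with significant calcium transients
#'
#' Filters a gridded recording down to the active subset: an ROI is kept when
#' its peak dF/F reaches `amp_min` and it has at least `min_events`
#' Schmitt-detected events. On a 900-ROI field with ~100 active neurons this
#' reduces the set to about 100 ROIs.
#'
#' @param rec a [fluorescence_recording()].
#' @param amp_min minimum peak dF/F (default 0.1).
#' @param min_events minimum number of detected events (default 1).
#' @param window_s drift window passed to [normalize_traces()].
#' @return the filtered `fluorescence_recording`, with attributes
#'   `kept` (indices), `n_kept`, `n_discarded`.
#' @export
filter_active_rois <- function(rec, amp_min = 0.1, min_events = 1,
                               window_s = 30) {
  stopifnot(inherits(rec, "fluorescence_recording"))
  norm <- normalize_traces(rec, window_s = window_s)
  ras <- schmitt_detect(norm)
  peak <- apply(norm$dff, 1, max)
  keep <- which(peak >= amp_min & lengths(ras$events) >= min_events)
  if (length(keep) < 10) {
    warning(sprintf("only %d ROIs passed the activity filter", length(keep)))
  }
  out <- fluorescence_recording(rec$times, rec$F[keep, , drop = FALSE],
                                rec$frame_rate,
                                roi_meta = if (!is.null(rec$roi_meta))
                                  rec$roi_meta[keep, , drop = FALSE])
  attr(out, "kept") <- keep
  attr(out, "n_kept") <- length(keep)
  attr(out, "n_discarded") <- nrow(rec$F) - length(keep)
  out
}

#' Population activity in a sliding window
#'
#' Fraction of neurons with at least one event in a sliding window (default
#' 0.5 s wide, 0.1 s step). The last window starts at `duration - window`;
#' no partial windows are used.
#'
#' @param raster a [spike_raster()].
#' @param window window width (s).
#' @param step window step (s).
#' @return object of class `population_activity`: `t_centers`,
#'   `fraction_active`, `window`, `step`, `n_neurons`.
#' @export
population_activity <- function(raster, window = 0.5, step = 0.1) {
  stopifnot(inherits(raster, "spike_raster"), raster$duration > 0,
            window > 0, step > 0, raster$duration >= window)
  n_w <- as.integer(floor((raster$duration - window) / step + 1e-9)) + 1L
  starts <- (seq_len(n_w) - 1) * step
  n <- raster$n_neurons
  active <- matrix(FALSE, n, n_w)
  for (i in seq_len(n)) {
    for (t in raster$events[[i]]) {
      lo <- max(1L, as.integer(floor((t - window) / step)) + 1L)
      hi <- min(n_w, as.integer(floor(t / step)) + 1L)
      if (lo > hi) next
      w <- lo:hi
      w <- w[starts[w] <= t & t < starts[w] + window]
      active[i, w] <- TRUE
    }
  }
  structure(list(t_centers = starts + window / 2,
                 fraction_active = colSums(active) / n,
                 window = window, step = step, n_neurons = n),
            class = "population_activity")
}

#' Detect synchronization peaks in a population-activity series
#'
#' Local maxima whose height reaches mean + `z_pk` sd of the series and at
#' least `min_fraction` of the network (so that isolated coincidences of a
#' couple of neurons on an otherwise quiet background do not count as
#' collective events); peaks closer than `merge_s` are merged (the higher
#' one is kept). Sharp peaks mark episodes of network-wide synchronous
#' activity.
#'
#' @param pa a [population_activity()] object.
#' @param z_pk threshold in sds above the series mean (default 3).
#' @param min_fraction absolute floor on the co-active fraction (default
#'   0.2).
#' @param merge_s minimum separation between reported peaks (s); defaults to
#'   the window width.
#' @return numeric vector of peak times (s, window centers).
#' @export
detect_sync_peaks <- function(pa, z_pk = 3, min_fraction = 0.2,
                              merge_s = NULL) {
  stopifnot(inherits(pa, "population_activity"))
  merge_s <- merge_s %||% pa$window
  s <- pa$fraction_active
  sdv <- stats::sd(s)
  if (!is.finite(sdv) || sdv == 0) return(numeric(0))
  thr <- max(mean(s) + z_pk * sdv, min_fraction)
  m <- length(s)
  left <- c(-Inf, s[-m])
  right <- c(s[-1], -Inf)
  cand <- which(s >= thr & s >= left & s >= right)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(s[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in cand) {
    t <- pa$t_centers[i]
    if (!length(kept) || all(abs(kept - t) >= merge_s)) kept <- c(kept, t)
  }
  sort(kept)
}

#' Population activity CSV writer
#'
#' @param pa a [population_activity()] object.
#' @param path CSV path.
#' @export
write_population_activity <- function(pa, path) {
  utils::write.csv(data.frame(t_center_s = pa$t_centers,
                              fraction_active = pa$fraction_active),
                   path, row.names = FALSE)
  write_sidecar(path, params = list(window = pa$window, step = pa$step,
                                    n_neurons = pa$n_neurons))
  invisible(path)
}

#' Trace table CSV I/O
#'
#' Wide table: first column time (s), one column per ROI.
#'
#' @param rec a [fluorescence_recording()].
#' @param path CSV path.
#' @param frame_rate frames/s for the reader (inferred from the time column
#'   when omitted).
#' @return `path` (write) or a `fluorescence_recording` (read).
#' @export
write_traces <- function(rec, path) {
  df <- data.frame(time_s = rec$times, t(rec$F))
  names(df)[-1] <- paste0("roi_", seq_len(nrow(rec$F)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, frame_rate = NULL) {
  df <- utils::read.csv(path)
  times <- df[[1]]
  fr <- frame_rate %||% (1 / stats::median(diff(times)))
  fluorescence_recording(times, t(as.matrix(df[, -1, drop = FALSE])), fr)
}
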