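#' Parameters of the synthetic calcium reporter
#'
#' Each activity event adds a difference-of-exponentials fluorescence kernel
#' (fast rise, slow decay) to the trace, normalized so the kernel peak equals
#' `amplitude_per_spike * baseline_F0`. Defaults emulate GCaMP6s kinetics
#' (0.2 s rise, 1.0 s decay) imaged at 33 frames/s.
#'
#' @param amplitude_per_spike transient peak in dF/F units.
#' @param rise_time,decay_time kernel time constants (s); `decay_time` must
#'   exceed `rise_time`.
#' @param baseline_F0 resting fluorescence (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param drift_amplitude amplitude of a slow sinusoidal baseline drift (a.u.);
#'   each trace gets a random phase.
#' @param drift_period drift period (s).
#' @param frame_rate acquisition rate (frames/s).
#' @param seed integer RNG seed.
#' @return list of class `calcium_params`.
#' @export
calcium_params <- function(amplitude_per_spike = 0.8, rise_time = 0.2,
                           decay_time = 1.0, baseline_F0 = 100,
                           noise_sd = 2, drift_amplitude = 0,
                           drift_period = 300, frame_rate = 33, seed = 1) {
  stopifnot(decay_time > rise_time, rise_time > 0, frame_rate > 0,
            baseline_F0 > 0, noise_sd >= 0, drift_amplitude >= 0,
            drift_period > 0, amplitude_per_spike >= 0)
  structure(as.list(environment()), class = "calcium_params")
}

# Difference-of-exponentials kernel, peak-normalized to 1.
calcium_kernel <- function(t, rise, decay) {
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  norm <- exp(-tpk / decay) - exp(-tpk / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / norm)
}

#' Render fluorescence traces from a spike raster
#'
#' @param raster a [spike_raster()].
#' @param params a [calcium_params()] object.
#' @return object of class `fluorescence_recording`: `times` (s), `F`
#'   (roi x frame matrix, a.u., clipped at 0), `frame_rate`, `roi_meta`.
#' @export
render_fluorescence <- function(raster, params) {
  stopifnot(inherits(raster, "spike_raster"), inherits(params, "calcium_params"))
  p <- params
  nf <- as.integer(round(raster$duration * p$frame_rate))
  times <- (seq_len(nf) - 1) / p$frame_rate
  n <- raster$n_neurons
  span <- 8 * p$decay_time
  amp <- p$amplitude_per_spike * p$baseline_F0
  with_seed(p$seed, {
    phases <- stats::runif(n, 0, 2 * pi)
    F <- matrix(0, n, nf)
    for (i in seq_len(n)) {
      tr <- rep.int(p$baseline_F0, nf)
      for (s in raster$events[[i]]) {
        i1 <- max(1L, as.integer(ceiling(s * p$frame_rate - 1e-9)) + 1L)
        i2 <- min(nf, as.integer(floor((s + span) * p$frame_rate)) + 1L)
        if (i1 > i2) next
        tr[i1:i2] <- tr[i1:i2] +
          amp * calcium_kernel(times[i1:i2] - s, p$rise_time, p$decay_time)
      }
      if (p$drift_amplitude > 0) {
        tr <- tr + p$drift_amplitude * sin(2 * pi * times / p$drift_period + phases[i])
      }
      if (p$noise_sd > 0) tr <- tr + stats::rnorm(nf, 0, p$noise_sd)
      F[i, ] <- pmax(tr, 0)
    }
    fluorescence_recording(times, F, p$frame_rate)
  })
}

#' Fluorescence recording container
#'
#' @param times frame times (s), uniformly sampled.
#' @param F roi x frame matrix of mean fluorescence (a.u., nonnegative).
#' @param frame_rate frames/s.
#' @param roi_meta optional data frame of ROI positions/sizes.
#' @return object of class `fluorescence_recording`.
#' @export
fluorescence_recording <- function(times, F, frame_rate, roi_meta = NULL) {
  stopifnot(is.matrix(F), length(times) == ncol(F), frame_rate > 0,
            all(F >= 0))
  structure(list(times = times, F = F, frame_rate = frame_rate,
                 roi_meta = roi_meta),
            class = "fluorescence_recording")
}

#' @export
print.fluorescence_recording <- function(x, ...) {
  cat(sprintf("<fluorescence_recording> %d ROIs x %d frames at %.1f fps (%.1f s)\n",
              nrow(x$F), ncol(x$F), x$frame_rate,
              ncol(x$F) / x$frame_rate))
  invisible(x)
}

#' Render an 8-bit frame stack from traces and neuron positions
#'
#' Each neuron is drawn as a Gaussian spot at its projected (x, y) position,
#' with brightness proportional to its fluorescence trace, on a uniform
#' background, quantized to 8-bit gray scale. Defaults reproduce a
#' 7.1 x 7.1 mm field at 5.9 um/pixel (1203 x 1203 px).
#'
#' @param recording a [fluorescence_recording()] (one trace per neuron).
#' @param net a `ground_truth_network` supplying neuron positions (um,
#'   centered on the field center).
#' @param field_mm side of the square imaging field (mm).
#' @param px_um pixel size (um/pixel).
#' @param spot_sd_um Gaussian spot sd (um).
#' @param gain a.u.-to-gray conversion gain.
#' @param background background gray level.
#' @return 8-bit integer array `[rows, cols, frames]` with attributes
#'   `px_um` and `field_mm`.
#' @export
render_frames <- function(recording, net, field_mm = 7.1, px_um = 5.9,
                          spot_sd_um = 6, gain = 1, background = 10) {
  stopifnot(inherits(recording, "fluorescence_recording"),
            inherits(net, "ground_truth_network"),
            nrow(recording$F) == net$n_neurons)
  npx <- as.integer(floor(field_mm * 1000 / px_um))
  half <- field_mm * 1000 / 2
  if (any(abs(net$positions[, 1:2]) > half)) {
    stop("neuron positions do not fit in the imaging field", call. = FALSE)
  }
  xy <- net$positions[, 1:2, drop = FALSE]
  if (net$n_neurons > 1) {
    dd <- as.matrix(stats::dist(xy))
    diag(dd) <- Inf
    if (min(dd) < 14) {
      warning("two neurons project within one ROI width (14 um); their traces will mix")
    }
  }
  cx <- (xy[, 1] + half) / px_um + 0.5
  cy <- (xy[, 2] + half) / px_um + 0.5
  sd_px <- spot_sd_um / px_um
  w <- as.integer(ceiling(3 * sd_px))
  nf <- ncol(recording$F)
  stack <- array(as.integer(round(background)), dim = c(npx, npx, nf))
  for (i in seq_len(net$n_neurons)) {
    r0 <- max(1L, as.integer(round(cy[i])) - w)
    r1 <- min(npx, as.integer(round(cy[i])) + w)
    c0 <- max(1L, as.integer(round(cx[i])) - w)
    c1 <- min(npx, as.integer(round(cx[i])) + w)
    if (r0 > r1 || c0 > c1) next
    prof <- outer(
      exp(-((r0:r1) - cy[i])^2 / (2 * sd_px^2)),
      exp(-((c0:c1) - cx[i])^2 / (2 * sd_px^2)))
    for (t in seq_len(nf)) {
      add <- as.integer(round(gain * recording$F[i, t] * prof))
      blk <- stack[r0:r1, c0:c1, t] + add
      stack[r0:r1, c0:c1, t] <- pmin(blk, 255L)
    }
  }
  attr(stack, "px_um") <- px_um
  attr(stack, "field_mm") <- field_mm
  stack
}

#' Multi-page 8-bit grayscale TIFF I/O for frame stacks
#'
#' @param stack integer array `[rows, cols, frames]`, values 0--255.
#' @param path TIFF file path.
#' @return `path` (write) or an integer array (read).
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3, all(stack >= 0), all(stack <= 255))
  frames <- lapply(seq_len(dim(stack)[3]), function(t) stack[, , t] / 255)
  tiff::writeTIFF(frames, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0L, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- as.integer(frames[[t]])
  arr
}
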