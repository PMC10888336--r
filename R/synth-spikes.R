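#' Spike raster container
#'
#' Per-neuron sorted event (activation onset) times in seconds over a fixed
#' recording duration. Produced both by the spiking simulator and by the
#' Schmitt-trigger detector, so inferred rasters can be compared directly with
#' ground truth.
#'
#' @param events list of numeric vectors (one per neuron, seconds, sorted).
#' @param n_neurons neuron count (defaults to `length(events)`).
#' @param duration recording duration (s).
#' @return object of class `spike_raster`.
#' @export
spike_raster <- function(events, n_neurons = length(events), duration) {
  stopifnot(duration > 0, length(events) == n_neurons)
  events <- lapply(events, function(e) sort(as.numeric(e)))
  bad <- vapply(events, function(e) length(e) && (min(e) < 0 || max(e) > duration),
                logical(1))
  if (any(bad)) stop("event times must lie within [0, duration]", call. = FALSE)
  structure(list(events = events, n_neurons = as.integer(n_neurons),
                 duration = duration),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  ne <- sum(lengths(x$events))
  cat(sprintf("<spike_raster> %d neurons, %d events over %.1f s (%.2f events/neuron/min)\n",
              x$n_neurons, ne, x$duration,
              ne / x$n_neurons / (x$duration / 60)))
  invisible(x)
}

#' Simulation parameters for the stochastic spiking cascade
#'
#' The simulator is a discrete-time stochastic cascade: in each time bin a
#' neuron fires with probability `baseline_rate * dt` plus
#' `coupling_scale * (weighted active presynaptic inputs one transmission
#' delay earlier)`, clipped to \[0, 1\], subject to an absolute refractory
#' period. Network-wide synchronous events are modeled as a global Poisson
#' drive that recruits a random 60--90% subset of neurons in one bin. This is
#' the minimal model whose directed causality a transfer-entropy analysis can
#' provably detect.
#'
#' @param duration recording duration (s).
#' @param dt simulation time step (s).
#' @param baseline_rate spontaneous event rate per neuron (events/s).
#' @param coupling_scale added firing probability per active presynaptic
#'   input (dimensionless).
#' @param transmission_delay axonal + synaptic delay (s); rounded to bins,
#'   minimum one bin.
#' @param refractory absolute refractory period (s).
#' @param sync_drive_rate rate of network-burst drive events (events/s); 0
#'   disables synchronous drive.
#' @param sync_recruit range of the recruited fraction per drive event.
#' @param sync_strength firing probability given to recruited neurons.
#' @param inhibition_strength if > 0, active inhibitory presynaptic inputs
#'   subtract `inhibition_strength * coupling_scale` each. Default 0 keeps the
#'   purely additive cascade.
#' @param seed integer RNG seed.
#' @return a validated list of class `spike_sim_params`.
#' @export
spike_sim_params <- function(duration = 900, dt = 0.03,
                             baseline_rate = 0.05, coupling_scale = 0.25,
                             transmission_delay = dt, refractory = 0.09,
                             sync_drive_rate = 0, sync_recruit = c(0.6, 0.9),
                             sync_strength = 0.8, inhibition_strength = 0,
                             seed = 1) {
  stopifnot(dt > 0, duration > 0, baseline_rate >= 0, coupling_scale >= 0,
            transmission_delay > 0, refractory >= 0, sync_drive_rate >= 0,
            length(sync_recruit) == 2, all(sync_recruit > 0),
            all(sync_recruit <= 1), inhibition_strength >= 0)
  structure(as.list(environment()), class = "spike_sim_params")
}

#' Simulate spontaneous activity on a ground-truth network
#'
#' @param net a [generate_network()] result.
#' @param params a [spike_sim_params()] object.
#' @return a [spike_raster()] with the ground-truth network attached as
#'   attribute `"net"` and the parameters as attribute `"params"`.
#' @export
simulate_spikes <- function(net, params) {
  stopifnot(inherits(net, "ground_truth_network"),
            inherits(params, "spike_sim_params"))
  p <- params
  if (p$duration < 10 * p$dt) {
    stop("duration must be at least 10 simulation steps", call. = FALSE)
  }
  n <- net$n_neurons
  nt <- round(p$duration / p$dt)
  delay_bins <- max(1L, as.integer(round(p$transmission_delay / p$dt)))
  refr_bins <- as.integer(round(p$refractory / p$dt))
  p_base <- p$baseline_rate * p$dt

  W <- net$weights * p$coupling_scale
  if (p$inhibition_strength > 0) {
    W[!net$excitatory_mask, ] <- -W[!net$excitatory_mask, ] * p$inhibition_strength
  }

  with_seed(p$seed, {
    # pre-draw synchronous drive events
    drive <- vector("list", nt)
    if (p$sync_drive_rate > 0) {
      nd <- stats::rpois(1, p$sync_drive_rate * p$duration)
      if (nd > 0) {
        bins <- sample.int(nt, nd, replace = TRUE)
        for (b in bins) {
          frac <- stats::runif(1, p$sync_recruit[1], p$sync_recruit[2])
          drive[[b]] <- sample.int(n, round(frac * n))
        }
      }
    }
    fired <- vector("list", nt)
    last <- rep.int(-1e9L, n)
    for (t in seq_len(nt)) {
      prob <- rep.int(p_base, n)
      if (t > delay_bins) {
        act <- fired[[t - delay_bins]]
        if (length(act)) {
          prob <- prob + colSums(W[act, , drop = FALSE])
        }
      }
      dr <- drive[[t]]
      if (!is.null(dr)) prob[dr] <- prob[dr] + p$sync_strength
      prob <- pmin(pmax(prob, 0), 1)
      elig <- (t - last) > refr_bins
      f <- which(elig & stats::runif(n) < prob)
      if (length(f)) {
        last[f] <- t
        fired[[t]] <- f
      }
    }
    events <- vector("list", n)
    for (i in seq_len(n)) events[[i]] <- numeric(0)
    nonempty <- which(lengths(fired) > 0)
    if (length(nonempty)) {
      all_t <- rep.int(nonempty, lengths(fired[nonempty]))
      all_i <- unlist(fired[nonempty], use.names = FALSE)
      times <- (all_t - 0.5) * p$dt  # bin centers
      ord <- split(times, factor(all_i, levels = seq_len(n)))
      events <- lapply(ord, sort)
    }
    ras <- spike_raster(events, n, p$duration)
    attr(ras, "net") <- net
    attr(ras, "params") <- p
    ras
  })
}

#' Mean firing rate of a raster
#'
#' Total number of events divided by (neurons x minutes), i.e. activations
#' per neuron per minute.
#'
#' @param raster a [spike_raster()].
#' @return scalar rate (activations / neuron / min).
#' @export
firing_rate <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"), raster$duration > 0)
  sum(lengths(raster$events)) / raster$n_neurons / (raster$duration / 60)
}

#' Raster CSV I/O
#'
#' Two-column CSV (`neuron_id`, `time_s`), sorted by neuron then time. Times
#' are written with 17 significant digits so the write/read round trip is
#' exact.
#'
#' @param raster a [spike_raster()].
#' @param path CSV file path.
#' @param n_neurons,duration raster geometry for the reader (the file itself
#'   stores them in a JSON sidecar when written by [write_raster()]).
#' @return `path` (write) or a `spike_raster` (read).
#' @export
write_raster <- function(raster, path) {
  df <- data.frame(
    neuron_id = rep.int(seq_len(raster$n_neurons), lengths(raster$events)),
    time_s = sprintf("%.17g", unlist(raster$events, use.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, params = list(n_neurons = raster$n_neurons,
                                    duration = raster$duration))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, n_neurons = NULL, duration = NULL) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side) && (is.null(n_neurons) || is.null(duration))) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)$params
    n_neurons <- n_neurons %||% meta$n_neurons
    duration <- duration %||% meta$duration
  }
  if (is.null(n_neurons)) n_neurons <- max(df$neuron_id, 0L)
  if (is.null(duration)) duration <- max(df$time_s, 1)
  ev <- split(as.numeric(df$time_s),
              factor(df$neuron_id, levels = seq_len(n_neurons)))
  spike_raster(unname(ev), n_neurons, duration)
}
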