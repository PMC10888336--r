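#' Ground truth for synthetic SAOS sweeps
#'
#' Describes the "true" viscoelastic behaviour behind a generated sweep
#' table: a low-frequency storage-modulus plateau with loss modulus a fixed
#' fraction of it (elasticity dominating by an order of magnitude at the
#' default `loss_ratio = 0.1`), power-law thickening above a high-frequency
#' onset, an exponential transient in time sweeps, and a slight negative
#' strain-amplitude trend.
#'
#' @param plateau_G1 true low-frequency storage modulus G' (Pa).
#' @param loss_ratio G''/G' before thickening (in (0, 1)).
#' @param thickening_onset frequency (rad/s) above which G' hardens.
#' @param thickening_exponent power-law exponent of the hardening.
#' @param transient_time_true settle time of the time-sweep transient (s):
#'   the time at which the underlying curve enters the +/-5% band of the
#'   terminal plateau.
#' @param transient_depth relative initial deviation of the time sweep from
#'   its plateau (positive = starts below the plateau).
#' @param strain_slope log-log slope of G' vs strain amplitude (slightly
#'   negative by default).
#' @param noise_cv relative (multiplicative, lognormal) noise level.
#' @param seed integer RNG seed.
#' @return list of class `rheo_truth`.
#' @export
rheo_truth <- function(plateau_G1 = 200, loss_ratio = 0.1,
                       thickening_onset = 50, thickening_exponent = 2,
                       transient_time_true = 300, transient_depth = 0.4,
                       strain_slope = -0.03, noise_cv = 0.05, seed = 1) {
  stopifnot(plateau_G1 > 0, loss_ratio > 0, loss_ratio < 1,
            thickening_onset > 0, thickening_exponent > 0,
            transient_time_true >= 0, transient_depth >= 0,
            transient_depth < 1, noise_cv >= 0)
  structure(as.list(environment()), class = "rheo_truth")
}

#' Default measurement grids for the three SAOS tests
#'
#' Time sweep: 15 min at fixed omega = 2*pi rad/s and gamma0 = 5%.
#' Strain sweep: gamma0 from 0.1 to 100% at omega = 2*pi rad/s.
#' Frequency sweep: omega from 0.6 to 600 rad/s at gamma0 = 5%.
#'
#' @param test one of "time", "strain", "frequency".
#' @return list with elements `t`, `omega`, `gamma0` as appropriate.
#' @export
default_sweep_grid <- function(test = c("frequency", "strain", "time")) {
  test <- match.arg(test)
  switch(test,
    time = list(t = seq(0, 900, by = 5), omega = 2 * pi, gamma0 = 5),
    strain = list(gamma0 = logseq(0.1, 100, 25), omega = 2 * pi),
    frequency = list(omega = logseq(0.6, 600, 30), gamma0 = 5))
}

#' Generate one synthetic SAOS sweep table
#'
#' Frequency sweeps show a plateau `G' = plateau_G1` for frequencies below
#' the thickening onset and power-law hardening beyond it; time sweeps relax
#' exponentially to the plateau with settle time `transient_time_true`;
#' strain sweeps are near-flat with a slight negative log-log slope.
#' `G'' = loss_ratio * G'` below the onset. Multiplicative lognormal noise
#' with coefficient of variation `noise_cv` is applied to both moduli. The
#' oscillation torque is emulated as `gamma0_frac * |G*|` (nN m), which puts
#' the lowest strain-sweep amplitudes below a 2 nN m instrument floor, as in
#' real strain sweeps.
#'
#' @param truth a [rheo_truth()] object.
#' @param test "time", "strain" or "frequency".
#' @param grid measurement grid as from [default_sweep_grid()].
#' @param DIV days-in-vitro label attached to the record.
#' @param replicate replicate id.
#' @return a `sweep_record`: data frame with columns `test_type`, `DIV`,
#'   `replicate`, `t_s`, `omega_rad_s`, `gamma0_pct`, `G1_Pa`, `G2_Pa`,
#'   `torque_nNm`.
#' @export
generate_sweeps <- function(truth, test = c("frequency", "strain", "time"),
                            grid = NULL, DIV = 1, replicate = 1) {
  stopifnot(inherits(truth, "rheo_truth"))
  test <- match.arg(test)
  grid <- grid %||% default_sweep_grid(test)
  tr <- truth
  band <- 0.05  # settle band fraction defining transient_time_true

  if (test == "frequency") {
    omega <- grid$omega
    if (!length(omega)) stop("empty frequency grid", call. = FALSE)
    gamma0 <- rep_len(grid$gamma0 %||% 5, length(omega))
    thick <- ifelse(omega > tr$thickening_onset,
                    ((omega - tr$thickening_onset) / tr$thickening_onset) ^
                      tr$thickening_exponent, 0)
    G1 <- tr$plateau_G1 * (1 + thick)
    G2 <- tr$loss_ratio * tr$plateau_G1 * rep_len(1, length(omega))
    t_s <- rep(NA_real_, length(omega))
  } else if (test == "strain") {
    gamma0 <- grid$gamma0
    if (!length(gamma0)) stop("empty strain grid", call. = FALSE)
    omega <- rep_len(grid$omega %||% (2 * pi), length(gamma0))
    G1 <- tr$plateau_G1 * (gamma0 / 5) ^ tr$strain_slope
    G2 <- tr$loss_ratio * G1
    t_s <- rep(NA_real_, length(gamma0))
  } else {
    t_s <- grid$t
    if (!length(t_s)) stop("empty time grid", call. = FALSE)
    omega <- rep_len(grid$omega %||% (2 * pi), length(t_s))
    gamma0 <- rep_len(grid$gamma0 %||% 5, length(t_s))
    if (tr$transient_time_true > 0 && tr$transient_depth > band) {
      tau <- tr$transient_time_true / log(tr$transient_depth / band)
      G1 <- tr$plateau_G1 * (1 - tr$transient_depth * exp(-t_s / tau))
    } else {
      G1 <- rep_len(tr$plateau_G1, length(t_s))
    }
    G2 <- tr$loss_ratio * G1
  }

  if (tr$noise_cv > 0) {
    with_seed(tr$seed, {
      G1 <- G1 * exp(stats::rnorm(length(G1), 0, tr$noise_cv))
      G2 <- G2 * exp(stats::rnorm(length(G2), 0, tr$noise_cv))
    })
  }
  torque <- (gamma0 / 100) * sqrt(G1^2 + G2^2)
  rec <- data.frame(test_type = test, DIV = DIV, replicate = replicate,
                    t_s = t_s, omega_rad_s = omega, gamma0_pct = gamma0,
                    G1_Pa = G1, G2_Pa = G2, torque_nNm = torque)
  class(rec) <- c("sweep_record", "data.frame")
  rec
}

#' Sweep table CSV I/O
#'
#' @param rec a `sweep_record` (or several row-bound together).
#' @param path CSV path.
#' @return `path` (write) or a `sweep_record` (read).
#' @export
write_sweeps <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  rec <- utils::read.csv(path)
  class(rec) <- c("sweep_record", "data.frame")
  rec
}
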