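#' Discard sweep rows below the instrument torque floor
#'
#' Oscillation torques below the rheometer's lower measurable limit (2 nN m
#' for the plate-plate setup emulated here) make the extracted moduli
#' unreliable; those rows are removed.
#'
#' @param rec a `sweep_record`.
#' @param floor torque floor (nN m).
#' @return the filtered `sweep_record`, with attribute `n_removed`. A record
#'   without a torque column passes through with a warning.
#' @export
filter_torque_floor <- function(rec, floor = 2) {
  stopifnot(is.data.frame(rec))
  if (!"torque_nNm" %in% names(rec)) {
    warning("no torque column; sweep passed through unfiltered")
    attr(rec, "n_removed") <- 0L
    attr(rec, "torque_missing") <- TRUE
    return(rec)
  }
  keep <- rec$torque_nNm >= floor
  if (!any(keep)) stop("all rows fall below the torque floor", call. = FALSE)
  out <- rec[keep, , drop = FALSE]
  class(out) <- class(rec)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Transient (settle) time of a time sweep
#'
#' Estimates the time tT the sample needs to reach mechanical equilibrium:
#' the earliest time after which G' stays within a +/-`band_pct` band of the
#' terminal-plateau mean (mean of the last 25% of samples). The default
#' method fits an exponential relaxation
#' `G'(t) = G_inf (1 + a exp(-t / tau))` and reports the time at which the
#' fitted curve enters the band, `tT = tau log(|a| / band)`, which is robust
#' to measurement noise; `method = "band"` applies the band rule directly to
#' a running-median-smoothed series.
#'
#' @param rec a time-sweep `sweep_record` with at least 20 samples.
#' @param band_pct band half-width in percent of the plateau (default 5).
#' @param method "fit" (default) or "band".
#' @return list with `tT` (s), `settled` (FALSE when the record never
#'   settles, in which case `tT` equals the record duration), `plateau`
#'   (terminal plateau, Pa), and `method` actually used.
#' @export
detect_transient <- function(rec, band_pct = 5, method = c("fit", "band")) {
  stopifnot(is.data.frame(rec))
  method <- match.arg(method)
  if (!all(rec$test_type == "time")) {
    stop("detect_transient expects a time-sweep record", call. = FALSE)
  }
  if (nrow(rec) < 20) stop("need at least 20 time samples", call. = FALSE)
  t <- rec$t_s
  g <- rec$G1_Pa
  ord <- order(t)
  t <- t[ord]
  g <- g[ord]
  band <- band_pct / 100
  plateau <- mean(g[t >= stats::quantile(t, 0.75)])

  band_rule <- function() {
    w <- max(5L, 2L * (length(g) %/% 40L) + 1L)
    sm <- stats::runmed(g, min(w, 2L * (length(g) %/% 2L) - 1L))
    ok <- abs(sm - plateau) / plateau <= band
    if (!any(!ok)) return(list(tT = t[1], settled = TRUE))
    i <- max(which(!ok)) + 1L
    if (i > length(t)) list(tT = max(t), settled = FALSE)
    else list(tT = t[i], settled = TRUE)
  }

  res <- if (method == "fit") {
    fit <- tryCatch({
      a0 <- (g[1] - plateau) / plateau
      minpack.lm::nlsLM(
        g ~ gi * (1 + a * exp(-t / tau)),
        start = list(gi = plateau, a = a0, tau = max(t) / 4),
        lower = c(gi = 1e-12, a = -0.999, tau = max(t) / 1e4),
        upper = c(gi = Inf, a = 10, tau = max(t) * 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      method <- "band"
      band_rule()
    } else {
      cf <- stats::coef(fit)
      plateau <- unname(cf["gi"])
      if (abs(cf["a"]) <= band) {
        list(tT = t[1], settled = TRUE)
      } else {
        tT <- unname(cf["tau"] * log(abs(cf["a"]) / band))
        if (tT >= max(t)) list(tT = max(t), settled = FALSE)
        else list(tT = max(tT, t[1]), settled = TRUE)
      }
    }
  } else band_rule()

  list(tT = res$tT, settled = res$settled, plateau = plateau, method = method)
}

#' Linear-viscoelastic-region check of a strain sweep
#'
#' Regresses log10 G' on log10 gamma0 and flags non-linearity when the
#' absolute slope exceeds `slope_max` (default 0.1 in log-log units; the gels
#' emulated here show only a slight negative trend). Also reports whether G'
#' stays above G'' throughout (the moduli should not cross in the LVR).
#'
#' @param rec a strain-sweep `sweep_record`.
#' @param slope_max flag threshold on |log-log slope|.
#' @return list with `slope`, `linear` (TRUE when |slope| <= slope_max),
#'   `crossing` (TRUE when G'' exceeds G' anywhere), `g1_over_g2` (median
#'   ratio).
#' @export
check_lvr <- function(rec, slope_max = 0.1) {
  stopifnot(is.data.frame(rec))
  if (!all(rec$test_type == "strain")) {
    stop("check_lvr expects a strain-sweep record", call. = FALSE)
  }
  fit <- stats::lm(log10(G1_Pa) ~ log10(gamma0_pct), data = rec)
  slope <- unname(stats::coef(fit)[2])
  list(slope = slope,
       linear = abs(slope) <= slope_max,
       crossing = any(rec$G2_Pa > rec$G1_Pa),
       g1_over_g2 = stats::median(rec$G1_Pa / rec$G2_Pa))
}

#' Plateau moduli of a frequency sweep
#'
#' Averages G' and G'' over the low-frequency plateau band (up to 10 rad/s
#' by default) with a geometric mean (moduli are log-distributed across
#' replicates), and locates the thickening onset: the first frequency at
#' which G' exceeds the plateau by more than `thicken_factor - 1` (default
#' +50%).
#'
#' @param rec a frequency-sweep `sweep_record`.
#' @param band_max upper edge of the plateau band (rad/s).
#' @param thicken_factor onset threshold as a multiple of the plateau.
#' @return object of class `modulus_summary`: `plateau_G1`, `plateau_G2`
#'   (Pa), `plateau_band` (rad/s), `thickening_onset` (rad/s or NA),
#'   `G1_over_G2`, `n_band`.
#' @export
plateau_modulus <- function(rec, band_max = 10, thicken_factor = 1.5) {
  stopifnot(is.data.frame(rec))
  if (!all(rec$test_type == "frequency")) {
    stop("plateau_modulus expects a frequency-sweep record", call. = FALSE)
  }
  in_band <- rec$omega_rad_s <= band_max
  if (sum(in_band) < 3) stop("fewer than 3 points in the plateau band",
                             call. = FALSE)
  gm <- function(v) exp(mean(log(v)))
  p1 <- gm(rec$G1_Pa[in_band])
  p2 <- gm(rec$G2_Pa[in_band])
  above <- rec$omega_rad_s[rec$G1_Pa > thicken_factor * p1 &
                             rec$omega_rad_s > band_max]
  structure(list(plateau_G1 = p1, plateau_G2 = p2,
                 plateau_band = c(min(rec$omega_rad_s[in_band]), band_max),
                 thickening_onset = if (length(above)) min(above) else NA_real_,
                 G1_over_G2 = p1 / p2, n_band = sum(in_band)),
            class = "modulus_summary")
}

#' Young's modulus from shear moduli
#'
#' `|G*| = sqrt(G'^2 + G''^2)` is the shear stiffness; the Young's modulus
#' follows from `E = 2 |G*| (1 + nu)` with Poisson ratio `nu` (0.25 for
#' fibrin matrices).
#'
#' @param G1 storage modulus G' (Pa).
#' @param G2 loss modulus G'' (Pa).
#' @param nu Poisson ratio.
#' @param DIV optional days-in-vitro label(s).
#' @return data frame of class `youngs_modulus` with columns `E`,
#'   `G_star_mod`, `nu`, `DIV`, `stage` (stage filled by [stage_group()]).
#' @export
youngs_modulus <- function(G1, G2 = 0, nu = 0.25, DIV = NA) {
  if (any(G1 < 0) || any(G2 < 0)) stop("moduli must be nonnegative", call. = FALSE)
  if (any(G1 == 0 & G2 == 0)) stop("G' and G'' cannot both be zero", call. = FALSE)
  gs <- sqrt(G1^2 + G2^2)
  out <- data.frame(E = 2 * gs * (1 + nu), G_star_mod = gs, nu = nu,
                    DIV = DIV, stage = NA_character_)
  class(out) <- c("youngs_modulus", "data.frame")
  out
}

#' Group modulus estimates into developmental stages
#'
#' Stages by days in vitro: early (DIV 1-3), young (DIV 4-8), mature
#' (DIV 13-20). DIVs outside those bins (e.g. 9-12) are flagged unassigned
#' with a warning.
#'
#' @param estimates a `youngs_modulus` data frame with a `DIV` column.
#' @return list with elements `early`, `young`, `mature` (subsets of the
#'   input with `stage` filled) and `unassigned`.
#' @export
stage_group <- function(estimates) {
  stopifnot(is.data.frame(estimates), "DIV" %in% names(estimates))
  if (nrow(estimates) == 0) {
    empty <- estimates
    return(list(early = empty, young = empty, mature = empty, unassigned = empty))
  }
  div <- estimates$DIV
  stage <- ifelse(div >= 1 & div <= 3, "early",
           ifelse(div >= 4 & div <= 8, "young",
           ifelse(div >= 13 & div <= 20, "mature", NA_character_)))
  if (anyNA(stage)) {
    warning(sprintf("%d estimate(s) with DIV outside the stage bins left unassigned",
                    sum(is.na(stage))))
  }
  estimates$stage <- stage
  split_by <- function(s) {
    out <- estimates[!is.na(stage) & stage == s, , drop = FALSE]
    class(out) <- class(estimates)
    out
  }
  un <- estimates[is.na(stage), , drop = FALSE]
  class(un) <- class(estimates)
  list(early = split_by("early"), young = split_by("young"),
       mature = split_by("mature"), unassigned = un)
}

#' Pairwise stage comparison of Young's moduli
#'
#' Two-sided two-sample Student's t-tests (equal variances by default;
#' `var_equal = FALSE` gives Welch) between the early/young, young/mature
#' and early/mature stage groups, with significance stars at p < 0.05 (*)
#' and p < 0.01 (**).
#'
#' @param groups a [stage_group()] result.
#' @param var_equal use the pooled-variance Student's test (default TRUE).
#' @return object of class `stage_comparison`: data frame `tests`
#'   (pair, p, stars) plus per-stage `means`, `sds`, `n`.
#' @export
compare_stages <- function(groups, var_equal = TRUE) {
  stages <- c("early", "young", "mature")
  e <- lapply(groups[stages], function(g) g$E)
  n <- vapply(e, length, integer(1))
  if (any(n < 2)) stop("each compared stage needs at least 2 estimates",
                       call. = FALSE)
  pairs <- list(c("early", "young"), c("young", "mature"), c("early", "mature"))
  p <- vapply(pairs, function(pr) {
    a <- e[[pr[1]]]
    b <- e[[pr[2]]]
    if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
      stop("degenerate (zero) variance in a stage group", call. = FALSE)
    }
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }, numeric(1))
  stars <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))
  structure(list(
    tests = data.frame(pair = vapply(pairs, paste, character(1), collapse = "-"),
                       p = p, stars = stars),
    means = vapply(e, mean, numeric(1)),
    sds = vapply(e, stats::sd, numeric(1)),
    n = n,
    test = if (var_equal) "Student t (equal variance)" else "Welch t"),
    class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat("<stage_comparison>", x$test, "\n")
  for (s in names(x$means)) {
    cat(sprintf("  %-6s E = %.0f +/- %.0f Pa (n=%d)\n",
                s, x$means[[s]], x$sds[[s]], x$n[[s]]))
  }
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("  %-14s p = %.4g %s\n", x$tests$pair[i], x$tests$p[i],
                x$tests$stars[i]))
  }
  invisible(x)
}
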