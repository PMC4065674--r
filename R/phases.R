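# Segmentation of a free-swelling trajectory into the five phases of the
# swelling response (initial equilibrium, water influx, swelling, ion
# re-equilibration, final equilibrium) plus shrink-delay metrics.

#' Segment a free-swelling trajectory into phases
#'
#' Phase boundaries are defined from the computed flux and displacement
#' series (all thresholds configurable): Phase I ends when the magnitude of
#' the top-surface water flux first exceeds `jw_start_frac` of its overall
#' maximum; the Phase II/III boundary is the time of maximal water influx;
#' Phase III/IV begins once the displacement reaches `plateau_frac` of its
#' peak; Phase IV/V begins when all three fluxes have fallen below
#' `quiet_frac` of their respective maxima. Shrink-delay metrics record the
#' most negative displacement and the first time the displacement exceeds
#' `positive_mm`.
#'
#' @param trajectory a `swell_trajectory` from [time_march()].
#' @param jw_start_frac,plateau_frac,quiet_frac phase thresholds.
#' @param positive_mm displacement threshold (mm) for "swelling has begun".
#' @return A list of class `phase_report`: `n_phases`, `boundaries_s` (ends
#'   of phases I-IV), `peak_u_mm`, `t_peak_s` (time of the maximum),
#'   `t_plateau_s` (plateau onset, first time at `plateau_frac` of the
#'   peak), `min_u_mm` (<= 0), `t_positive_s`, and `flux_signs` (per-phase
#'   sign of the mean water/cation/anion flux).
#' @export
detect_phases <- function(trajectory, jw_start_frac = 0.05,
                          plateau_frac = 0.99, quiet_frac = 0.01,
                          positive_mm = 1e-6) {
  t <- trajectory$times
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("invalid input: non-monotone time vector", call. = FALSE)
  }
  u <- trajectory$u_top_mm
  jw <- trajectory$Jw_top; jp <- trajectory$Jp_top; jm <- trajectory$Jm_top
  mk <- function(...) structure(list(...), class = "phase_report")

  if (!length(t) || max(abs(u)) < 1e-9) {
    return(mk(n_phases = 1L, boundaries_s = numeric(),
              peak_u_mm = 0, t_peak_s = NA_real_, t_plateau_s = NA_real_,
              min_u_mm = 0, t_positive_s = NA_real_,
              flux_signs = data.frame(phase = "equilibrium", Jw = 0,
                                      Jp = 0, Jm = 0)))
  }

  jw_max <- max(abs(jw)); jp_max <- max(abs(jp)); jm_max <- max(abs(jm))
  peak_u <- max(u)
  t_peak <- t[which.max(u)]
  # for a response that never swells past zero the "plateau" degenerates to
  # the first attainment of the maximum
  plateau_thr <- if (peak_u > 0) plateau_frac * peak_u else peak_u
  i_plateau <- which(u >= plateau_thr)[1]
  t_plateau <- t[i_plateau]
  i_II <- which(abs(jw) > jw_start_frac * jw_max)[1]
  # with a no-ramp bath step the flux can exceed the threshold already at
  # the first stored step; phase I then degenerates to the instant t = 0
  t_I_end <- if (is.na(i_II)) t[1] else if (i_II == 1L) 0 else t[i_II - 1L]
  t_II_end <- t[which.max(jw)]
  t_III_end <- max(t_plateau, t_II_end)
  quiet <- abs(jw) < quiet_frac * jw_max & abs(jp) < quiet_frac * jp_max &
    abs(jm) < quiet_frac * jm_max & t > t_III_end
  t_IV_end <- if (any(quiet)) t[which(quiet)[1]] else t[length(t)]
  bounds <- cummax(c(t_I_end, t_II_end, t_III_end, t_IV_end))
  names(bounds) <- c("I_end", "II_end", "III_end", "IV_end")

  phase_of <- findInterval(t, bounds, left.open = TRUE) + 1L
  sgn <- function(v) {
    s <- vapply(split(v, factor(phase_of, levels = 1:5)),
                function(z) if (length(z)) sign(mean(z)) else NA_real_,
                numeric(1))
    s
  }
  flux_signs <- data.frame(phase = c("I", "II", "III", "IV", "V"),
                           Jw = sgn(jw), Jp = sgn(jp), Jm = sgn(jm))
  min_u <- min(0, min(u))
  i_pos <- which(u > positive_mm)[1]
  mk(n_phases = 5L, boundaries_s = bounds,
     peak_u_mm = peak_u, t_peak_s = t_peak, t_plateau_s = t_plateau,
     min_u_mm = min_u,
     t_positive_s = if (is.na(i_pos)) NA_real_ else t[i_pos],
     flux_signs = flux_signs)
}

#' @export
print.phase_report <- function(x, ...) {
  if (x$n_phases == 1L) {
    cat("Phase report: single phase (equilibrium), no swelling response\n")
    return(invisible(x))
  }
  cat("Phase report (five phases)\n")
  cat(sprintf("  boundaries (s): I|%0.5g II|%0.5g III|%0.5g IV|%0.5g\n",
              x$boundaries_s[1], x$boundaries_s[2], x$boundaries_s[3],
              x$boundaries_s[4]))
  cat(sprintf("  peak u = %.6g mm at t = %.5g s (plateau onset %.5g s)\n",
              x$peak_u_mm, x$t_peak_s, x$t_plateau_s))
  cat(sprintf("  shrink-delay: min u = %.3g mm, positive swelling from t = %.5g s\n",
              x$min_u_mm, x$t_positive_s))
  invisible(x)
}
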