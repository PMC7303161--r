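#' Kinetic energy of a single voxel, in microjoules
#'
#' `KE = 1/2 * rho * V * v^2` with rho in g/cm^3, V in cm^3 and v in cm/s
#' yields erg; 1 erg = 0.1 uJ, so the returned value is
#' `0.05 * rho * V * v^2` uJ. Speed is a magnitude: negative inputs are
#' taken in absolute value (which the square makes immaterial).
#'
#' @param speed_cm_s voxel speed, cm/s
#' @param voxel_volume_cm3 voxel volume, cm^3
#' @param rho_g_cm3 blood density, g/cm^3 (default 1.06)
#' @return kinetic energy, uJ
#' @export
voxel_ke <- function(speed_cm_s, voxel_volume_cm3, rho_g_cm3 = .RHO_BLOOD) {
  stopifnot(voxel_volume_cm3 > 0, rho_g_cm3 > 0)
  .KE_UJ_FACTOR * rho_g_cm3 * voxel_volume_cm3 * abs(speed_cm_s)^2
}

#' Time-resolved RV kinetic energy curve
#'
#' For each cardiac phase the total KE inside the ventricle is the sum of
#' [voxel_ke()] over the masked voxels; the EDV-normalised curve KEi_EDV
#' divides by the end-diastolic volume (in uJ/ml). The EDV used for
#' normalisation should come from the cine-derived volumetrics, not the
#' flow-grid mask.
#'
#' @param field a `velocity_field`
#' @param masks an `rv_masks` object aligned with the field grid
#' @param edv_ml end-diastolic volume for normalisation, ml
#' @param rho_g_cm3 blood density, g/cm^3
#' @return object of class `ke_curve`: `ke_uJ`, `kei_uJ_ml` (per phase),
#'   `time_ms`, `edv_ml`, `phase_ms`, `rho_g_cm3`
#' @export
ke_curve <- function(field, masks, edv_ml, rho_g_cm3 = .RHO_BLOOD) {
  np <- n_phases(field)
  stopifnot(inherits(masks, "rv_masks"),
            all(dim(masks$mask)[1:3] == dim(field$v)[1:3]),
            dim(masks$mask)[4L] == np, edv_ml > 0)
  vvox <- voxel_volume_cm3(field)
  ke <- numeric(np)
  for (t in seq_len(np)) {
    m <- masks$mask[, , , t]
    if (!any(m)) stop("phase ", t, ": empty RV mask, KE curve invalid")
    sp2 <- field$v[, , , t, 1L][m]^2 + field$v[, , , t, 2L][m]^2 +
           field$v[, , , t, 3L][m]^2
    ke[t] <- .KE_UJ_FACTOR * rho_g_cm3 * vvox * sum(sp2)
  }
  structure(list(ke_uJ = ke, kei_uJ_ml = ke / edv_ml,
                 time_ms = (seq_len(np) - 1) * field$phase_ms,
                 edv_ml = edv_ml, phase_ms = field$phase_ms,
                 rho_g_cm3 = rho_g_cm3),
            class = "ke_curve")
}

#' @export
print.ke_curve <- function(x, ...) {
  cat(sprintf("<ke_curve> %d phases; KE %.1f..%.1f uJ; KEi_EDV %.2f..%.2f uJ/ml (EDV %.1f ml)\n",
              length(x$ke_uJ), min(x$ke_uJ), max(x$ke_uJ),
              min(x$kei_uJ_ml), max(x$kei_uJ_ml), x$edv_ml))
  invisible(x)
}

#' Cardiac timing: systole, diastole and E/A windows
#'
#' End-systole is the phase of minimum ventricular volume (earliest on flat
#' minima); systole spans phases 1..ES and diastole the remainder. The
#' diastolic KEi curve is split into an early-filling (E) and a late-filling
#' (A) window: when two distinct diastolic KE maxima exist, the boundary is
#' the KE minimum between the two largest maxima; otherwise diastole is
#' split at its temporal midpoint and the timing is flagged.
#'
#' @param volume_ml per-phase ventricular volume, ml
#' @param kei per-phase KEi_EDV curve (a `ke_curve` or numeric vector)
#' @return object of class `cardiac_timing`: `es_phase`, `systole`,
#'   `diastole`, `e_window`, `a_window`, `midpoint_fallback`
#' @export
detect_cardiac_phases <- function(volume_ml, kei) {
  if (inherits(kei, "ke_curve")) kei <- kei$kei_uJ_ml
  np <- length(volume_ml)
  stopifnot(np >= 8L, length(kei) == np)
  es <- which.min(volume_ml)
  if (es == np || all(diff(volume_ml) <= 0) || all(diff(volume_ml) >= 0))
    stop("volume curve shows no refilling: cannot define diastole")
  dia <- (es + 1L):np
  kd <- kei[dia]
  ## interior local maxima of the diastolic KEi curve
  n <- length(kd)
  is_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) kd[i] > kd[i - 1L] else kd[i] > 0
    right <- if (i < n) kd[i] >= kd[i + 1L] else FALSE
    left && right
  }, TRUE))
  rng <- diff(range(kd))
  if (rng > 0) {
    prom <- kd[is_max] - min(kd)
    is_max <- is_max[prom > 0.05 * rng]
  }
  midpoint_fallback <- FALSE
  if (length(is_max) >= 2L) {
    top2 <- sort(is_max[order(kd[is_max], decreasing = TRUE)[1:2]])
    split <- top2[1L] + which.min(kd[top2[1L]:top2[2L]]) - 1L
  } else {
    split <- floor(n / 2)
    midpoint_fallback <- TRUE
  }
  structure(list(es_phase = es,
                 systole = 1L:es,
                 diastole = dia,
                 e_window = dia[seq_len(split)],
                 a_window = dia[(split + 1L):n],
                 midpoint_fallback = midpoint_fallback),
            class = "cardiac_timing")
}

#' @export
print.cardiac_timing <- function(x, ...) {
  cat(sprintf("<cardiac_timing> ES phase %d; E window %d..%d; A window %d..%d%s\n",
              x$es_phase, min(x$e_window), max(x$e_window),
              min(x$a_window), max(x$a_window),
              if (x$midpoint_fallback) " (midpoint fallback)" else ""))
  invisible(x)
}

#' Summary KE parameters of a cardiac cycle
#'
#' Derives the six physiological KE parameters from the time-resolved
#' KEi_EDV curve: global (mean over the whole cycle), systolic and
#' diastolic (means over their windows; peak-based alternatives are
#' available via `window_stat`), minimum over the cycle, peak E-wave and
#' peak A-wave (maxima over the respective diastolic windows) and their
#' ratio. Un-indexed twins in mJ are derived from the raw KE curve.
#'
#' @param curve a `ke_curve`
#' @param timing a `cardiac_timing`
#' @param window_stat statistic for the systolic/diastolic summaries:
#'   `"mean"` (default) or `"peak"`
#' @return object of class `ke_parameters`
#' @export
extract_ke_parameters <- function(curve, timing, window_stat = c("mean", "peak")) {
  window_stat <- match.arg(window_stat)
  stopifnot(inherits(curve, "ke_curve"), inherits(timing, "cardiac_timing"))
  kei <- curve$kei_uJ_ml
  agg <- if (window_stat == "mean") mean else max
  peak_e <- max(kei[timing$e_window])
  peak_a <- max(kei[timing$a_window])
  ea <- if (peak_a > 0) peak_e / peak_a else NA_real_
  mj <- function(idx, f) f(curve$ke_uJ[idx]) / 1000
  structure(list(global_kei = mean(kei),
                 systolic_kei = agg(kei[timing$systole]),
                 diastolic_kei = agg(kei[timing$diastole]),
                 min_kei = min(kei),
                 peak_e_kei = peak_e,
                 peak_a_kei = peak_a,
                 ea_ratio = ea,
                 global_ke_mJ = mj(seq_along(kei), mean),
                 systolic_ke_mJ = mj(timing$systole, if (window_stat == "mean") mean else max),
                 diastolic_ke_mJ = mj(timing$diastole, if (window_stat == "mean") mean else max),
                 peak_e_ke_mJ = mj(timing$e_window, max),
                 peak_a_ke_mJ = mj(timing$a_window, max)),
            class = "ke_parameters")
}

#' @export
print.ke_parameters <- function(x, ...) {
  cat("<ke_parameters> (uJ/ml)\n")
  cat(sprintf("  global %.2f | systolic %.2f | diastolic %.2f | min %.2f\n",
              x$global_kei, x$systolic_kei, x$diastolic_kei, x$min_kei))
  cat(sprintf("  peak E %.2f | peak A %.2f | E/A ratio %.3f\n",
              x$peak_e_kei, x$peak_a_kei, x$ea_ratio))
  invisible(x)
}
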