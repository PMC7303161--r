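#' Endocardial contour stack
#'
#' Per-phase, per-slice closed endocardial polygons from short-axis imaging.
#' `contours[[phase]][[slice]]` is a two-column matrix of (x, y) physical
#' coordinates in mm, or `NULL` where the slice was not contoured.
#'
#' @param contours list (length `n_phases`) of lists (length `n_slices`) of
#'   two-column vertex matrices (mm) or `NULL`
#' @param slice_z_mm ascending slice-centre z positions, mm
#' @param slice_thickness_mm slice thickness, mm
#' @return object of class `contour_stack`
#' @export
contour_stack <- function(contours, slice_z_mm, slice_thickness_mm) {
  stopifnot(length(contours) >= 1L, slice_thickness_mm > 0,
            !is.unsorted(slice_z_mm))
  n_slices <- length(slice_z_mm)
  for (ph in seq_along(contours)) {
    stopifnot(length(contours[[ph]]) == n_slices)
    for (sl in seq_len(n_slices)) {
      p <- contours[[ph]][[sl]]
      if (is.null(p)) next
      if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 8L)
        stop("contour [phase ", ph, ", slice ", sl,
             "] must be a matrix with >= 8 vertices and 2 columns")
      if (polygon_area(p) <= 0)
        stop("contour [phase ", ph, ", slice ", sl, "] has non-positive area")
    }
  }
  structure(list(contours = contours,
                 slice_z_mm = as.numeric(slice_z_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 n_phases = length(contours)),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> %d phases, %d slices (z %.1f..%.1f mm, thickness %g mm)\n",
              x$n_phases, length(x$slice_z_mm), min(x$slice_z_mm),
              max(x$slice_z_mm), x$slice_thickness_mm))
  invisible(x)
}

#' Propagate keyframe contours to all cardiac phases
#'
#' Endocardial contours are drawn manually on a subset of keyframe phases
#' (by default phases 1, 6, 12, 18 and 24 of a 30-phase cycle) and
#' propagated automatically to the intermediate phases. Each keyframe
#' contour is resampled to a fixed vertex count by arc length, anchored at
#' the angle-0 boundary point from its area centroid, so that vertex `j`
#' corresponds across keyframes; intermediate vertex positions (hence radii)
#' are linearly interpolated in phase between the flanking keyframes,
#' cyclically across the R-R wrap. Keyframe phases reproduce their
#' (resampled) keyframes exactly.
#'
#' A slice present in one flanking keyframe but absent in the other is
#' ramped: its polygon is shrunk about its centroid so that area goes
#' linearly to zero toward the keyframe where it is absent, and dropped when
#' the ramp weight reaches zero.
#'
#' @param keyframes `contour_stack` holding contours at the keyframe phases
#'   only (other phases may be `NULL`-filled or the stack may have
#'   `length(keyframe_phases)` entries in keyframe order)
#' @param n_phases total number of cardiac phases to produce
#' @param keyframe_phases 1-based phase indices of the keyframes
#' @param n_vertices vertex count of the resampled contours
#' @return `contour_stack` with `n_phases` phases
#' @export
propagate_contours <- function(keyframes, n_phases,
                               keyframe_phases = c(1L, 6L, 12L, 18L, 24L),
                               n_vertices = 96L) {
  kf <- sort(unique(as.integer(keyframe_phases)))
  stopifnot(length(kf) >= 2L, all(kf >= 1L), all(kf <= n_phases))
  n_slices <- length(keyframes$slice_z_mm)
  ## accept either a full-length stack or one entry per keyframe
  if (keyframes$n_phases == length(kf)) {
    key_list <- keyframes$contours
  } else {
    key_list <- keyframes$contours[kf]
  }
  ## resample all keyframe contours once
  key_rs <- lapply(key_list, function(phase_contours)
    lapply(phase_contours, function(p) if (is.null(p)) NULL else resample_contour(p, n_vertices)))

  interp_slice <- function(p1, p2, w) {
    ## w = weight of the second keyframe in [0, 1]
    if (is.null(p1) && is.null(p2)) return(NULL)
    if (is.null(p1) || is.null(p2)) {
      present <- if (is.null(p1)) p2 else p1
      ramp <- if (is.null(p1)) w else 1 - w   # area weight of the present keyframe
      if (ramp <= 1e-9) return(NULL)
      cen <- polygon_centroid(present)
      message("slice absent in one flanking keyframe: area-ramped (weight ",
              signif(ramp, 3), ")")
      return(sweep(sweep(present, 2L, cen) * sqrt(ramp), 2L, cen, `+`))
    }
    p1 * (1 - w) + p2 * w
  }

  out <- vector("list", n_phases)
  nk <- length(kf)
  for (ph in seq_len(n_phases)) {
    ki <- findInterval(ph, kf)
    if (ki == 0L) {                    # before first keyframe: wrap from last
      a <- nk; b <- 1L
      gap <- (kf[1L] + n_phases) - kf[nk]
      w <- ((ph + n_phases) - kf[nk]) / gap
    } else if (ki == nk) {             # after last keyframe: wrap to first
      a <- nk; b <- 1L
      gap <- (kf[1L] + n_phases) - kf[nk]
      w <- (ph - kf[nk]) / gap
    } else {
      a <- ki; b <- ki + 1L
      w <- (ph - kf[a]) / (kf[b] - kf[a])
    }
    out[[ph]] <- lapply(seq_len(n_slices), function(sl)
      interp_slice(key_rs[[a]][[sl]], key_rs[[b]][[sl]], w))
  }
  contour_stack(out, keyframes$slice_z_mm, keyframes$slice_thickness_mm)
}

#' RV volumetric and functional metrics
#'
#' Per-phase ventricular volume by disc summation (contour area times slice
#' thickness), or voxel counting for mask input; end-diastolic volume (EDV)
#' is the maximum, end-systolic volume (ESV) the minimum (earliest phase on
#' ties), stroke volume SV = EDV - ESV, ejection fraction
#' EF = 100 * SV / EDV. Body-surface-area (BSA) indexed variants divide by
#' BSA in m^2.
#'
#' @param x a `contour_stack` or an `rv_masks` object (see [mesh_to_mask()])
#' @param bsa_m2 body surface area, m^2 (`NA` to skip indexing)
#' @param ... unused
#' @return object of class `volume_metrics`: list with `volume_ml`
#'   (per-phase series), `edv_ml`, `esv_ml`, `sv_ml`, `ef_pct`, `es_phase`,
#'   and BSA-indexed `edvi`, `esvi`, `svi` when `bsa_m2` is given
#' @export
compute_volumes <- function(x, bsa_m2 = NA_real_, ...) UseMethod("compute_volumes")

#' @export
compute_volumes.contour_stack <- function(x, bsa_m2 = NA_real_, ...) {
  vol <- vapply(x$contours, function(phase_contours) {
    areas <- vapply(phase_contours,
                    function(p) if (is.null(p)) 0 else polygon_area(p), 0)
    sum(areas) * x$slice_thickness_mm / 1000   # mm^3 -> ml
  }, 0)
  finish_volume_metrics(vol, bsa_m2)
}

#' @export
compute_volumes.rv_masks <- function(x, bsa_m2 = NA_real_, ...) {
  vol <- vapply(seq_len(dim(x$mask)[4L]),
                function(t) sum(x$mask[, , , t]) * x$voxel_cm3, 0)
  finish_volume_metrics(vol, bsa_m2)
}

finish_volume_metrics <- function(volume_ml, bsa_m2) {
  stopifnot(length(volume_ml) >= 2L)
  if (!is.na(bsa_m2) && bsa_m2 <= 0) stop("bsa_m2 must be positive")
  edv <- max(volume_ml); esv <- min(volume_ml)
  es_phase <- which.min(volume_ml)       # earliest phase on flat minima
  sv <- edv - esv
  ef <- 100 * sv / edv
  out <- list(volume_ml = volume_ml, edv_ml = edv, esv_ml = esv,
              sv_ml = sv, ef_pct = ef, es_phase = es_phase,
              bsa_m2 = bsa_m2,
              edvi_ml_m2 = edv / bsa_m2, esvi_ml_m2 = esv / bsa_m2,
              svi_ml_m2 = sv / bsa_m2)
  structure(out, class = "volume_metrics")
}

#' @export
print.volume_metrics <- function(x, ...) {
  cat(sprintf("<volume_metrics> EDV %.1f ml, ESV %.1f ml, SV %.1f ml, EF %.1f%% (ES phase %d)\n",
              x$edv_ml, x$esv_ml, x$sv_ml, x$ef_pct, x$es_phase))
  invisible(x)
}

#' Tricuspid annular plane systolic excursion (TAPSE)
#'
#' Displacement of the lateral tricuspid annulus landmark along the long
#' axis between end-diastole and end-systole, in mm. The displacement vector
#' is projected onto the (apex-ward) long-axis direction, so pure
#' perpendicular motion yields zero.
#'
#' @param annulus_mm matrix `(n_phases, 3)` of landmark positions, mm; rows
#'   with any `NA` mark missing landmarks
#' @param es_phase end-systolic phase index
#' @param ed_phase end-diastolic phase index (default first phase)
#' @param long_axis length-3 apex-ward long-axis direction (normalised
#'   internally)
#' @return TAPSE in mm, or `NA` when a landmark is missing
#' @export
compute_tapse <- function(annulus_mm, es_phase, ed_phase = 1L,
                          long_axis = c(0, 0, -1)) {
  stopifnot(is.matrix(annulus_mm), ncol(annulus_mm) == 3L,
            nrow(annulus_mm) >= 2L)
  p_ed <- annulus_mm[ed_phase, ]
  p_es <- annulus_mm[es_phase, ]
  if (anyNA(p_ed) || anyNA(p_es)) return(NA_real_)
  u <- long_axis / sqrt(sum(long_axis^2))
  sum((p_es - p_ed) * u)
}

#' Right atrial area by the shoelace formula
#'
#' Area of the four-chamber right-atrial contour drawn just before tricuspid
#' valve opening (end-systole), reported in cm^2, raw and BSA-indexed.
#' Vertex orientation does not matter; self-intersecting or degenerate
#' polygons are rejected.
#'
#' @param polygon_mm two-column matrix of contour vertices, mm
#' @param bsa_m2 body surface area, m^2
#' @return list with `raa_cm2` and `raai_cm2_m2`
#' @export
compute_raa <- function(polygon_mm, bsa_m2 = NA_real_) {
  stopifnot(is.matrix(polygon_mm), ncol(polygon_mm) == 2L)
  if (polygon_self_intersects(polygon_mm))
    stop("right atrial contour is self-intersecting")
  a_mm2 <- polygon_area(polygon_mm)
  if (a_mm2 <= 0) stop("right atrial contour has zero area")
  list(raa_cm2 = a_mm2 / 100, raai_cm2_m2 = a_mm2 / 100 / bsa_m2)
}
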