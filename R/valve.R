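#' Track the tricuspid annular measurement plane
#'
#' From per-phase annular landmarks (two from the four-chamber and two from
#' the two-chamber view) and an apex landmark, builds the retrospective
#' valve-tracking measurement plane: centre = mean of the four annular
#' landmarks; unit normal = inflow direction, the normalised long-axis
#' vector from the annular centre toward the apex landmark, so the plane is
#' perpendicular to inflow at every phase.
#'
#' @param track list with `landmarks_mm` (array `(n_phases, 4, 3)`, mm) and
#'   `apex_mm` (matrix `(n_phases, 3)`, mm)
#' @return object of class `valve_planes`: `centre_mm` and `normal`
#'   matrices `(n_phases, 3)`
#' @export
track_plane <- function(track) {
  lm <- track$landmarks_mm
  apex <- track$apex_mm
  stopifnot(length(dim(lm)) == 3L, dim(lm)[2L] >= 3L, dim(lm)[3L] == 3L,
            is.matrix(apex), ncol(apex) == 3L, nrow(apex) == dim(lm)[1L])
  np <- dim(lm)[1L]
  centre <- t(vapply(seq_len(np), function(t) colMeans(lm[t, , ]), numeric(3L)))
  ## landmarks must span a plane (not be collinear)
  for (t in seq_len(np)) {
    P <- sweep(lm[t, , ], 2L, centre[t, ])
    if (any(!is.finite(P)) || qr(P)$rank < 2L)
      stop("phase ", t, ": annular landmarks are collinear, plane undefined")
  }
  dirn <- apex - centre
  len <- sqrt(rowSums(dirn^2))
  if (any(len < 1e-9)) stop("apex landmark coincides with annular centre")
  structure(list(centre_mm = centre, normal = dirn / len, n_phases = np),
            class = "valve_planes")
}

#' Reformat through-plane velocity on the tracked valve plane
#'
#' Samples the velocity field (trilinear) on a regular in-plane grid
#' carried by each phase's plane and projects the velocity vectors onto the
#' plane normal. Apex-ward (inflow) velocities are positive. The in-plane
#' sampling pitch defaults to half the smallest voxel dimension.
#'
#' @param field a `velocity_field`
#' @param planes a `valve_planes` from [track_plane()]
#' @param aperture_polygon two-column matrix of aperture vertices in plane
#'   (u, v) coordinates, mm
#' @param margin_mm extra in-plane extent sampled beyond the aperture (to
#'   accommodate a myocardial background ROI)
#' @param pitch_mm in-plane sampling pitch, mm
#' @return object of class `plane_velocity_maps`: `vmap[u, v, phase]`
#'   (cm/s), `u_mm`, `v_mm`, `pixel_area_cm2`, `in_aperture` logical matrix
#' @export
reformat_plane_velocity <- function(field, planes, aperture_polygon,
                                    margin_mm = 25, pitch_mm = NULL) {
  stopifnot(inherits(planes, "valve_planes"),
            is.matrix(aperture_polygon), ncol(aperture_polygon) == 2L)
  if (is.null(pitch_mm)) pitch_mm <- min(field$voxel_mm) / 2
  ext <- apply(aperture_polygon, 2L, range)
  us <- seq(ext[1L, 1L] - margin_mm, ext[2L, 1L] + margin_mm, by = pitch_mm)
  vs <- seq(ext[1L, 2L] - margin_mm, ext[2L, 2L] + margin_mm, by = pitch_mm)
  U <- rep(us, times = length(vs)); V <- rep(vs, each = length(us))
  np <- planes$n_phases
  stopifnot(np == n_phases(field))
  vmap <- array(NA_real_, c(length(us), length(vs), np))
  any_inside <- FALSE
  d <- dim(field$v)
  for (t in seq_len(np)) {
    nrm <- planes$normal[t, ]
    ## in-plane orthonormal basis
    ref <- if (abs(nrm[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2L] * e1[3L] - nrm[3L] * e1[2L],
            nrm[3L] * e1[1L] - nrm[1L] * e1[3L],
            nrm[1L] * e1[2L] - nrm[2L] * e1[1L])
    P <- cbind(planes$centre_mm[t, 1L] + U * e1[1L] + V * e2[1L],
               planes$centre_mm[t, 2L] + U * e1[2L] + V * e2[2L],
               planes$centre_mm[t, 3L] + U * e1[3L] + V * e2[3L])
    ix <- (P[, 1L] - field$origin_mm[1L]) / field$voxel_mm[1L] + 1
    iy <- (P[, 2L] - field$origin_mm[2L]) / field$voxel_mm[2L] + 1
    iz <- (P[, 3L] - field$origin_mm[3L]) / field$voxel_mm[3L] + 1
    if (any(ix >= 1 & ix <= d[1L] & iy >= 1 & iy <= d[2L] & iz >= 1 & iz <= d[3L]))
      any_inside <- TRUE
    vn <- trilinear_sample(field$v[, , , t, 1L], ix, iy, iz) * nrm[1L] +
          trilinear_sample(field$v[, , , t, 2L], ix, iy, iz) * nrm[2L] +
          trilinear_sample(field$v[, , , t, 3L], ix, iy, iz) * nrm[3L]
    vmap[, , t] <- matrix(vn, length(us), length(vs))
  }
  if (!any_inside) stop("valve plane lies entirely outside the field of view")
  in_ap <- matrix(points_in_polygon(U, V, aperture_polygon),
                  length(us), length(vs))
  structure(list(vmap = vmap, u_mm = us, v_mm = vs,
                 pixel_area_cm2 = pitch_mm^2 / 100,
                 in_aperture = in_ap,
                 phase_ms = field$phase_ms),
            class = "plane_velocity_maps")
}

#' Myocardial background correction of plane velocity maps
#'
#' Subtracts, per phase, the mean through-plane velocity over the
#' myocardial ROI from the whole map. This removes both residual phase
#' offsets and the annular through-plane motion the tracked plane shares
#' with the myocardium. An empty ROI skips the correction with a warning.
#'
#' @param maps a `plane_velocity_maps`
#' @param myocardium_roi either a logical matrix matching the map grid or a
#'   list with polygons `outer` (and optionally `inner`) in plane
#'   coordinates defining a ring
#' @return corrected `plane_velocity_maps`; attribute
#'   `"background_cm_s"` stores the per-phase subtracted velocity
#' @export
background_correct_plane <- function(maps, myocardium_roi) {
  roi <- roi_mask(maps, myocardium_roi)
  if (!any(roi)) {
    warning("empty myocardial ROI: background correction skipped", call. = FALSE)
    attr(maps, "background_cm_s") <- rep(0, dim(maps$vmap)[3L])
    return(maps)
  }
  np <- dim(maps$vmap)[3L]
  bg <- numeric(np)
  for (t in seq_len(np)) {
    bg[t] <- mean(maps$vmap[, , t][roi])
    maps$vmap[, , t] <- maps$vmap[, , t] - bg[t]
  }
  attr(maps, "background_cm_s") <- bg
  maps
}

roi_mask <- function(maps, myocardium_roi) {
  if (is.matrix(myocardium_roi) && is.logical(myocardium_roi)) {
    stopifnot(all(dim(myocardium_roi) == dim(maps$vmap)[1:2]))
    return(myocardium_roi)
  }
  U <- rep(maps$u_mm, times = length(maps$v_mm))
  V <- rep(maps$v_mm, each = length(maps$u_mm))
  m <- points_in_polygon(U, V, myocardium_roi$outer)
  if (!is.null(myocardium_roi$inner))
    m <- m & !points_in_polygon(U, V, myocardium_roi$inner)
  matrix(m, length(maps$u_mm), length(maps$v_mm))
}

#' Tricuspid through-plane flow metrics
#'
#' Integrates the (background-corrected) through-plane velocity over the
#' aperture: flow rate `q[t] = sum(v * pixel_area)` in ml/s; tricuspid
#' valve stroke volume as the forward-flow integral over diastole
#' (`net = TRUE` integrates signed flow instead); peak E- and A-wave
#' velocities as the maxima of the per-phase peak in-aperture velocity over
#' the early- and late-filling windows, and their ratio.
#'
#' @param maps a `plane_velocity_maps` (after [background_correct_plane()])
#' @param timing a `cardiac_timing`
#' @param net integrate net (signed) diastolic flow instead of forward-only
#' @return object of class `tv_flow_curve`: `q_ml_s`, `mean_vel_cm_s`,
#'   `peak_vel_cm_s` per phase; `sv_ml`, `peak_e_vel`, `peak_a_vel`,
#'   `ea_vel_ratio`
#' @export
tv_flow_metrics <- function(maps, timing, net = FALSE) {
  stopifnot(inherits(maps, "plane_velocity_maps"), inherits(timing, "cardiac_timing"))
  ap <- maps$in_aperture
  if (!any(ap)) stop("empty aperture polygon on the sampling grid")
  np <- dim(maps$vmap)[3L]
  q <- mean_v <- peak_v <- numeric(np)
  for (t in seq_len(np)) {
    vt <- maps$vmap[, , t][ap]
    q[t] <- sum(vt) * maps$pixel_area_cm2
    mean_v[t] <- mean(vt)
    peak_v[t] <- max(vt)
  }
  dt_s <- maps$phase_ms / 1000
  qd <- q[timing$diastole]
  sv <- if (net) sum(qd) * dt_s else sum(pmax(qd, 0)) * dt_s
  if (!net && all(qd <= 0)) {
    warning("no forward diastolic flow through the aperture", call. = FALSE)
    sv <- 0
  }
  pe <- max(peak_v[timing$e_window])
  pa <- max(peak_v[timing$a_window])
  structure(list(q_ml_s = q, mean_vel_cm_s = mean_v, peak_vel_cm_s = peak_v,
                 sv_ml = max(sv, 0),
                 peak_e_vel = pe, peak_a_vel = pa,
                 ea_vel_ratio = if (pa > 0) pe / pa else NA_real_),
            class = "tv_flow_curve")
}

#' @export
print.tv_flow_curve <- function(x, ...) {
  cat(sprintf("<tv_flow_curve> TV SV %.1f ml; peak E %.1f cm/s, peak A %.1f cm/s, E/A %.3f\n",
              x$sv_ml, x$peak_e_vel, x$peak_a_vel, x$ea_vel_ratio))
  invisible(x)
}
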