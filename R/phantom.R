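#' Specification of an analytic 4D-flow cardiac phantom
#'
#' Describes a time-varying solid-of-revolution "right ventricle" (a tapered
#' cylinder of short-axis discs) carrying a three-peak intracavity velocity
#' program (systolic ejection peak, early E-wave and late A-wave diastolic
#' filling peaks), embedded in a static tissue background. The defaults
#' emulate the acquisition the package targets: 30 reconstructed phases,
#' 3 mm isotropic voxels and VENC 150 cm/s, with cavity volumes and inflow
#' velocities in the healthy adult range (EDV 150 ml, ESV 60 ml, peak E/A
#' inflow 50/38 cm/s).
#'
#' The diastolic filling is volumetrically closed: the tricuspid aperture
#' area is derived as `A = (EDV - ESV) / integral(v dt)` over diastole, so
#' the programmed through-plane flow refills exactly the programmed stroke
#' volume and valve-plane stroke volume equals the cine volume change by
#' construction.
#'
#' @param grid_shape integer triple (nx, ny, nz)
#' @param voxel_mm voxel spacing, mm (scalar or triple)
#' @param n_phases number of cardiac phases
#' @param phase_ms phase duration, ms
#' @param venc velocity-encoding limit, cm/s
#' @param edv_ml,esv_ml end-diastolic / end-systolic cavity volume, ml
#' @param es_phase 1-based phase index of end-systole
#' @param v_sys,v_e,v_a peak intracavity speeds of the systolic, E- and
#'   A-wave program, cm/s
#' @param noise_sd Gaussian velocity noise per component, cm/s
#' @param offset_model background phase-offset description: `list(type =
#'   "none")`, `list(type = "constant", value = c(ox, oy, oz))` (cm/s), or
#'   `list(type = "linear_x", amplitude = c(ax, ay, az))` (offset ramps
#'   linearly from -a to +a across the x field of view)
#' @param seed integer seed; all phantom randomness flows from it
#' @param n_slices,slice_thickness_mm short-axis disc geometry
#' @param taper apex taper fraction in `[0, 1)`: apical radius is
#'   `(1 - taper)` times the basal radius
#' @param profile `"uniform"` (spatially uniform speed per phase; total KE
#'   has a closed form) or `"parabolic"` (radially parabolic, spatially
#'   smooth; truth KE comes from the voxel oracle)
#' @param n_vertices vertex count of the emitted contour polygons
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 30L),
                         voxel_mm = 3,
                         n_phases = 30L,
                         phase_ms = 30,
                         venc = 150,
                         edv_ml = 150, esv_ml = 60,
                         es_phase = 12L,
                         v_sys = 60, v_e = 50, v_a = 38,
                         noise_sd = 0,
                         offset_model = list(type = "none"),
                         seed = 1L,
                         n_slices = 10L, slice_thickness_mm = 8,
                         taper = 0.7,
                         profile = c("uniform", "parabolic"),
                         n_vertices = 96L) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  profile <- match.arg(profile)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            all(voxel_mm > 0), n_phases >= 8L, phase_ms > 0, venc > 0,
            edv_ml > 0, esv_ml > 0, esv_ml <= edv_ml,
            es_phase > 1L, es_phase < n_phases - 1L,
            v_sys >= 0, v_e >= 0, v_a >= 0, noise_sd >= 0,
            n_slices >= 2L, slice_thickness_mm > 0,
            taper >= 0, taper < 1)
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 n_phases = as.integer(n_phases), phase_ms = phase_ms,
                 venc = venc, edv_ml = edv_ml, esv_ml = esv_ml,
                 es_phase = as.integer(es_phase),
                 v_sys = v_sys, v_e = v_e, v_a = v_a,
                 noise_sd = noise_sd, offset_model = offset_model,
                 seed = as.integer(seed),
                 n_slices = as.integer(n_slices),
                 slice_thickness_mm = slice_thickness_mm,
                 taper = taper, profile = profile,
                 n_vertices = as.integer(n_vertices)),
            class = "phantom_spec")
}

## ---- velocity / volume program -------------------------------------------

## Continuous three-peak speed program, cm/s, at time t (ms).
## Systole: v_sys * sin^2(pi t / t_es). Diastole: raised-cosine E and A
## bumps at 30% and 78% of diastole with widths 50% and 36% of diastole.
phantom_speed_at <- function(spec, t) {
  rr <- spec$n_phases * spec$phase_ms
  t_es <- (spec$es_phase - 1) * spec$phase_ms
  d <- rr - t_es
  c_e <- t_es + 0.30 * d; w_e <- 0.50 * d
  c_a <- t_es + 0.78 * d; w_a <- 0.36 * d
  v <- numeric(length(t))
  sys <- t <= t_es
  v[sys] <- spec$v_sys * sin(pi * t[sys] / t_es)^2
  eb <- abs(t - c_e) <= w_e / 2
  v[eb] <- v[eb] + spec$v_e * cos(pi * (t[eb] - c_e) / w_e)^2
  ab <- abs(t - c_a) <= w_a / 2
  v[ab] <- v[ab] + spec$v_a * cos(pi * (t[ab] - c_a) / w_a)^2
  v
}

#' Evaluate the phantom's programmed speed, volume and timing
#'
#' Returns the continuous velocity/volume program sampled at the phase
#' times, together with the derived tricuspid aperture area and the phase
#' windows of the E and A bumps. This is the closed-form ground truth the
#' voxelised phantom is checked against.
#'
#' @param spec a `phantom_spec`
#' @return list with `time_ms`, `speed_cm_s` (magnitude per phase),
#'   `vz_cm_s` (signed: base-ward positive in systole, apex-ward negative in
#'   diastole), `volume_ml` (programmed continuous volume at phase times),
#'   `aperture_cm2`, `e_phases`, `a_phases`, `diastole_phases`
#' @export
phantom_program <- function(spec) {
  rr <- spec$n_phases * spec$phase_ms
  t_es <- (spec$es_phase - 1) * spec$phase_ms
  d <- rr - t_es
  tk <- (seq_len(spec$n_phases) - 1) * spec$phase_ms
  ## fine-grid quadrature of the speed program
  tf <- seq(0, rr, length.out = 4001L)
  vf <- phantom_speed_at(spec, tf)
  dt_s <- (tf[2L] - tf[1L]) / 1000
  cum <- c(0, cumsum((vf[-1L] + vf[-length(vf)]) / 2) * dt_s)  # cm
  cum_at <- function(t) stats::approx(tf, cum, xout = t)$y
  i_es <- cum_at(t_es)
  i_tot <- cum[length(cum)]
  i_dia <- i_tot - i_es
  sv <- spec$edv_ml - spec$esv_ml
  aperture_cm2 <- if (i_dia > 0) sv / i_dia else NA_real_
  vol_at <- function(t) {
    frac_sys <- if (i_es > 0) cum_at(pmin(t, t_es)) / i_es else pmin(t, t_es) / t_es
    frac_dia <- if (i_dia > 0) (cum_at(pmax(t, t_es)) - i_es) / i_dia
                else pmax(t - t_es, 0) / d
    ifelse(t <= t_es, spec$edv_ml - sv * frac_sys,
           spec$esv_ml + sv * frac_dia)
  }
  c_e <- t_es + 0.30 * d; w_e <- 0.50 * d
  c_a <- t_es + 0.78 * d; w_a <- 0.36 * d
  speed_k <- phantom_speed_at(spec, tk)
  list(time_ms = tk,
       speed_cm_s = speed_k,
       vz_cm_s = ifelse(tk <= t_es, speed_k, -speed_k),
       volume_ml = vol_at(tk),
       volume_at = vol_at,
       aperture_cm2 = aperture_cm2,
       e_phases = which(abs(tk - c_e) <= w_e / 2),
       a_phases = which(abs(tk - c_a) <= w_a / 2),
       diastole_phases = which(tk > t_es))
}

## ---- geometry -------------------------------------------------------------

## Per-slice radius multipliers (apex = slice 1) and basal radius per phase.
phantom_radii <- function(spec, volume_ml) {
  s <- seq_len(spec$n_slices)
  p <- 1 - spec$taper * (spec$n_slices - s) / (spec$n_slices - 1)
  th_cm <- spec$slice_thickness_mm / 10
  r_base_cm <- sqrt(volume_ml / (pi * th_cm * sum(p^2)))
  list(profile = p, r_base_mm = r_base_cm * 10)
}

phantom_slice_z <- function(spec) {
  zmid <- (spec$grid_shape[3L] - 1) * spec$voxel_mm[3L] / 2
  h <- spec$n_slices * spec$slice_thickness_mm
  zmid - h / 2 + spec$slice_thickness_mm / 2 +
    (seq_len(spec$n_slices) - 1) * spec$slice_thickness_mm
}

#' Generate the phantom's time-resolved endocardial contours
#'
#' Builds per-phase per-slice circular contours of a tapered solid of
#' revolution whose disc-summed volume follows the programmed
#' EDV -> ESV -> EDV curve with its minimum at `es_phase`, and returns the
#' truth volume series alongside.
#'
#' @param spec a `phantom_spec`
#' @return list with `contours` (a [contour_stack()]) and `truth`
#'   (list with `volume_ml` disc-summed truth series and the programmed
#'   `program` from [phantom_program()])
#' @export
make_geometry <- function(spec) {
  prog <- phantom_program(spec)
  slice_z <- phantom_slice_z(spec)
  fov <- (spec$grid_shape[1:2] - 1) * spec$voxel_mm[1:2]
  cx <- fov[1L] / 2; cy <- fov[2L] / 2
  geom_ed <- phantom_radii(spec, spec$edv_ml)
  r_max <- max(geom_ed$r_base_mm * geom_ed$profile)
  if (r_max > min(fov) / 2 - max(spec$voxel_mm) ||
      min(slice_z) < 0 || max(slice_z) > (spec$grid_shape[3L] - 1) * spec$voxel_mm[3L])
    stop("grid too small to contain the phantom geometry (basal radius ",
         round(r_max, 1), " mm)")
  contours <- vector("list", spec$n_phases)
  vol_truth <- numeric(spec$n_phases)
  for (ph in seq_len(spec$n_phases)) {
    g <- phantom_radii(spec, prog$volume_ml[ph])
    polys <- lapply(seq_len(spec$n_slices), function(s)
      circle_polygon(cx, cy, g$r_base_mm * g$profile[s], spec$n_vertices))
    contours[[ph]] <- polys
    vol_truth[ph] <- sum(vapply(polys, polygon_area, 0)) *
      spec$slice_thickness_mm / 1000
  }
  list(contours = contour_stack(contours, slice_z, spec$slice_thickness_mm),
       truth = list(volume_ml = vol_truth, program = prog),
       centre_mm = c(cx, cy))
}

## ---- velocity field -------------------------------------------------------

#' Generate the phantom velocity and magnitude volumes
#'
#' Inside the cavity the velocity is long-axis aligned with the programmed
#' three-peak speed (uniform per phase, or radially parabolic with the
#' programmed peak at the axis), signed apex-ward during diastolic inflow.
#' Outside, velocity is zero plus the background offset model plus Gaussian
#' noise. A magnitude volume distinguishes blood (bright), static tissue
#' (moderate) and air (dark). Truth KE per phase is the closed form
#' `0.05 * rho * V_truth * v^2` for the uniform profile, and the voxel
#' oracle (sum over generated cavity voxels of the clean field) for the
#' parabolic profile.
#'
#' @param spec a `phantom_spec`
#' @param geometry output of [make_geometry()] (generated if `NULL`)
#' @param rho_g_cm3 blood density, g/cm^3
#' @return list with `field` (a [velocity_field()]), `truth` (volume, speed,
#'   KE and KEi_EDV series plus `tv_sv_ml`), and the geometry
#' @export
make_velocity_field <- function(spec, geometry = NULL, rho_g_cm3 = .RHO_BLOOD) {
  if (is.null(geometry)) geometry <- make_geometry(spec)
  prog <- geometry$truth$program
  d <- spec$grid_shape
  xs <- (seq_len(d[1L]) - 1) * spec$voxel_mm[1L]
  ys <- (seq_len(d[2L]) - 1) * spec$voxel_mm[2L]
  zs <- (seq_len(d[3L]) - 1) * spec$voxel_mm[3L]
  cx <- geometry$centre_mm[1L]; cy <- geometry$centre_mm[2L]
  slice_z <- phantom_slice_z(spec)
  th <- spec$slice_thickness_mm
  ## slice index of each z (0 = outside the stack)
  zslice <- findInterval(zs, c(slice_z - th / 2, slice_z[spec$n_slices] + th / 2))
  zslice[zslice > spec$n_slices & zs <= slice_z[spec$n_slices] + th / 2] <- spec$n_slices
  zslice[zs < slice_z[1L] - th / 2 | zs > slice_z[spec$n_slices] + th / 2] <- 0L
  R2 <- outer(xs - cx, ys - cy, function(a, b) a^2 + b^2)  # in-plane r^2 (nx x ny)

  v <- array(0, c(d, spec$n_phases, 3L))
  ke_oracle <- numeric(spec$n_phases)
  vvox_cm3 <- prod(spec$voxel_mm) / 1000
  for (ph in seq_len(spec$n_phases)) {
    g <- phantom_radii(spec, prog$volume_ml[ph])
    vz_ph <- prog$vz_cm_s[ph]
    ke_ph <- 0
    for (k in which(zslice > 0L)) {
      r_s <- g$r_base_mm * g$profile[zslice[k]]
      inside <- R2 <= r_s^2
      if (!any(inside)) next
      if (spec$profile == "uniform") {
        vz_vox <- vz_ph
        plane <- ifelse(inside, vz_vox, 0)
      } else {
        plane <- ifelse(inside, vz_ph * (1 - R2 / r_s^2), 0)
      }
      v[, , k, ph, 3L] <- plane
      ke_ph <- ke_ph + .KE_UJ_FACTOR * rho_g_cm3 * vvox_cm3 * sum(plane^2)
    }
    ke_oracle[ph] <- ke_ph
  }

  if (max(abs(v)) > spec$venc)
    warning("programmed speeds exceed VENC (", spec$venc,
            " cm/s); wrap_velocities() will alias them", call. = FALSE)

  ## truth KE before offsets/noise
  vol_truth <- geometry$truth$volume_ml
  ke_truth <- if (spec$profile == "uniform") {
    .KE_UJ_FACTOR * rho_g_cm3 * vol_truth * prog$speed_cm_s^2
  } else ke_oracle
  edv_truth <- max(vol_truth)

  ## background offsets (time-constant) and noise
  om <- spec$offset_model %||% list(type = "none")
  if (identical(om$type, "constant")) {
    for (cc in 1:3) v[, , , , cc] <- v[, , , , cc] + om$value[cc]
  } else if (identical(om$type, "linear_x")) {
    xr <- if (length(xs) > 1L) 2 * (xs - mean(xs)) / (max(xs) - min(xs)) else 0 * xs
    for (cc in 1:3) {
      ramp <- om$amplitude[cc] * xr
      v[, , , , cc] <- v[, , , , cc] + array(ramp, c(d, spec$n_phases))
    }
  } else if (!identical(om$type, "none")) {
    stop("unknown offset_model type: ", om$type)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    v <- v + array(stats::rnorm(length(v), sd = spec$noise_sd), dim(v))
  }

  ## magnitude: blood 100, tissue 80, air 5
  mag <- array(5, d)
  body_r <- 0.46 * min((d[1:2] - 1) * spec$voxel_mm[1:2])
  body <- array(rep(R2 <= body_r^2, d[3L]), d)
  mag[body] <- 80
  g_ed <- phantom_radii(spec, max(prog$volume_ml))
  for (k in which(zslice > 0L)) {
    r_s <- g_ed$r_base_mm * g_ed$profile[zslice[k]]
    mag[, , k][R2 <= r_s^2] <- 100
  }

  field <- velocity_field(v, spec$voxel_mm, spec$phase_ms, spec$venc, mag = mag)
  truth <- list(volume_ml_per_phase = vol_truth,
                speed_cm_s_per_phase = prog$speed_cm_s,
                ke_uJ_per_phase = ke_truth,
                kei_uJ_ml_per_phase = ke_truth / edv_truth,
                edv_ml = edv_truth,
                tv_sv_ml = spec$edv_ml - spec$esv_ml,
                aperture_cm2 = prog$aperture_cm2,
                program = prog)
  truth$ke_params_truth <- phantom_truth_params(truth, spec)
  list(field = field, truth = truth, geometry = geometry)
}

## Closed-form KE summary parameters of the truth curve (discrete phase grid).
phantom_truth_params <- function(truth, spec) {
  kei <- truth$kei_uJ_ml_per_phase
  prog <- truth$program
  sys <- seq_len(spec$es_phase)
  dia <- prog$diastole_phases
  peak_e <- max(kei[prog$e_phases])
  peak_a <- max(kei[prog$a_phases])
  list(global_kei = mean(kei),
       systolic_kei = mean(kei[sys]),
       diastolic_kei = mean(kei[dia]),
       min_kei = min(kei),
       peak_e_kei = peak_e, peak_a_kei = peak_a,
       ea_ratio = if (peak_a > 0) peak_e / peak_a else NA_real_)
}

#' Emulate acquisition phase-aliasing
#'
#' Maps every velocity component to `((v + venc) mod 2 venc) - venc`: the
#' wrap the phase signal suffers when true velocities exceed the
#' velocity-encoding limit. Idempotent on in-range fields.
#'
#' @param field a `velocity_field`
#' @return the wrapped `velocity_field`
#' @export
wrap_velocities <- function(field) {
  venc <- field$venc
  field$v <- ((field$v + venc) %% (2 * venc)) - venc
  field
}

#' Full phantom dataset: contours, field, valve geometry and truth
#'
#' Convenience wrapper running [make_geometry()] and
#' [make_velocity_field()], and attaching the retrospective-valve-tracking
#' inputs: a static annular landmark track at the basal plane, the aperture
#' polygon (in-plane coordinates, mm) whose area closes the diastolic
#' volume balance, and a myocardial ring ROI for background correction.
#'
#' @param spec a `phantom_spec`
#' @return object of class `rv_phantom`
#' @export
make_phantom <- function(spec) {
  geometry <- make_geometry(spec)
  vf <- make_velocity_field(spec, geometry)
  slice_z <- phantom_slice_z(spec)
  plane_z <- slice_z[spec$n_slices - 1L]
  cx <- geometry$centre_mm[1L]; cy <- geometry$centre_mm[2L]
  ap_cm2 <- vf$truth$aperture_cm2
  r_ap <- if (is.finite(ap_cm2)) sqrt(ap_cm2 / pi) * 10 else NA_real_  # mm
  g_ed <- phantom_radii(spec, spec$edv_ml)
  r_plane_ed <- g_ed$r_base_mm * g_ed$profile[spec$n_slices - 1L]
  g_es <- phantom_radii(spec, spec$esv_ml)
  r_plane_es <- g_es$r_base_mm * g_es$profile[spec$n_slices - 1L]
  if (is.finite(r_ap) && r_ap > 0.97 * r_plane_es)
    stop("derived aperture radius (", round(r_ap, 1),
         " mm) does not fit inside the cavity at end-systole (",
         round(r_plane_es, 1), " mm); increase diastolic speeds or durations")
  np <- spec$n_phases
  ang <- c(0, 0.5, 1, 1.5) * pi
  lm_r <- if (is.finite(r_ap)) r_ap else 0.5 * r_plane_es
  landmarks <- array(NA_real_, c(np, 4L, 3L))
  for (j in 1:4) {
    landmarks[, j, 1L] <- cx + lm_r * cos(ang[j])
    landmarks[, j, 2L] <- cy + lm_r * sin(ang[j])
    landmarks[, j, 3L] <- plane_z
  }
  apex <- cbind(rep(cx, np), rep(cy, np),
                rep(slice_z[1L] - spec$slice_thickness_mm / 2, np))
  aperture <- if (is.finite(r_ap)) circle_polygon(0, 0, r_ap, 64L) else NULL
  roi <- list(outer = circle_polygon(0, 0, r_plane_ed * 1.30, 64L),
              inner = circle_polygon(0, 0, r_plane_ed * 1.10, 64L))
  structure(list(spec = spec,
                 contours = geometry$contours,
                 field = vf$field,
                 truth = vf$truth,
                 annular_track = list(landmarks_mm = landmarks, apex_mm = apex),
                 aperture_polygon_mm = aperture,
                 myocardium_roi = roi),
            class = "rv_phantom")
}

#' @export
print.rv_phantom <- function(x, ...) {
  cat(sprintf("<rv_phantom> EDV %.0f ml, ESV %.0f ml, %d phases; truth E/A KE ratio %.3f\n",
              x$spec$edv_ml, x$spec$esv_ml, x$spec$n_phases,
              x$truth$ke_params_truth$ea_ratio))
  invisible(x)
}

#' Calibrate the A-wave speed to hit a target KE E/A ratio
#'
#' Solves for the late-filling peak speed `v_a` such that the phantom's
#' closed-form KEi_EDV curve has the requested peak-E to peak-A ratio on the
#' discrete phase grid (the ratio depends on `v_a` both directly and through
#' the filling-volume program, so a one-dimensional root search is used).
#'
#' @param spec a `phantom_spec`
#' @param target_ratio desired peak-E / peak-A KEi_EDV ratio
#' @return the `phantom_spec` with `v_a` replaced
#' @export
calibrate_phantom_ea <- function(spec, target_ratio) {
  stopifnot(target_ratio > 0)
  ratio_at <- function(va) {
    s <- spec; s$v_a <- va
    prog <- phantom_program(s)
    v <- prog$volume_ml; sp <- prog$speed_cm_s
    ke <- v * sp^2
    max(ke[prog$e_phases]) / max(ke[prog$a_phases]) - target_ratio
  }
  sol <- stats::uniroot(ratio_at, lower = 1, upper = 4 * max(spec$v_e, 1),
                        tol = 1e-8)
  spec$v_a <- sol$root
  spec
}
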