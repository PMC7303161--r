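#' Time-resolved cylindrical RV mesh from endocardial contours
#'
#' Represents the right-ventricular endocardial surface in cylindrical
#' coordinates: for every cardiac phase, a per-level centroid and a radius
#' for each (level, angle) pair on a uniform angle grid, with levels spaced
#' uniformly along the slice axis. The radius at a level between two slice
#' planes is derived by linear interpolation of the per-slice radii; beyond
#' the outermost slice centres radii extend constantly over the half slice
#' thickness (the disc model). Mesh volume is
#' `sum over levels and angles of 1/2 r^2 dtheta dz`.
#'
#' @param contours a `contour_stack` with contours on >= 2 slices per phase
#' @param n_angles number of uniform angles
#' @param n_levels number of axial levels (default 3 per slice)
#' @return object of class `rv_mesh`: `radii[level, angle, phase]` (mm),
#'   `centroid[level, 1:2, phase]` (mm), `level_z_mm`, `level_dz_mm`,
#'   `angles` (radians)
#' @export
build_mesh <- function(contours, n_angles = 64L, n_levels = NULL) {
  st <- contours
  n_slices <- length(st$slice_z_mm)
  if (is.null(n_levels)) n_levels <- 3L * n_slices
  th <- st$slice_thickness_mm
  z_lo <- st$slice_z_mm[1L] - th / 2
  z_hi <- st$slice_z_mm[n_slices] + th / 2
  dz <- (z_hi - z_lo) / n_levels
  level_z <- z_lo + (seq_len(n_levels) - 0.5) * dz
  angles <- (seq_len(n_angles) - 1L) * 2 * pi / n_angles

  radii <- array(0, c(n_levels, n_angles, st$n_phases))
  cents <- array(NA_real_, c(n_levels, 2L, st$n_phases))
  for (ph in seq_len(st$n_phases)) {
    present <- which(!vapply(st$contours[[ph]], is.null, TRUE))
    if (length(present) < 2L)
      stop("phase ", ph, ": mesh needs contours on >= 2 slices")
    zc <- st$slice_z_mm[present]
    slice_cen <- t(vapply(st$contours[[ph]][present], polygon_centroid, numeric(2L)))
    slice_rad <- t(vapply(seq_along(present), function(i)
      polygon_polar_radii(st$contours[[ph]][[present[i]]], slice_cen[i, ], angles),
      numeric(n_angles)))
    ## axial support of this phase: present slices plus half thickness
    lo <- zc[1L] - th / 2; hi <- zc[length(zc)] + th / 2
    inside <- level_z >= lo & level_z <= hi
    zq <- pmin(pmax(level_z, zc[1L]), zc[length(zc)])  # constant extension
    for (a in seq_len(n_angles)) {
      r <- stats::approx(zc, slice_rad[, a], xout = zq, rule = 2)$y
      radii[, a, ph] <- ifelse(inside, r, 0)
    }
    cents[, 1L, ph] <- stats::approx(zc, slice_cen[, 1L], xout = zq, rule = 2)$y
    cents[, 2L, ph] <- stats::approx(zc, slice_cen[, 2L], xout = zq, rule = 2)$y
  }
  structure(list(radii = radii, centroid = cents, level_z_mm = level_z,
                 level_dz_mm = dz, angles = angles,
                 n_phases = st$n_phases),
            class = "rv_mesh")
}

#' Per-phase mesh volume in ml
#' @param mesh an `rv_mesh`
#' @return numeric vector, ml
#' @export
mesh_volume <- function(mesh) {
  dtheta <- 2 * pi / length(mesh$angles)
  vapply(seq_len(mesh$n_phases), function(ph)
    sum(0.5 * mesh$radii[, , ph]^2 * dtheta * mesh$level_dz_mm) / 1000, 0)
}

#' @export
print.rv_mesh <- function(x, ...) {
  v <- mesh_volume(x)
  cat(sprintf("<rv_mesh> %d phases, %d levels x %d angles; volume %.1f..%.1f ml\n",
              x$n_phases, dim(x$radii)[1L], dim(x$radii)[2L], min(v), max(v)))
  invisible(x)
}

#' Voxel membership of the RV mesh on a velocity-field grid
#'
#' A voxel belongs to the RV at a given phase iff its centre lies inside the
#' mesh surface: the voxel's (level, angle) boundary radius is obtained by
#' bilinear interpolation of the mesh radii (cyclic in angle) and compared
#' with the voxel's in-plane distance from the interpolated centroid.
#' Centres exactly on the boundary are inside (closed boundary rule). The
#' mesh and grid must share one physical frame (apply any rigid cine-to-flow
#' transform first).
#'
#' @param mesh an `rv_mesh`
#' @param field a `velocity_field` supplying the voxel grid
#' @return object of class `rv_masks`: logical `mask[x, y, z, phase]` plus
#'   `voxel_cm3`
#' @export
mesh_to_mask <- function(mesh, field) {
  d <- dim(field$v)[1:3]
  xs <- axis_coords(field, 1L); ys <- axis_coords(field, 2L); zs <- axis_coords(field, 3L)
  n_levels <- dim(mesh$radii)[1L]; n_ang <- dim(mesh$radii)[2L]
  dtheta <- 2 * pi / n_ang
  z_lo <- mesh$level_z_mm[1L] - mesh$level_dz_mm / 2
  mask <- array(FALSE, c(d, mesh$n_phases))

  ## half-open along z (lower cap in, upper cap out) so commensurate grids
  ## do not double-count both end-cap planes; the radial test stays closed
  zin <- which(zs >= z_lo & zs < z_lo + n_levels * mesh$level_dz_mm)
  if (!length(zin)) stop("grid does not intersect the mesh axial extent")
  X <- matrix(rep(xs, times = length(ys)), nrow = d[1L])
  Y <- matrix(rep(ys, each = d[1L]), nrow = d[1L])

  for (ph in seq_len(mesh$n_phases)) {
    for (k in zin) {
      ## fractional level position of this z
      lf <- (zs[k] - mesh$level_z_mm[1L]) / mesh$level_dz_mm + 1
      l0 <- max(1L, min(n_levels - 1L, floor(lf)))
      wl <- min(max(lf - l0, 0), 1)
      cen <- mesh$centroid[l0, , ph] * (1 - wl) + mesh$centroid[l0 + 1L, , ph] * wl
      r0 <- mesh$radii[l0, , ph]; r1 <- mesh$radii[l0 + 1L, , ph]
      rl <- r0 * (1 - wl) + r1 * wl              # radii at this z, per angle
      dx <- X - cen[1L]; dy <- Y - cen[2L]
      theta <- atan2(dy, dx) %% (2 * pi)
      af <- theta / dtheta + 1
      a0 <- pmin(floor(af), n_ang)
      wa <- af - a0
      a1 <- ifelse(a0 == n_ang, 1L, a0 + 1L)
      rb <- rl[a0] * (1 - wa) + rl[a1] * wa
      rv <- sqrt(dx^2 + dy^2)
      mask[, , k, ph] <- rb > 0 & rv <= rb + 1e-9
    }
    if (!any(mask[, , , ph]))
      stop("phase ", ph, ": mesh produced an empty voxel mask")
  }
  structure(list(mask = mask, voxel_cm3 = voxel_volume_cm3(field)),
            class = "rv_masks")
}

#' @export
print.rv_masks <- function(x, ...) {
  n <- apply(x$mask, 4L, sum)
  cat(sprintf("<rv_masks> %d phases; %d..%d voxels (%.1f..%.1f ml)\n",
              dim(x$mask)[4L], min(n), max(n),
              min(n) * x$voxel_cm3, max(n) * x$voxel_cm3))
  invisible(x)
}
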