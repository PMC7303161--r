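#' Time-resolved three-component velocity field
#'
#' Container for a 4D flow acquisition: a five-dimensional array
#' `v[x, y, z, phase, component]` of velocities in cm/s on a regular grid,
#' optionally accompanied by a co-registered anatomical magnitude volume.
#' Physical coordinates use voxel-centre addressing:
#' `x_mm = origin_mm + (index - 1) * voxel_mm` along each axis.
#'
#' @param v numeric array `(nx, ny, nz, n_phases, 3)`, cm/s; components are
#'   (vx, vy, vz) along the grid axes
#' @param voxel_mm length-3 positive voxel spacing, mm
#' @param phase_ms duration of one cardiac phase, ms
#' @param venc velocity-encoding limit, cm/s; velocities beyond `+-venc`
#'   alias (wrap) in the phase signal
#' @param mag optional magnitude volume `(nx, ny, nz)`, arbitrary units >= 0
#' @param origin_mm physical position of voxel (1,1,1), mm
#' @return object of class `velocity_field`
#' @export
velocity_field <- function(v, voxel_mm, phase_ms, venc,
                           mag = NULL, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(v), length(dim(v)) == 5L, dim(v)[5L] == 3L,
            length(voxel_mm) == 3L, all(voxel_mm > 0),
            phase_ms > 0, venc > 0, dim(v)[4L] >= 2L)
  if (!is.null(mag)) {
    stopifnot(all(dim(mag)[1:3] == dim(v)[1:3]), all(mag >= 0))
  }
  structure(list(v = v, mag = mag,
                 voxel_mm = as.numeric(voxel_mm),
                 phase_ms = as.numeric(phase_ms),
                 venc = as.numeric(venc),
                 origin_mm = as.numeric(origin_mm)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_field> %d x %d x %d grid, %d phases, VENC %g cm/s\n",
              d[1L], d[2L], d[3L], d[4L], x$venc))
  cat(sprintf("  voxel %s mm, phase %g ms, |v| range [%.2f, %.2f] cm/s\n",
              paste(signif(x$voxel_mm, 3), collapse = " x "),
              x$phase_ms, min(abs(x$v)), max(abs(x$v))))
  invisible(x)
}

#' Number of cardiac phases of a velocity field
#' @param field a `velocity_field`
#' @export
n_phases <- function(field) dim(field$v)[4L]

#' Voxel volume in cm^3
#' @param field a `velocity_field`
#' @export
voxel_volume_cm3 <- function(field) prod(field$voxel_mm) / 1000

#' Voxel-centre physical coordinates along one axis, mm
#' @keywords internal
axis_coords <- function(field, axis) {
  n <- dim(field$v)[axis]
  field$origin_mm[axis] + (seq_len(n) - 1) * field$voxel_mm[axis]
}

#' Per-voxel speed (velocity magnitude) for one phase, cm/s
#' @keywords internal
phase_speed <- function(field, phase) {
  sqrt(field$v[, , , phase, 1L]^2 +
       field$v[, , , phase, 2L]^2 +
       field$v[, , , phase, 3L]^2)
}
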