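## Shared fixtures: small phantoms sized for fast unit tests.

small_spec <- function(...) {
  args <- list(grid_shape = c(24L, 24L, 20L), voxel_mm = 3, n_phases = 12L,
               es_phase = 5L, n_slices = 6L, slice_thickness_mm = 5,
               edv_ml = 35, esv_ml = 18)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

## Straight-cylinder phantom matching a pi r^2 h closed form.
cylinder_contours <- function(r_mm = 20, n_slices = 10L, thickness_mm = 8,
                              n_phases = 1L, centre = c(50, 50), n_vertices = 96L) {
  polys <- replicate(n_phases,
                     lapply(seq_len(n_slices), function(s)
                       rvkinergy:::circle_polygon(centre[1L], centre[2L], r_mm, n_vertices)),
                     simplify = FALSE)
  contour_stack(polys, slice_z_mm = (seq_len(n_slices) - 1L) * thickness_mm + thickness_mm / 2,
                slice_thickness_mm = thickness_mm)
}

## Minimal velocity field: constant per-component values on a small grid.
uniform_field <- function(v = c(0, 0, 0), d = c(8L, 8L, 6L), np = 2L,
                          voxel = 3, venc = 150, phase_ms = 30) {
  arr <- array(0, c(d, np, 3L))
  for (cc in 1:3) arr[, , , , cc] <- v[cc]
  velocity_field(arr, rep(voxel, 3L), phase_ms, venc)
}

## A hand-built cylindrical mesh (constant radius), independent of polygons.
manual_mesh <- function(radius_mm, centre = c(10.5, 10.5), n_levels = 10L,
                        n_angles = 64L, z_lo = 0, z_hi = 30, n_phases = 1L) {
  dz <- (z_hi - z_lo) / n_levels
  structure(list(radii = array(radius_mm, c(n_levels, n_angles, n_phases)),
                 centroid = array(rep(centre, each = n_levels),
                                  c(n_levels, 2L, n_phases)),
                 level_z_mm = z_lo + (seq_len(n_levels) - 0.5) * dz,
                 level_dz_mm = dz,
                 angles = (seq_len(n_angles) - 1L) * 2 * pi / n_angles,
                 n_phases = n_phases),
            class = "rv_mesh")
}

## Timing object for hand-built flow tests.
manual_timing <- function(es, np, split = NULL) {
  dia <- (es + 1L):np
  if (is.null(split)) split <- floor(length(dia) / 2)
  structure(list(es_phase = es, systole = 1L:es, diastole = dia,
                 e_window = dia[seq_len(split)],
                 a_window = dia[(split + 1L):length(dia)],
                 midpoint_fallback = FALSE),
            class = "cardiac_timing")
}
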