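test_that("two identical keyframes propagate to identical intermediate contours", {
  mk <- function(r) list(rvkinergy:::circle_polygon(50, 50, r, 64))
  key <- contour_stack(list(mk(25), mk(25)), 10, 8)
  out <- propagate_contours(key, n_phases = 8L, keyframe_phases = c(1L, 5L))
  for (ph in 2:8)
    expect_equal(out$contours[[ph]][[1L]], out$contours[[1L]][[1L]], tolerance = 1e-9)
})

test_that("radii interpolate linearly in phase between flanking keyframes", {
  mk <- function(r) list(rvkinergy:::circle_polygon(50, 50, r, 64))
  key <- contour_stack(list(mk(20), mk(30)), 10, 8)
  out <- propagate_contours(key, n_phases = 10L, keyframe_phases = c(1L, 6L))
  radius_at <- function(ph) {
    p <- out$contours[[ph]][[1L]]
    mean(sqrt(rowSums(sweep(p, 2L, rvkinergy:::polygon_centroid(p))^2)))
  }
  ## (3-1)/(6-1) * 10 + 20 = 24 mm
  expect_equal(radius_at(3L), 24, tolerance = 0.05)
  ## cyclic wrap: phase 10 sits 4/5 of the way from keyframe 6 back to keyframe 1
  expect_equal(radius_at(10L), 22, tolerance = 0.05)
  ## keyframe phases reproduce their (resampled) keyframes exactly
  rs <- rvkinergy:::resample_contour(key$contours[[1L]][[1L]], 96L)
  expect_equal(out$contours[[1L]][[1L]], rs, tolerance = 1e-12)
  expect_equal(rvkinergy:::polygon_area(out$contours[[1L]][[1L]]),
               rvkinergy:::polygon_area(rs))
})

test_that("a slice missing from one flanking keyframe is area-ramped toward zero", {
  full <- list(rvkinergy:::circle_polygon(50, 50, 20, 64),
               rvkinergy:::circle_polygon(50, 50, 15, 64))
  partial <- list(rvkinergy:::circle_polygon(50, 50, 20, 64), NULL)
  key <- contour_stack(list(full, partial), c(10, 18), 8)
  expect_message(out <- propagate_contours(key, n_phases = 6L, keyframe_phases = c(1L, 4L)),
                 "area-ramped")
  a1 <- rvkinergy:::polygon_area(out$contours[[1L]][[2L]])
  a2 <- rvkinergy:::polygon_area(out$contours[[2L]][[2L]])
  a3 <- rvkinergy:::polygon_area(out$contours[[3L]][[2L]])
  expect_equal(a2 / a1, 2 / 3, tolerance = 1e-6)
  expect_equal(a3 / a1, 1 / 3, tolerance = 1e-6)
  expect_null(out$contours[[4L]][[2L]])
})

test_that("mesh volume matches pi r^2 h for a cylinder and converges in angles", {
  cyl <- cylinder_contours(r_mm = 20, n_slices = 10L, thickness_mm = 8)
  mesh64 <- build_mesh(cyl, n_angles = 64L)
  expect_equal(mesh_volume(mesh64), 100.53, tolerance = 0.02)
  mesh128 <- build_mesh(cyl, n_angles = 128L)
  expect_lt(abs(mesh_volume(mesh128) - mesh_volume(mesh64)) / mesh_volume(mesh64),
            0.005)
})

test_that("mesh cross-sections of an elliptical cylinder match pi a b", {
  th <- seq(0, 2 * pi, length.out = 97L)[-97L]
  ell <- cbind(50 + 30 * cos(th), 50 + 15 * sin(th))
  st <- contour_stack(replicate(1L, list(ell, ell), simplify = FALSE),
                      c(10, 18), 8)
  mesh <- build_mesh(st, n_angles = 64L)
  level_area_mm2 <- mesh_volume(mesh) * 1000 / 16   # total z extent 16 mm
  expect_equal(level_area_mm2, pi * 30 * 15, tolerance = 0.02)
})

test_that("voxel masks recover the mesh volume and nest across phases", {
  spec <- small_spec()
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  mesh <- build_mesh(g$contours)
  masks <- mesh_to_mask(mesh, vf$field)
  vmask <- apply(masks$mask, 4L, sum) * masks$voxel_cm3
  expect_equal(vmask, mesh_volume(mesh), tolerance = 0.08)
  ## the shrunken end-systolic cavity is strictly inside the end-diastolic one
  expect_true(all(masks$mask[, , , spec$es_phase] <= masks$mask[, , , 1L]))
})

test_that("voxel centres exactly on the mesh boundary are inside (closed rule)", {
  ## constant-radius mesh at 9 mm on a 3 mm grid centred on a voxel centre:
  ## voxels at x = centre +- 9 mm sit exactly on the surface
  mesh <- manual_mesh(radius_mm = 9, centre = c(15, 15), z_lo = 0, z_hi = 18,
                      n_levels = 6L, n_phases = 2L)
  f <- uniform_field(d = c(11L, 11L, 7L), np = 2L, voxel = 3)
  m <- mesh_to_mask(mesh, f)
  expect_true(m$mask[9L, 6L, 3L, 1L])   # (24, 15) mm: exactly 9 mm from centre
  expect_true(m$mask[3L, 6L, 3L, 1L])   # (6, 15) mm
  expect_false(m$mask[10L, 6L, 3L, 1L]) # 12 mm away: outside
})

test_that("volume metrics implement EDV/ESV/SV/EF and BSA indexing", {
  spec <- phantom_spec()   # EDV 150, ESV 60
  g <- make_geometry(spec)
  vm <- compute_volumes(g$contours, bsa_m2 = 1.85)
  expect_equal(vm$sv_ml, vm$edv_ml - vm$esv_ml)
  expect_equal(vm$ef_pct, 100 * vm$sv_ml / vm$edv_ml)
  expect_equal(vm$ef_pct, 60, tolerance = 0.001)
  expect_equal(vm$sv_ml, 90, tolerance = 0.01)
  expect_equal(vm$edvi_ml_m2, vm$edv_ml / 1.85)
  expect_error(compute_volumes(g$contours, bsa_m2 = -1), "positive")
})

test_that("EF is invariant under uniform scaling of all contours", {
  g <- make_geometry(small_spec())
  scaled <- g$contours
  for (ph in seq_len(scaled$n_phases))
    scaled$contours[[ph]] <- lapply(scaled$contours[[ph]], function(p) p * 1.3)
  expect_equal(compute_volumes(scaled)$ef_pct, compute_volumes(g$contours)$ef_pct,
               tolerance = 1e-9)
})

test_that("TAPSE projects annular displacement onto the long axis", {
  lm <- matrix(0, 10L, 3L); lm[, 3L] <- seq(50, 22, length.out = 10L)
  expect_equal(compute_tapse(lm, es_phase = 10L), 28, tolerance = 1e-9)
  expect_equal(compute_tapse(matrix(5, 4L, 3L), es_phase = 3L), 0)
  ## pure in-plane motion projects to zero
  lm2 <- matrix(0, 6L, 3L); lm2[, 1L] <- 1:6
  expect_equal(compute_tapse(lm2, es_phase = 6L), 0)
  lm3 <- lm; lm3[10L, 1L] <- NA
  expect_true(is.na(compute_tapse(lm3, es_phase = 10L)))
})

test_that("right atrial area uses the shoelace formula with orientation invariance", {
  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 57.5, 57.5))
  out <- compute_raa(rect, bsa_m2 = 1.85)
  expect_equal(out$raa_cm2, 23)
  expect_equal(out$raai_cm2_m2, 23 / 1.85)
  expect_equal(compute_raa(rect[4:1, ])$raa_cm2, 23)
  expect_error(compute_raa(cbind(c(0, 10, 10, 0), c(5, 5, 5, 5))), "zero area")
  bowtie <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(compute_raa(bowtie), "self-intersecting")
})
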