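make_track <- function(np = 6L, centre = c(30, 30), z = 24, r = 15,
                       apex_z = 0) {
  lm <- array(NA_real_, c(np, 4L, 3L))
  ang <- c(0, 0.5, 1, 1.5) * pi
  for (j in 1:4) {
    lm[, j, 1L] <- centre[1L] + r * cos(ang[j])
    lm[, j, 2L] <- centre[2L] + r * sin(ang[j])
    lm[, j, 3L] <- z
  }
  list(landmarks_mm = lm,
       apex_mm = cbind(rep(centre[1L], np), rep(centre[2L], np), rep(apex_z, np)))
}

test_that("static annular landmarks give identical planes with an apex-ward normal", {
  planes <- track_plane(make_track())
  expect_equal(planes$centre_mm, matrix(rep(c(30, 30, 24), each = 6L), 6L))
  expect_equal(planes$normal, matrix(rep(c(0, 0, -1), each = 6L), 6L))
})

test_that("the tracked plane follows rigid annular translation exactly", {
  tr <- make_track()
  tr$landmarks_mm[4L, , 3L] <- tr$landmarks_mm[4L, , 3L] - 5   # 5 mm apex-ward at ES
  planes <- track_plane(tr)
  expect_equal(planes$centre_mm[4L, 3L], 19)
  expect_equal(planes$centre_mm[3L, 3L], 24)
})

test_that("collinear landmarks are rejected", {
  tr <- make_track()
  for (j in 1:4) tr$landmarks_mm[, j, ] <- matrix(rep(c(10 + j, 0, 24), each = 6L), 6L)
  expect_error(track_plane(tr), "collinear")
})

test_that("through-plane reformatting projects onto the plane normal", {
  d <- c(20L, 20L, 16L)
  planes <- track_plane(make_track(np = 2L, centre = c(28.5, 28.5), z = 24))
  ap <- rvkinergy:::circle_polygon(0, 0, 12, 64L)
  ## parallel: apex-ward (-z) flow appears at +|v|
  f1 <- uniform_field(c(0, 0, -40), d = d, np = 2L)
  m1 <- reformat_plane_velocity(f1, planes, ap, margin_mm = 5)
  expect_equal(mean(m1$vmap[, , 1L][m1$in_aperture]), 40, tolerance = 1e-9)
  ## perpendicular: in-plane flow projects to zero
  f2 <- uniform_field(c(40, 0, 0), d = d, np = 2L)
  m2 <- reformat_plane_velocity(f2, planes, ap, margin_mm = 5)
  expect_equal(max(abs(m2$vmap[, , 1L][m2$in_aperture])), 0, tolerance = 1e-9)
  ## 45 degrees: s/sqrt(2)
  s <- 40
  f3 <- uniform_field(c(s / sqrt(2), 0, -s / sqrt(2)), d = d, np = 2L)
  m3 <- reformat_plane_velocity(f3, planes, ap, margin_mm = 5)
  expect_equal(mean(m3$vmap[, , 1L][m3$in_aperture]), s / sqrt(2), tolerance = 1e-9)
})

test_that("myocardial background correction removes offsets and annular motion", {
  d <- c(20L, 20L, 16L)
  planes <- track_plane(make_track(np = 2L, centre = c(28.5, 28.5), z = 24))
  ap <- rvkinergy:::circle_polygon(0, 0, 10, 64L)
  roi <- list(outer = rvkinergy:::circle_polygon(0, 0, 20, 64L),
              inner = rvkinergy:::circle_polygon(0, 0, 14, 64L))
  ## constant +2 cm/s offset everywhere: removed exactly
  f <- uniform_field(c(0, 0, -2), d = d, np = 2L)
  maps <- background_correct_plane(reformat_plane_velocity(f, planes, ap, margin_mm = 12), roi)
  expect_equal(max(abs(maps$vmap)), 0, tolerance = 1e-9)
  expect_equal(attr(maps, "background_cm_s"), c(2, 2), tolerance = 1e-9)
  ## annulus moving at 3 cm/s through a static pool: corrected inflow is zero
  planes4 <- track_plane(make_track(np = 4L, centre = c(28.5, 28.5), z = 24))
  fm <- uniform_field(c(0, 0, 3), d = d, np = 4L)   # apparent base-ward motion
  mm <- background_correct_plane(reformat_plane_velocity(fm, planes4, ap, margin_mm = 12), roi)
  t4 <- manual_timing(es = 2L, np = 4L, split = 1L)
  expect_equal(tv_flow_metrics(mm, t4, net = TRUE)$sv_ml, 0, tolerance = 1e-9)
  ## zero-motion phantom: identity
  fz <- uniform_field(c(0, 0, 0), d = d, np = 2L)
  mz <- background_correct_plane(reformat_plane_velocity(fz, planes, ap, margin_mm = 12), roi)
  expect_equal(max(abs(mz$vmap)), 0)
  ## empty ROI: skipped with warning
  empty <- list(outer = rvkinergy:::circle_polygon(100, 100, 1, 16L))
  expect_warning(background_correct_plane(mz, empty), "skipped")
})

test_that("plug flow stroke volume matches v * A * t arithmetic", {
  d <- c(24L, 24L, 12L); np <- 10L
  arr <- array(0, c(d, np, 3L))
  arr[, , , 6:10, 3L] <- -50                     # 50 cm/s inflow for 5 phases
  f <- velocity_field(arr, c(3, 3, 3), 80, 150)  # 80 ms phases: 400 ms diastole
  planes <- track_plane(make_track(np = np, centre = c(34.5, 34.5), z = 24, apex_z = 0))
  ap <- rvkinergy:::circle_polygon(0, 0, sqrt(10 / pi) * 10, 256L)   # 10 cm^2
  maps <- reformat_plane_velocity(f, planes, ap, margin_mm = 2)
  tvf <- tv_flow_metrics(maps, manual_timing(es = 5L, np = np))
  expect_equal(tvf$sv_ml, 50 * 10 * 0.4, tolerance = 0.02)
  expect_equal(tvf$peak_e_vel, 50, tolerance = 1e-6)
})

test_that("stroke volume is invariant to in-plane rotation of the aperture", {
  d <- c(24L, 24L, 12L)
  arr <- array(0, c(d, 4L, 3L)); arr[, , , 3:4, 3L] <- -30
  f <- velocity_field(arr, c(3, 3, 3), 50, 150)
  planes <- track_plane(make_track(np = 4L, centre = c(34.5, 34.5), z = 24))
  sq <- cbind(c(-10, 10, 10, -10), c(-10, -10, 10, 10))
  rot <- function(p, a) p %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  t4 <- manual_timing(es = 2L, np = 4L, split = 1L)
  sv0 <- tv_flow_metrics(reformat_plane_velocity(f, planes, sq,
                                                 margin_mm = 2, pitch_mm = 0.5), t4)$sv_ml
  sv45 <- tv_flow_metrics(reformat_plane_velocity(f, planes, rot(sq, pi / 4),
                                                  margin_mm = 2, pitch_mm = 0.5), t4)$sv_ml
  expect_equal(sv45, sv0, tolerance = 0.01)
})

test_that("phantom tricuspid metrics recover programmed truth", {
  ph <- make_phantom(phantom_spec())
  vol <- compute_volumes(ph$contours)
  mesh <- build_mesh(ph$contours)
  masks <- mesh_to_mask(mesh, ph$field)
  kec <- ke_curve(ph$field, masks, vol$edv_ml)
  timing <- detect_cardiac_phases(vol$volume_ml, kec)
  planes <- track_plane(ph$annular_track)
  maps <- background_correct_plane(
    reformat_plane_velocity(ph$field, planes, ph$aperture_polygon_mm),
    ph$myocardium_roi)
  tvf <- tv_flow_metrics(maps, timing)
  expect_equal(tvf$sv_ml, ph$truth$tv_sv_ml, tolerance = 0.05)
  ## E/A velocity ratio equals the programmed speed ratio on plug-flow phantoms
  expect_equal(tvf$ea_vel_ratio, ph$spec$v_e / ph$spec$v_a, tolerance = 0.03)
})

test_that("zero fields yield zero flow metrics and an absent velocity ratio", {
  d <- c(16L, 16L, 12L)
  f <- uniform_field(c(0, 0, 0), d = d, np = 4L)
  planes <- track_plane(make_track(np = 4L, centre = c(22.5, 22.5), z = 24))
  ap <- rvkinergy:::circle_polygon(0, 0, 10, 64L)
  maps <- reformat_plane_velocity(f, planes, ap, margin_mm = 2)
  expect_warning(tvf <- tv_flow_metrics(maps, manual_timing(es = 2L, np = 4L, split = 1L)),
                 "no forward diastolic flow")
  expect_equal(tvf$sv_ml, 0)
  expect_true(is.na(tvf$ea_vel_ratio))
})
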