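test_that("voxel KE follows the erg-to-microjoule unit chain", {
  expect_equal(voxel_ke(0, 0.027), 0)
  ## v = 100 cm/s in a 3 mm voxel at rho = 1.06: 143.1 erg = 14.31 uJ
  expect_equal(voxel_ke(100, 0.027), 14.31, tolerance = 1e-9)
  expect_equal(voxel_ke(200, 0.027), 4 * voxel_ke(100, 0.027))
  expect_equal(voxel_ke(-100, 0.027), voxel_ke(100, 0.027))
  expect_error(voxel_ke(10, -1), "voxel_volume")
})

test_that("the KE curve equals the closed form on a uniform-speed phantom", {
  ## straight cylinder: the mask lies wholly inside the uniform-speed cavity,
  ## so summation reproduces 0.05 * rho * V_mask * v^2 exactly
  spec <- small_spec(taper = 0, edv_ml = 30, esv_ml = 15)
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  vol <- compute_volumes(g$contours)
  masks <- mesh_to_mask(build_mesh(g$contours), vf$field)
  kec <- ke_curve(vf$field, masks, edv_ml = vol$edv_ml)
  vmask <- apply(masks$mask, 4L, sum) * masks$voxel_cm3
  oracle <- 0.05 * 1.06 * vmask * vf$truth$speed_cm_s_per_phase^2
  expect_equal(kec$ke_uJ, oracle, tolerance = 1e-9)
  expect_equal(kec$kei_uJ_ml, kec$ke_uJ / vol$edv_ml)
  ## tapered apex: mesh levels interpolate between stepped discs, so a small
  ## band of mask voxels carries no flow; agreement stays within a few percent
  spec2 <- small_spec()
  g2 <- make_geometry(spec2)
  vf2 <- make_velocity_field(spec2, g2)
  masks2 <- mesh_to_mask(build_mesh(g2$contours), vf2$field)
  kec2 <- ke_curve(vf2$field, masks2, edv_ml = 35)
  vmask2 <- apply(masks2$mask, 4L, sum) * masks2$voxel_cm3
  oracle2 <- 0.05 * 1.06 * vmask2 * vf2$truth$speed_cm_s_per_phase^2
  nz <- oracle2 > 1
  expect_lt(max(abs(kec2$ke_uJ[nz] - oracle2[nz]) / oracle2[nz]), 0.05)
})

test_that("KE is additive over disjoint mask partitions and zero on zero fields", {
  spec <- small_spec()
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  masks <- mesh_to_mask(build_mesh(g$contours), vf$field)
  ## split every phase mask at the volume mid-plane
  lower <- masks; upper <- masks
  lower$mask[, , 11:20, ] <- FALSE
  upper$mask[, , 1:10, ] <- FALSE
  keep <- apply(lower$mask, 4L, any) & apply(upper$mask, 4L, any)
  expect_true(all(keep))
  k_all <- ke_curve(vf$field, masks, 35)$ke_uJ
  k_lo <- ke_curve(vf$field, lower, 35)$ke_uJ
  k_hi <- ke_curve(vf$field, upper, 35)$ke_uJ
  expect_equal(k_lo + k_hi, k_all, tolerance = 1e-12)
  ## zero velocity everywhere: identically zero curve
  zf <- vf$field; zf$v[] <- 0
  expect_equal(max(ke_curve(zf, masks, 35)$ke_uJ), 0)
})

test_that("cardiac phase detection finds programmed end-systole and E/A windows", {
  spec <- small_spec()
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  vol <- compute_volumes(g$contours)
  masks <- mesh_to_mask(build_mesh(g$contours), vf$field)
  kec <- ke_curve(vf$field, masks, vol$edv_ml)
  timing <- detect_cardiac_phases(vol$volume_ml, kec)
  expect_equal(timing$es_phase, spec$es_phase)
  prog <- vf$truth$program
  ie <- prog$e_phases[which.max(vf$truth$ke_uJ_per_phase[prog$e_phases])]
  ia <- prog$a_phases[which.max(vf$truth$ke_uJ_per_phase[prog$a_phases])]
  expect_true(ie %in% timing$e_window)
  expect_true(ia %in% timing$a_window)
})

test_that("bimodal diastolic KE splits at the trough; flat curves fall back to midpoint", {
  vol <- c(10, 8, 6, 5, 6, 7, 8, 9, 10, 10, 10, 10)
  kei <- c(1, 2, 1, 0.5, 1, 3, 1, 0.4, 2, 4, 2, 0.5)   # bumps at phases 6 and 10
  t1 <- detect_cardiac_phases(vol, kei)
  expect_equal(t1$es_phase, 4L)
  expect_true(6L %in% t1$e_window)
  expect_true(10L %in% t1$a_window)
  flat <- detect_cardiac_phases(vol, rep(1, 12))
  expect_true(flat$midpoint_fallback)
  expect_error(detect_cardiac_phases(sort(vol, decreasing = TRUE), kei),
               "no refilling")
})

test_that("a constant KEi curve collapses every summary parameter to the same value", {
  curve <- structure(list(ke_uJ = rep(70, 12), kei_uJ_ml = rep(2, 12),
                          time_ms = (0:11) * 30, edv_ml = 35, phase_ms = 30,
                          rho_g_cm3 = 1.06), class = "ke_curve")
  p <- extract_ke_parameters(curve, manual_timing(es = 5L, np = 12L))
  expect_equal(p$global_kei, 2)
  expect_equal(p$systolic_kei, 2)
  expect_equal(p$diastolic_kei, 2)
  expect_equal(p$min_kei, 2)
  expect_equal(p$peak_e_kei, 2)
  expect_equal(p$peak_a_kei, 2)
  expect_equal(p$ea_ratio, 1)
})

test_that("scaling velocities by alpha scales KE parameters by alpha^2, E/A ratio fixed", {
  spec <- small_spec()
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  vol <- compute_volumes(g$contours)
  masks <- mesh_to_mask(build_mesh(g$contours), vf$field)
  timing <- detect_cardiac_phases(vol$volume_ml,
                                  ke_curve(vf$field, masks, vol$edv_ml))
  p1 <- extract_ke_parameters(ke_curve(vf$field, masks, vol$edv_ml), timing)
  alpha <- 1.7
  f2 <- vf$field; f2$v <- f2$v * alpha
  p2 <- extract_ke_parameters(ke_curve(f2, masks, vol$edv_ml), timing)
  for (nm in c("global_kei", "systolic_kei", "diastolic_kei", "min_kei",
               "peak_e_kei", "peak_a_kei"))
    expect_equal(p2[[nm]], alpha^2 * p1[[nm]], tolerance = 1e-12)
  expect_equal(p2$ea_ratio, p1$ea_ratio, tolerance = 1e-12)
})

test_that("peak-based systolic/diastolic summaries are exposed as an option", {
  spec <- small_spec()
  g <- make_geometry(spec)
  vf <- make_velocity_field(spec, g)
  vol <- compute_volumes(g$contours)
  masks <- mesh_to_mask(build_mesh(g$contours), vf$field)
  kec <- ke_curve(vf$field, masks, vol$edv_ml)
  timing <- detect_cardiac_phases(vol$volume_ml, kec)
  pm <- extract_ke_parameters(kec, timing, window_stat = "mean")
  pp <- extract_ke_parameters(kec, timing, window_stat = "peak")
  expect_gte(pp$systolic_kei, pm$systolic_kei)
  expect_equal(pp$systolic_kei, max(kec$kei_uJ_ml[timing$systole]))
})
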