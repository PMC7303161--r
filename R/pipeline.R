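#' Run the full single-subject analysis pipeline
#'
#' Sequences preprocessing, geometry, kinetic-energy mapping and valve flow
#' for one subject, from either a phantom specification or real data paths,
#' and optionally writes the per-subject outputs (KE curve CSV, KE
#' parameter JSON, one-row metric CSV, resolved configuration and log).
#' All randomness flows from `config$seed`; a fixed configuration yields
#' byte-identical outputs.
#'
#' Configuration entries (all optional unless stated):
#' \describe{
#'   \item{phantom}{list of [phantom_spec()] arguments (phantom mode), or}
#'   \item{data}{list with `flow_dir`/`flow_prefix` and `contours` paths
#'     (real-data mode); exactly one of `phantom`/`data` must be present}
#'   \item{preprocess}{list: `wrap` (emulate aliasing before analysis),
#'     `unwrap`, `lpc`, `lpc_kernel_mm`, `static_sd`, `static_mag_frac`,
#'     `transform` (6 numbers: 3 rotations deg, 3 translations mm)}
#'   \item{keyframes}{keyframe phase indices; when present, contours are
#'     subset to these phases and re-propagated (the manual-contouring
#'     workflow); `NULL` uses all supplied contours}
#'   \item{bsa_m2}{body surface area (default 1.85)}
#'   \item{n_angles, n_levels}{mesh resolution}
#'   \item{window_stat}{`"mean"` or `"peak"` systolic/diastolic summaries}
#'   \item{net_flow}{integrate net instead of forward-only diastolic flow}
#'   \item{out_dir}{output directory; omit to skip writing}
#'   \item{seed}{integer (default 1)}
#' }
#'
#' @param config nested list as above, or path to a YAML file
#' @return list with `metrics` (one-row data.frame), `volumes`, `ke_curve`,
#'   `ke_parameters`, `timing`, `tv_flow`, `truth` (phantom mode), `log`
#' @export
run_subject <- function(config) {
  config <- resolve_config(config)
  seed <- config$seed %||% 1L
  set.seed(seed)
  log <- character(0L)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[rvkinergy] ", msg)
  }
  has_phantom <- !is.null(config$phantom)
  has_data <- !is.null(config$data)
  if (has_phantom == has_data)
    stop("config must contain exactly one of 'phantom' or 'data'")

  truth <- NULL
  if (has_phantom) {
    pargs <- config$phantom
    pargs$seed <- pargs$seed %||% seed
    spec <- do.call(phantom_spec, pargs)
    ph <- make_phantom(spec)
    field <- ph$field
    contours <- ph$contours
    truth <- ph$truth
    track <- ph$annular_track
    aperture <- ph$aperture_polygon_mm
    myo_roi <- ph$myocardium_roi
    say("phantom generated: EDV %.1f ml, ESV %.1f ml, %d phases",
        spec$edv_ml, spec$esv_ml, spec$n_phases)
  } else {
    field <- read_velocity_field(config$data$flow_dir,
                                 config$data$flow_prefix %||% "flow")
    contours <- read_contours_json(config$data$contours)
    track <- config$data$annular_track
    aperture <- config$data$aperture_polygon_mm
    myo_roi <- config$data$myocardium_roi
    say("data loaded: %d phases", n_phases(field))
  }

  pp <- config$preprocess %||% list()
  if (isTRUE(pp$wrap)) {
    field <- wrap_velocities(field)
    say("velocities wrapped at VENC %.0f cm/s", field$venc)
  }
  if (isTRUE(pp$unwrap)) {
    field <- unwrap_velocity(field)
    ul <- attr(field, "unwrap_log")
    say("unwrap: %d voxel corrections in %d sweeps (%d double-wraps flagged)",
        ul$n_corrected, ul$sweeps, ul$n_flagged_double)
  }
  if (isTRUE(pp$lpc)) {
    static <- detect_static_mask(field,
                                 std_threshold = pp$static_sd %||% 2,
                                 mag_threshold = pp$static_mag_frac %||% 0.2)
    field <- local_phase_correction(field, static,
                                    kernel_mm = pp$lpc_kernel_mm %||% 24)
    say("LPC applied over %d static voxels", attr(field, "lpc_log")$n_static)
  }
  if (!is.null(pp$transform)) {
    tr <- pp$transform
    field <- apply_rigid_transform(field,
                                   rigid_transform(tr[1:3], tr[4:6]))
    say("rigid transform applied (rot %s deg, trans %s mm)",
        paste(tr[1:3], collapse = "/"), paste(tr[4:6], collapse = "/"))
  }

  if (!is.null(config$keyframes)) {
    kf <- as.integer(config$keyframes)
    np <- contours$n_phases
    key_stack <- contour_stack(contours$contours[kf], contours$slice_z_mm,
                               contours$slice_thickness_mm)
    contours <- propagate_contours(key_stack, np, keyframe_phases = kf)
    say("contours propagated from keyframes %s", paste(kf, collapse = ","))
  }

  bsa <- config$bsa_m2 %||% 1.85
  vol <- compute_volumes(contours, bsa_m2 = bsa)
  say("cine volumes: EDV %.1f ml, ESV %.1f ml, EF %.1f%% (ES phase %d)",
      vol$edv_ml, vol$esv_ml, vol$ef_pct, vol$es_phase)
  mesh <- build_mesh(contours,
                     n_angles = config$n_angles %||% 64L,
                     n_levels = config$n_levels)
  masks <- mesh_to_mask(mesh, field)
  nv <- apply(masks$mask, 4L, sum)
  say("RV masks: %d..%d voxels per phase", min(nv), max(nv))

  kec <- ke_curve(field, masks, edv_ml = vol$edv_ml)
  timing <- detect_cardiac_phases(vol$volume_ml, kec)
  params <- extract_ke_parameters(kec, timing,
                                  window_stat = config$window_stat %||% "mean")
  say("KE: global %.2f, peak E %.2f, peak A %.2f uJ/ml (E/A %.3f)",
      params$global_kei, params$peak_e_kei, params$peak_a_kei, params$ea_ratio)

  tvf <- NULL
  if (!is.null(track) && !is.null(aperture)) {
    planes <- track_plane(track)
    maps <- reformat_plane_velocity(field, planes, aperture)
    if (!is.null(myo_roi)) maps <- background_correct_plane(maps, myo_roi)
    tvf <- tv_flow_metrics(maps, timing, net = isTRUE(config$net_flow))
    say("TV flow: SV %.1f ml, peak E %.1f / peak A %.1f cm/s",
        tvf$sv_ml, tvf$peak_e_vel, tvf$peak_a_vel)
  }

  metrics <- data.frame(
    edv_ml = vol$edv_ml, esv_ml = vol$esv_ml, sv_ml = vol$sv_ml,
    ef_pct = vol$ef_pct, es_phase = vol$es_phase,
    rvedvi = vol$edvi_ml_m2, rvesvi = vol$esvi_ml_m2, rvsvi = vol$svi_ml_m2,
    global_kei = params$global_kei, min_kei = params$min_kei,
    systolic_kei = params$systolic_kei, diastolic_kei = params$diastolic_kei,
    peak_e_kei = params$peak_e_kei, peak_a_kei = params$peak_a_kei,
    ea_kei_ratio = params$ea_ratio,
    tv_sv = if (is.null(tvf)) NA_real_ else tvf$sv_ml,
    peak_e_vel = if (is.null(tvf)) NA_real_ else tvf$peak_e_vel,
    peak_a_vel = if (is.null(tvf)) NA_real_ else tvf$peak_a_vel,
    ea_vel_ratio = if (is.null(tvf)) NA_real_ else tvf$ea_vel_ratio)

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(phase = seq_along(kec$ke_uJ),
                                time_ms = kec$time_ms,
                                ke_uJ = kec$ke_uJ,
                                kei_uJ_ml = kec$kei_uJ_ml),
                     file.path(od, "ke_curve.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(params), file.path(od, "ke_parameters.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(metrics, file.path(od, "metrics.csv"), row.names = FALSE)
    yaml::write_yaml(config, file.path(od, "resolved_config.yaml"))
    writeLines(log, file.path(od, "run_subject.log"))
  }

  list(metrics = metrics, volumes = vol, ke_curve = kec,
       ke_parameters = params, timing = timing, tv_flow = tvf,
       truth = truth, log = log)
}

#' Run the cohort-level analysis
#'
#' Either generates a synthetic cohort from `config$cohort` (a list of
#' [cohort_spec()] arguments) or aggregates a supplied per-subject table
#' (`config$cohort_csv`), then builds the cohort report and writes the four
#' standard tables plus a JSON report.
#'
#' @param config nested list or YAML path; entries `cohort` or
#'   `cohort_csv`, plus optional `age_breaks`, `n_groups`, `out_dir`,
#'   `seed`
#' @return a `cohort_result` with the generated/loaded `cohort` attached as
#'   attribute `"cohort"`
#' @export
run_cohort <- function(config) {
  config <- resolve_config(config)
  seed <- config$seed %||% 1L
  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort_csv(config$cohort_csv)
    truth <- NULL
  } else if (!is.null(config$cohort)) {
    cargs <- config$cohort
    cargs$seed <- cargs$seed %||% seed
    cs <- do.call(cohort_spec, cargs)
    gen <- make_cohort(cs)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    stop("config must contain 'cohort' (synthetic spec) or 'cohort_csv'")
  }
  if (nrow(cohort) < 3L) stop("cohort too small: need at least 3 subjects")
  report <- build_report(cohort,
                         age_breaks = config$age_breaks,
                         n_groups = config$n_groups %||% 5L)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(od, "cohort.csv"))
    utils::write.csv(report$descriptives, file.path(od, "table1_descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(report$correlations, file.path(od, "table2_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(rbind(cbind(model = "univariate",
                                 stats::setNames(report$regression$univariate,
                                                 c("variable", "beta", "se", "p"))),
                           if (nrow(report$regression$multivariate))
                             cbind(model = "multivariate",
                                   report$regression$multivariate)),
                     file.path(od, "table3_regression.csv"), row.names = FALSE)
    utils::write.csv(report$age_groups$summary,
                     file.path(od, "table4_age_groups.csv"), row.names = FALSE)
    jsonlite::write_json(list(n = report$n,
                              correlations = report$correlations,
                              selected = report$regression$selected,
                              group_sizes = as.integer(report$age_groups$sizes)),
                         file.path(od, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "cohort") <- cohort
  attr(report, "truth") <- truth
  report
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}
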