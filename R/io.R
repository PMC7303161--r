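#' Write a velocity field as NIfTI volumes with a JSON sidecar
#'
#' One 4D NIfTI file per velocity component (`<prefix>_vx/vy/vz.nii.gz`,
#' cm/s), an optional magnitude volume, and `<prefix>.json` holding the
#' acquisition geometry (voxel spacing, phase duration, VENC, origin).
#'
#' @param field a `velocity_field`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the sidecar path
#' @export
write_velocity_field <- function(field, dir, prefix = "flow") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- c("vx", "vy", "vz")
  for (cc in 1:3) {
    img <- RNifti::asNifti(field$v[, , , , cc],
                           pixdim = c(field$voxel_mm, field$phase_ms / 1000),
                           datatype = "double")
    RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_", comp[cc], ".nii.gz")))
  }
  if (!is.null(field$mag)) {
    img <- RNifti::asNifti(field$mag, pixdim = field$voxel_mm,
                           datatype = "double")
    RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_mag.nii.gz")))
  }
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(list(venc_cm_s = field$venc,
                            phase_ms = field$phase_ms,
                            voxel_mm = field$voxel_mm,
                            origin_mm = field$origin_mm,
                            has_magnitude = !is.null(field$mag)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a velocity field written by [write_velocity_field()]
#' @param dir directory holding the files
#' @param prefix file-name prefix
#' @return a `velocity_field`
#' @export
read_velocity_field <- function(dir, prefix = "flow") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  comp <- c("vx", "vy", "vz")
  vols <- lapply(comp, function(cn) {
    as.array(RNifti::readNifti(file.path(dir, paste0(prefix, "_", cn, ".nii.gz"))))
  })
  d <- dim(vols[[1L]])
  v <- array(0, c(d, 3L))
  for (cc in 1:3) v[, , , , cc] <- vols[[cc]]
  mag <- if (isTRUE(meta$has_magnitude)) {
    img <- RNifti::readNifti(file.path(dir, paste0(prefix, "_mag.nii.gz")))
    array(as.numeric(img), dim(img))
  } else NULL
  velocity_field(v, meta$voxel_mm, meta$phase_ms, meta$venc_cm_s,
                 mag = mag, origin_mm = meta$origin_mm)
}

#' Write an endocardial contour stack as JSON
#'
#' Schema: one record per contoured slice,
#' `{phase, slice_index, z_mm, points_mm: [[x, y], ...]}`, plus the slice
#' geometry in the header.
#'
#' @param contours a `contour_stack`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_contours_json <- function(contours, path) {
  recs <- list()
  for (ph in seq_len(contours$n_phases)) {
    for (sl in seq_along(contours$slice_z_mm)) {
      p <- contours$contours[[ph]][[sl]]
      if (is.null(p)) next
      recs[[length(recs) + 1L]] <- list(phase = ph, slice_index = sl,
                                        z_mm = contours$slice_z_mm[sl],
                                        points_mm = unname(apply(p, 1L, as.list)))
    }
  }
  jsonlite::write_json(list(n_phases = contours$n_phases,
                            slice_z_mm = contours$slice_z_mm,
                            slice_thickness_mm = contours$slice_thickness_mm,
                            contours = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour stack written by [write_contours_json()]
#' @param path JSON file
#' @return a `contour_stack`
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n_phases <- obj$n_phases
  slice_z <- unlist(obj$slice_z_mm)
  cl <- replicate(n_phases, vector("list", length(slice_z)), simplify = FALSE)
  for (rec in obj$contours) {
    pts <- do.call(rbind, lapply(rec$points_mm, function(p) unlist(p)))
    cl[[rec$phase]][[rec$slice_index]] <- unname(pts)
  }
  contour_stack(cl, slice_z, obj$slice_thickness_mm)
}

#' Write / read a cohort table as CSV
#'
#' Plain CSV with a header row; columns are `subject`, `age` (years),
#' `sex` (F/M), `bsa` (m^2) and one column per derived metric.
#'
#' @param cohort data.frame
#' @param path CSV file
#' @return invisibly, `path`
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
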