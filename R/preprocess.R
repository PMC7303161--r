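#' Detect signal-bearing static tissue
#'
#' Voxels usable as the static reference for background-offset estimation:
#' temporal standard deviation of the speed below `std_threshold` (no flow)
#' AND magnitude at least `mag_threshold` times the volume median magnitude
#' (signal-bearing tissue, not noisy air). Without a magnitude volume only
#' the temporal criterion applies.
#'
#' @param field a `velocity_field` with >= 2 phases
#' @param std_threshold temporal speed SD threshold, cm/s
#' @param mag_threshold fraction of the median magnitude
#' @return logical volume `(nx, ny, nz)`
#' @export
detect_static_mask <- function(field, std_threshold = 2, mag_threshold = 0.2) {
  d <- dim(field$v)
  np <- d[4L]
  nvox <- prod(d[1:3])
  sp <- matrix(0, nvox, np)
  for (t in seq_len(np)) sp[, t] <- as.vector(phase_speed(field, t))
  mu <- rowMeans(sp)
  sdv <- sqrt(pmax(rowSums((sp - mu)^2) / (np - 1), 0))
  static <- sdv < std_threshold
  if (!is.null(field$mag))
    static <- static & (as.vector(field$mag) >= mag_threshold * stats::median(field$mag))
  array(static, d[1:3])
}

## Truncated-window box sum of a matrix (integral-image), half-widths h1, h2.
box_filter2d <- function(m, h1, h2) {
  n1 <- nrow(m); n2 <- ncol(m)
  C <- rbind(0, apply(m, 2L, cumsum))
  hi <- pmin(seq_len(n1) + h1, n1); lo <- pmax(seq_len(n1) - h1 - 1L, 0L)
  m2 <- C[hi + 1L, , drop = FALSE] - C[lo + 1L, , drop = FALSE]
  C2 <- cbind(0, t(apply(m2, 1L, cumsum)))
  hj <- pmin(seq_len(n2) + h2, n2); lj <- pmax(seq_len(n2) - h2 - 1L, 0L)
  C2[, hj + 1L, drop = FALSE] - C2[, lj + 1L, drop = FALSE]
}

#' Local phase correction (LPC) of residual background offsets
#'
#' Removes residual background velocity offsets slice by slice: per slice,
#' phase and component, a smooth offset surface is estimated as the
#' magnitude-weighted local average of the velocity over static voxels
#' (square window of width `kernel_mm`) and subtracted from every voxel of
#' the slice. Flowing-region velocities change only by the estimated local
#' offset. Positions whose window contains no static voxel fall back to the
#' slice-wide weighted mean; slices without any static voxel are skipped
#' with a warning.
#'
#' @param field a `velocity_field`
#' @param static logical static-tissue volume from [detect_static_mask()]
#' @param kernel_mm window width, mm (must cover at least one voxel)
#' @return corrected `velocity_field`; attribute `"lpc_log"` records the
#'   static voxel count and skipped slices
#' @export
local_phase_correction <- function(field, static, kernel_mm = 24) {
  d <- dim(field$v)
  stopifnot(all(dim(static) == d[1:3]))
  if (kernel_mm < max(field$voxel_mm[1:2]))
    stop("kernel_mm (", kernel_mm, ") smaller than one voxel")
  if (!any(static))
    stop("static mask is empty: no reference tissue for offset estimation")
  h1 <- max(1L, floor(kernel_mm / field$voxel_mm[1L] / 2))
  h2 <- max(1L, floor(kernel_mm / field$voxel_mm[2L] / 2))
  skipped <- integer(0L)
  wbase <- if (is.null(field$mag)) array(1, d[1:3]) else field$mag
  for (k in seq_len(d[3L])) {
    w <- wbase[, , k] * static[, , k]
    if (!any(w > 0)) { skipped <- c(skipped, k); next }
    den <- box_filter2d(w, h1, h2)
    for (t in seq_len(d[4L])) {
      for (cc in 1:3) {
        vk <- field$v[, , k, t, cc]
        num <- box_filter2d(w * vk, h1, h2)
        off <- num / den
        off[den <= 0] <- sum(w * vk) / sum(w)
        field$v[, , k, t, cc] <- vk - off
      }
    }
  }
  if (length(skipped))
    warning("LPC skipped ", length(skipped),
            " slice(s) without static voxels: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  attr(field, "lpc_log") <- list(n_static = sum(static), skipped_slices = skipped)
  field
}

#' Unwrap phase-aliased velocities
#'
#' Voxels whose value jumps by about `2 venc` relative to the median of
#' their spatio-temporal neighbourhood (3x3x3 spatial window plus adjacent
#' phases) are shifted by the corresponding multiple of `2 venc`, iterating
#' from the wrap boundary inwards until stable. Only single wraps are
#' corrected; apparent double wraps are flagged and left untouched. In-range
#' fields pass through unchanged, and no voxel is ever altered by anything
#' other than an integer multiple of `2 venc`.
#'
#' @param field a `velocity_field`
#' @param max_iter maximum correction sweeps
#' @return unwrapped `velocity_field`; attribute `"unwrap_log"` holds the
#'   corrected/flagged voxel counts and sweep count
#' @export
unwrap_velocity <- function(field, max_iter = 50L) {
  venc <- field$venc
  d <- dim(field$v)
  n_corrected <- 0L; n_double <- 0L; iter <- 0L
  for (i in seq_len(max_iter)) {
    iter <- i
    changed <- FALSE
    for (cc in 1:3) {
      comp <- field$v[, , , , cc]
      med <- median_filter4(comp, dim(comp))
      dif <- comp - med
      dbl <- abs(dif) > 3 * venc
      if (i == 1L) n_double <- n_double + sum(dbl)
      up <- dif < -venc & !dbl
      dn <- dif > venc & !dbl
      nfix <- sum(up) + sum(dn)
      if (nfix > 0L) {
        comp[up] <- comp[up] + 2 * venc
        comp[dn] <- comp[dn] - 2 * venc
        field$v[, , , , cc] <- comp
        n_corrected <- n_corrected + nfix
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(field, "unwrap_log") <- list(n_corrected = n_corrected,
                                    n_flagged_double = n_double,
                                    sweeps = iter)
  field
}

#' Rigid cine-to-flow transform
#'
#' Rotation (degrees, applied about the volume centre as Rz Ry Rx) followed
#' by translation (mm). The transform itself is estimated elsewhere (for
#' example by image registration) and supplied here.
#'
#' @param rotation_deg length-3 rotation angles about x, y, z, degrees
#' @param translation_mm length-3 translation, mm
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3L, length(translation_mm) == 3L,
            all(is.finite(rotation_deg)), all(is.finite(translation_mm)))
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1L]); sx <- sin(a[1L])
  cy <- cos(a[2L]); sy <- sin(a[2L])
  cz <- cos(a[3L]); sz <- sin(a[3L])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  Rz %*% Ry %*% Rx
}

## Trilinear sampling of a 3D array at fractional 1-based voxel coordinates.
## Out-of-grid samples return 0.
trilinear_sample <- function(a, x, y, z) {
  d <- dim(a)
  ok <- x >= 1 & x <= d[1L] & y >= 1 & y <= d[2L] & z >= 1 & z <= d[3L]
  out <- numeric(length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1L] - 1L); y0 <- pmin(floor(y), d[2L] - 1L)
  z0 <- pmin(floor(z), d[3L] - 1L)
  x0 <- pmax(x0, 1L); y0 <- pmax(y0, 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) i + d[1L] * ((j - 1L) + d[2L] * (k - 1L))
  v000 <- a[idx(x0, y0, z0)];       v100 <- a[idx(x0 + 1, y0, z0)]
  v010 <- a[idx(x0, y0 + 1, z0)];   v110 <- a[idx(x0 + 1, y0 + 1, z0)]
  v001 <- a[idx(x0, y0, z0 + 1)];   v101 <- a[idx(x0 + 1, y0, z0 + 1)]
  v011 <- a[idx(x0, y0 + 1, z0 + 1)]; v111 <- a[idx(x0 + 1, y0 + 1, z0 + 1)]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

#' Apply a rigid transform to a velocity field
#'
#' Resamples the grid (trilinear) under the transform and rotates the
#' velocity vectors by the same rotation; the zero transform is the
#' identity. Samples falling outside the field of view become zero; if the
#' whole volume maps outside, a coverage error is raised.
#'
#' @param field a `velocity_field`
#' @param transform a [rigid_transform()]
#' @return transformed `velocity_field`
#' @export
apply_rigid_transform <- function(field, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  d <- dim(field$v)
  R <- rotation_matrix(transform$rotation_deg)
  xs <- axis_coords(field, 1L); ys <- axis_coords(field, 2L); zs <- axis_coords(field, 3L)
  ctr <- c(mean(range(xs)), mean(range(ys)), mean(range(zs)))
  G <- cbind(rep(xs, times = d[2L] * d[3L]),
             rep(rep(ys, each = d[1L]), times = d[3L]),
             rep(zs, each = d[1L] * d[2L]))
  ## source physical point for each output voxel
  S <- sweep(sweep(G, 2L, ctr + transform$translation_mm) %*% R, 2L, ctr, `+`)
  ix <- (S[, 1L] - field$origin_mm[1L]) / field$voxel_mm[1L] + 1
  iy <- (S[, 2L] - field$origin_mm[2L]) / field$voxel_mm[2L] + 1
  iz <- (S[, 3L] - field$origin_mm[3L]) / field$voxel_mm[3L] + 1
  inside <- ix >= 1 & ix <= d[1L] & iy >= 1 & iy <= d[2L] & iz >= 1 & iz <= d[3L]
  if (!any(inside))
    stop("rigid transform maps the whole volume outside the field of view")
  out <- array(0, d)
  for (t in seq_len(d[4L])) {
    vs <- lapply(1:3, function(cc)
      trilinear_sample(field$v[, , , t, cc], ix, iy, iz))
    for (cc in 1:3) {
      out[, , , t, cc] <- array(R[cc, 1L] * vs[[1L]] + R[cc, 2L] * vs[[2L]] +
                                R[cc, 3L] * vs[[3L]], d[1:3])
    }
  }
  field$v <- out
  if (!is.null(field$mag))
    field$mag <- array(trilinear_sample(field$mag, ix, iy, iz), d[1:3])
  field
}
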