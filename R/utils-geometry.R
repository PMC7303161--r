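## Shared low-level geometry and unit helpers.

## Unit chain for kinetic energy: rho [g/cm^3] * V [cm^3] * v^2 [cm^2/s^2]
## gives erg; 1 erg = 0.1 uJ. The 0.5 of the kinetic-energy formula and the
## erg->uJ conversion are kept in a single constant so the conversion lives
## in exactly one place.
.KE_UJ_FACTOR <- 0.5 * 0.1

#' Density of blood used throughout the package (g/cm^3)
#' @keywords internal
.RHO_BLOOD <- 1.06

#' Signed polygon area (shoelace), mm^2 for mm inputs
#' @param xy two-column matrix of vertices (closed implicitly)
#' @keywords internal
polygon_area_signed <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

polygon_area <- function(xy) abs(polygon_area_signed(xy))

#' Area centroid of a simple polygon
#' @keywords internal
polygon_centroid <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps * 100) return(c(mean(x), mean(y)))
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  c(cx, cy)
}

#' Regular polygon approximating a circle
#' @keywords internal
circle_polygon <- function(cx, cy, r, n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Does a closed polygon self-intersect (non-adjacent edge crossing)?
#' @keywords internal
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  seg <- function(i) rbind(xy[i, ], xy[if (i == n) 1L else i + 1L, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    si <- seg(i)
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      sj <- seg(j)
      if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Radial distance from a centroid to a polygon boundary along rays
#'
#' Casts rays from `centre` at the given angles and returns the distance to
#' the nearest boundary intersection along each ray (the cylindrical-mesh
#' radius definition). Convex/star-shaped polygons have a unique
#' intersection; otherwise the nearest one is used with a warning.
#'
#' @param xy polygon vertices (two columns, mm)
#' @param centre length-2 centre point
#' @param angles radians
#' @return numeric vector of radii, mm
#' @keywords internal
polygon_polar_radii <- function(xy, centre, angles, warn_nonstar = TRUE) {
  P <- sweep(xy, 2L, centre)
  n <- nrow(P)
  A <- P
  E <- P[c(2:n, 1L), , drop = FALSE] - P
  dx <- cos(angles); dy <- sin(angles)
  ## t = (A x d)/(d x E); r = (A + tE) . d
  AxD <- outer(A[, 1L], dy) - outer(A[, 2L], dx)     # n x m
  DxE <- outer(dx, E[, 2L]) - outer(dy, E[, 1L])     # m x n
  t <- AxD / t(DxE)
  Px <- A[, 1L] + t * E[, 1L]   # recycled columnwise: t is n x m
  Py <- A[, 2L] + t * E[, 2L]
  r <- sweep(Px, 2L, dx, `*`) + sweep(Py, 2L, dy, `*`)
  ok <- t >= 0 & t < 1 & r > 1e-9
  r[!ok] <- NA_real_
  if (warn_nonstar) {
    ## a ray through a vertex hits two edges at the same distance; only
    ## materially distinct intersections indicate a non-star-shaped polygon
    rmin <- suppressWarnings(apply(r, 2L, min, na.rm = TRUE))
    rmax <- suppressWarnings(apply(r, 2L, max, na.rm = TRUE))
    distinct <- is.finite(rmin) & is.finite(rmax) & (rmax - rmin > 1e-6 * pmax(rmax, 1))
    if (any(distinct))
      warning("polygon not star-shaped about centroid; using nearest boundary intersection",
              call. = FALSE)
  }
  out <- suppressWarnings(apply(r, 2L, min, na.rm = TRUE))
  if (any(!is.finite(out))) {
    ## numerical miss (ray through a vertex): fall back to nearest vertex distance
    miss <- !is.finite(out)
    out[miss] <- min(sqrt(rowSums(P^2)))
  }
  out
}

#' Crossing-number point-in-polygon test, vectorised over points
#' @param px,py point coordinates
#' @param xy polygon vertices
#' @keywords internal
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1L]; yi <- xy[i, 2L]
    xj <- xy[j, 1L]; yj <- xy[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Resample a closed contour to a fixed vertex count by arc length
#'
#' Vertices are ordered counter-clockwise and anchored at the boundary point
#' lying on the positive-x ray from the area centroid, so matched vertex
#' indices correspond across phases.
#' @keywords internal
resample_contour <- function(xy, n_out = 96L) {
  if (polygon_area_signed(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  cen <- polygon_centroid(xy)
  ## rotate vertex order so the walk starts at the angle-0 boundary point
  r0 <- polygon_polar_radii(xy, cen, 0, warn_nonstar = FALSE)
  anchor <- c(cen[1L] + r0, cen[2L])
  ## insert anchor into the boundary walk
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  ## find the edge containing the anchor (distance along edge minimal)
  ex <- xy[nxt, 1L] - xy[, 1L]; ey <- xy[nxt, 2L] - xy[, 2L]
  len2 <- ex^2 + ey^2
  tt <- ((anchor[1L] - xy[, 1L]) * ex + (anchor[2L] - xy[, 2L]) * ey) / pmax(len2, 1e-12)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- xy[, 1L] + tt * ex; qy <- xy[, 2L] + tt * ey
  d2 <- (qx - anchor[1L])^2 + (qy - anchor[2L])^2
  k <- which.min(d2)
  pts <- rbind(c(qx[k], qy[k]),
               xy[if (k == n) seq_len(0L) else (k + 1L):n, , drop = FALSE],
               xy[seq_len(k), , drop = FALSE])
  ## drop duplicated walk points (anchor may coincide with a vertex),
  ## including a final point that closes onto the first
  seglen <- sqrt(diff(c(pts[, 1L], pts[1L, 1L]))^2 + diff(c(pts[, 2L], pts[1L, 2L]))^2)
  keep <- c(TRUE, seglen[-length(seglen)] > 1e-9)
  keep[length(keep)] <- keep[length(keep)] && seglen[length(seglen)] > 1e-9
  pts <- pts[keep, , drop = FALSE]
  seglen <- sqrt(diff(c(pts[, 1L], pts[1L, 1L]))^2 + diff(c(pts[, 2L], pts[1L, 2L]))^2)
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  px <- stats::approx(s, c(pts[, 1L], pts[1L, 1L]), xout = target)$y
  py <- stats::approx(s, c(pts[, 2L], pts[1L, 2L]), xout = target)$y
  cbind(px, py, deparse.level = 0L)
}

#' Quantile of a truncated normal distribution
#' @keywords internal
qtruncnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + p * (pu - pl), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
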