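# Long-axis alignment by iterated 2D projection + moment ellipse fitting,
# mirroring the segmentation-era workflow: project the cell onto a plane
# through the Z axis, fit an ellipse, rotate its major axis onto Z, repeat
# with the orthogonal plane until converged.

#' Binary projection of the foreground onto a plane through the Z axis
#'
#' @param vol A [new_label_volume()] object.
#' @param plane `"xz"` (collapse Y) or `"yz"` (collapse X).
#' @param cytoplasm_label Optional label excluded from the foreground.
#' @return Logical matrix; the first axis is X (or Y), the second axis is Z,
#'   so ellipse angles from [ellipse_orientation()] are measured against Z.
#' @export
project_mask <- function(vol, plane = c("xz", "yz"), cytoplasm_label = NULL) {
  plane <- match.arg(plane)
  fg <- vol$voxels != 0L
  if (!is.null(cytoplasm_label)) fg <- fg & vol$voxels != cytoplasm_label
  if (!any(fg)) abort_degenerate("volume has no foreground to project")
  # voxels are (z, y, x): keep z plus x or y
  m <- if (plane == "xz") apply(fg, c(3, 1), any) else apply(fg, c(2, 1), any)
  m
}

#' Major-axis orientation of a binary mask from second central moments
#'
#' `angle = 0.5 * atan2(2 * m11, m20 - m02)` in degrees, in `(-90, 90]`,
#' measured from the mask's second array axis (positive toward the first
#' axis).  A degenerate mask (`m11 == 0` and `m20 == m02`, e.g. a disc)
#' returns 0 by convention.
#'
#' @param mask Logical (or 0/1) matrix with at least 2 on-pixels.
#' @return Angle in degrees.
#' @export
ellipse_orientation <- function(mask) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) < 2L) abort_degenerate("need at least 2 pixels to fit")
  v <- pts[, 1] - mean(pts[, 1])   # first axis
  u <- pts[, 2] - mean(pts[, 2])   # second axis (reference for the angle)
  m20 <- sum(u^2); m02 <- sum(v^2); m11 <- sum(u * v)
  if (m11 == 0 && m20 == m02) return(0)
  ang <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  ang
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
}

foreground_centroid_index <- function(vol, cytoplasm_label = NULL) {
  fg <- vol$voxels != 0L
  if (!is.null(cytoplasm_label)) fg <- fg & vol$voxels != cytoplasm_label
  idx <- which(fg, arr.ind = TRUE)
  colMeans(idx)   # (k, j, i)
}

# Re-voxelize under a rigid rotation about `center` (index space, isotropic
# spacing): out[q] = in[round(R^T (q - c) + c)], nearest neighbor, chunked
# over Z to bound memory.  R acts on world (x, y, z) vectors.
rotate_volume <- function(vol, rotation, center_kji) {
  d <- dim(vol$voxels)
  out <- array(0L, d)
  cx <- center_kji[3]; cy <- center_kji[2]; cz <- center_kji[1]
  Rt <- t(rotation)
  chunk <- max(1L, as.integer(2e6 / (d[2] * d[3])))
  for (k0 in seq(1L, d[1], by = chunk)) {
    k1 <- min(d[1], k0 + chunk - 1L)
    nk <- k1 - k0 + 1L
    kk <- rep(k0:k1, times = d[2] * d[3])
    jj <- rep(rep(seq_len(d[2]), each = nk), times = d[3])
    ii <- rep(seq_len(d[3]), each = nk * d[2])
    px <- ii - cx; py <- jj - cy; pz <- kk - cz
    sx <- Rt[1, 1] * px + Rt[1, 2] * py + Rt[1, 3] * pz + cx
    sy <- Rt[2, 1] * px + Rt[2, 2] * py + Rt[2, 3] * pz + cy
    sz <- Rt[3, 1] * px + Rt[3, 2] * py + Rt[3, 3] * pz + cz
    si <- as.integer(round(sx)); sj <- as.integer(round(sy))
    sk <- as.integer(round(sz))
    ok <- si >= 1L & si <= d[3] & sj >= 1L & sj <= d[2] &
      sk >= 1L & sk <= d[1]
    vals <- integer(nk * d[2] * d[3])
    lin <- (si[ok] - 1L) * (d[1] * d[2]) + (sj[ok] - 1L) * d[1] + sk[ok]
    vals[ok] <- vol$voxels[lin]
    out[k0:k1, , ] <- vals
  }
  new_label_volume(out, vol$spacing, vol$label_names)
}

#' Align the cell long axis with +Z
#'
#' Alternates two moment-based ellipse fits on orthogonal projections:
#' project the foreground onto the XZ plane, rotate about Y so the fitted
#' major axis becomes parallel to Z, then the same with the YZ projection
#' and a rotation about X, until both fitted angles are below `tol_deg` or
#' `max_iter` passes are used.  Rotations are taken about the foreground
#' centroid and labels are re-voxelized by nearest neighbor under the
#' accumulated rotation (always from the original volume, so label identity
#' never degrades).  After convergence the shell is flipped 180 degrees
#' about X, if needed, so that the aperture end sits at high Z; the flip is
#' decided by the sign of the third central moment of foreground mass along
#' Z (an egg carries more mass near its wide, aperture end, giving a
#' negative Z skewness when the aperture is up) and can be forced or
#' suppressed with `flip_z`.
#'
#' @param vol A [new_label_volume()] with isotropic spacing.
#' @param tol_deg Convergence tolerance on the fitted angles, degrees.
#' @param max_iter Maximum number of projection/rotation passes.
#' @param cytoplasm_label Optional label excluded from the fit (it still
#'   rotates with the volume).
#' @param flip_z `"auto"` (skewness heuristic), `"never"`, or `"always"`.
#' @return A list with `volume` (the aligned [new_label_volume()]) and
#'   `result`, a list of class `alignment_result`: `rotation` (3x3, acting
#'   on world (x, y, z)), `center` (world micrometres), `residual_angle`
#'   (degrees), `iterations`, `converged` and `flipped`.
#' @export
align_long_axis <- function(vol, tol_deg = 0.5, max_iter = 10,
                            cytoplasm_label = NULL,
                            flip_z = c("auto", "never", "always")) {
  flip_z <- match.arg(flip_z)
  s <- require_isotropic(vol, "align_long_axis()")
  center <- foreground_centroid_index(vol, cytoplasm_label)
  R <- diag(3)
  cur <- vol
  iter <- 0L
  a_xz <- a_yz <- Inf
  repeat {
    iter <- iter + 1L
    a_xz <- ellipse_orientation(project_mask(cur, "xz", cytoplasm_label))
    if (abs(a_xz) > tol_deg) {
      # mask axes are (x, z); positive angle tips +z toward +x, undone by
      # rotating the volume by -angle about Y
      R <- rot_y(-a_xz) %*% R
      cur <- rotate_volume(vol, R, center)
    }
    a_yz <- ellipse_orientation(project_mask(cur, "yz", cytoplasm_label))
    if (abs(a_yz) > tol_deg) {
      R <- rot_x(a_yz) %*% R
      cur <- rotate_volume(vol, R, center)
    }
    conv <- abs(a_xz) <= tol_deg && abs(a_yz) <= tol_deg
    if (conv || iter >= max_iter) break
  }
  # re-measure the residual on the final volume
  a_xz <- ellipse_orientation(project_mask(cur, "xz", cytoplasm_label))
  a_yz <- ellipse_orientation(project_mask(cur, "yz", cytoplasm_label))
  residual <- sqrt(a_xz^2 + a_yz^2)

  flipped <- FALSE
  if (flip_z != "never") {
    fg <- cur$voxels != 0L
    if (!is.null(cytoplasm_label)) fg <- fg & cur$voxels != cytoplasm_label
    kz <- which(fg, arr.ind = TRUE)[, 1]
    m3 <- mean((kz - mean(kz))^3)
    if (flip_z == "always" || (flip_z == "auto" && m3 > 0)) {
      R <- rot_x(180) %*% R
      cur <- rotate_volume(vol, R, center)
      flipped <- TRUE
    }
  }
  res <- structure(list(
    rotation = R,
    center = c(x = center[3] - 0.5, y = center[2] - 0.5,
               z = center[1] - 0.5) * s,
    residual_angle = residual,
    iterations = iter,
    converged = residual <= sqrt(2) * tol_deg,
    flipped = flipped
  ), class = "alignment_result")
  list(volume = cur, result = res)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> residual %.3f deg after %d iteration(s)%s%s\n",
    x$residual_angle, x$iterations,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$flipped) ", Z flipped" else ""))
  invisible(x)
}

#' Principal axis of the foreground (independent oracle)
#'
#' Dominant eigenvector of the second-central-moment tensor of the
#' foreground voxel centers, in world coordinates; the reference
#' implementation the projection/ellipse alignment is validated against.
#'
#' @param vol A [new_label_volume()] object.
#' @param cytoplasm_label Optional label excluded from the foreground.
#' @return Unit vector `(x, y, z)` with non-negative Z component; attribute
#'   `degenerate` is `TRUE` when the two largest eigenvalues coincide (the
#'   direction is then arbitrary).
#' @export
principal_axis <- function(vol, cytoplasm_label = NULL) {
  fg <- vol$voxels != 0L
  if (!is.null(cytoplasm_label)) fg <- fg & vol$voxels != cytoplasm_label
  idx <- which(fg, arr.ind = TRUE)
  if (nrow(idx) < 2L) abort_degenerate("need at least 2 foreground voxels")
  xyz <- cbind(idx[, 3] * vol$spacing[3], idx[, 2] * vol$spacing[2],
               idx[, 1] * vol$spacing[1])
  cen <- scale(xyz, scale = FALSE)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[3] < 0) v <- -v
  degen <- (ev$values[1] - ev$values[2]) <= 1e-9 * max(ev$values[1], 1e-300)
  structure(v / sqrt(sum(v^2)), degenerate = degen)
}
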