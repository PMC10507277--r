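# Mother/daughter two-fold symmetry: midpoints of homologous centroid
# pairs, symmetry-axis fit, collinearity, and 180-degree rotation overlap.

scale_index <- function(names) {
  idx <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", names)))
  if (anyNA(idx)) abort_usage("scale names must end in an integer index")
  idx
}

pair_tables <- function(mother, daughter, max_pair_index = Inf) {
  mi <- scale_index(mother$name)
  di <- scale_index(daughter$name)
  shared <- intersect(mi, di)
  shared <- shared[shared <= max_pair_index]
  if (length(shared) < 2L)
    abort_usage("need >= 2 homologous scale pairs (shared name indices)")
  shared <- sort(shared)
  list(m = as_xyz(mother[match(shared, mi), , drop = FALSE]),
       d = as_xyz(daughter[match(shared, di), , drop = FALSE]),
       index = shared)
}

#' Midpoints of homologous mother/daughter centroid pairs
#'
#' Scales correspond by the integer suffix of their names (`M7` pairs with
#' `D7`); no geometric matching is attempted.
#'
#' @param mother,daughter Data frames with a `name` column and centroid
#'   columns (`x`/`y`/`z` or `centroid_*_um`).
#' @param max_pair_index Only use pairs with index at or below this (the
#'   published analysis used pairs 1-14); default all shared pairs.
#' @return Matrix of midpoints `(x, y, z)`, one row per shared index,
#'   ordered by index (attribute `index`).
#' @export
homologous_midpoints <- function(mother, daughter, max_pair_index = Inf) {
  p <- pair_tables(mother, daughter, max_pair_index)
  mid <- (p$m + p$d) / 2
  colnames(mid) <- c("x", "y", "z")
  structure(mid, index = p$index)
}

#' Fit a straight line through 3D points
#'
#' Total-least-squares line: through the centroid of the points, along the
#' dominant eigenvector of their second-central-moment tensor, with the
#' direction sign fixed so the Z component is non-negative.
#'
#' @param points Matrix (n >= 2 rows) of `(x, y, z)`.
#' @return A list with `point` (on the line), `direction` (unit), and
#'   `rmsd` (root-mean-square perpendicular distance of the points).
#' @export
fit_axis <- function(points) {
  points <- as_xyz(points)
  if (nrow(points) < 2L) abort_usage("need at least 2 points to fit a line")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  if (all(abs(cen) < 1e-12))
    abort_degenerate("all points identical: line direction undefined")
  ev <- eigen(crossprod(cen), symmetric = TRUE)
  dir <- ev$vectors[, 1]
  if (dir[3] < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  ax <- cen %*% dir
  perp2 <- rowSums(cen^2) - ax^2
  list(point = ctr, direction = as.vector(dir),
       rmsd = sqrt(max(mean(perp2), 0)))
}

#' Overlap RMSD after rotating the daughter 180 degrees about an axis
#'
#' Rotates every daughter centroid by pi about the affine line `axis`
#' (Rodrigues rotation) and returns the root-mean-square distance between
#' rotated daughter centroids and their homologous mother centroids.
#'
#' @inheritParams homologous_midpoints
#' @param axis List with `point` and `direction` (from [fit_axis()]).
#' @return Overlap RMSD in micrometres.
#' @export
rotation_overlap <- function(mother, daughter, axis,
                             max_pair_index = Inf) {
  nd <- sqrt(sum(axis$direction^2))
  if (!is.finite(nd) || nd == 0) abort_degenerate("axis direction undefined")
  p <- pair_tables(mother, daughter, max_pair_index)
  rot <- rotate_pi_about(p$d, axis$point, axis$direction)
  sqrt(mean(rowSums((rot - p$m)^2)))
}

#' Two-fold symmetry analysis of a mother/daughter pair
#'
#' Implements the midpoint procedure: homologous centroid midpoints are
#' fitted by a straight line (the candidate symmetry axis), the residual of
#' that fit is the collinearity RMSD, and rotating the daughter 180 degrees
#' about the fitted axis onto the mother gives the overlap RMSD.
#'
#' @inheritParams homologous_midpoints
#' @return A list of class `symmetry_result`: `axis` (point, unit
#'   direction), `collinearity_rmsd` (um), `overlap_rmsd` (um), `n_pairs`.
#' @export
symmetry_analysis <- function(mother, daughter, max_pair_index = Inf) {
  mid <- homologous_midpoints(mother, daughter, max_pair_index)
  ax <- fit_axis(mid)
  structure(list(
    axis = ax[c("point", "direction")],
    collinearity_rmsd = ax$rmsd,
    overlap_rmsd = rotation_overlap(mother, daughter, ax, max_pair_index),
    n_pairs = nrow(mid)
  ), class = "symmetry_result")
}

#' @export
print.symmetry_result <- function(x, ...) {
  cat(sprintf(
    "<symmetry_result> %d pairs; midpoint collinearity RMSD %.4f um; 180-deg overlap RMSD %.4f um\n",
    x$n_pairs, x$collinearity_rmsd, x$overlap_rmsd))
  cat(sprintf("  axis through (%.2f, %.2f, %.2f) along (%.3f, %.3f, %.3f)\n",
              x$axis$point[1], x$axis$point[2], x$axis$point[3],
              x$axis$direction[1], x$axis$direction[2], x$axis$direction[3]))
  invisible(x)
}
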