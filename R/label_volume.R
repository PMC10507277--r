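#' Labeled 3D volume
#'
#' Container for a segmented image stack: a 3D array of non-negative integer
#' labels in `(z, y, x)` index order plus the physical voxel spacing.
#' Label 0 is background.  The world coordinate of the *center* of voxel
#' `(k, j, i)` (1-based array indices) is
#' `((i - 0.5) * sx, (j - 0.5) * sy, (k - 0.5) * sz)` micrometres; this
#' convention is used by every function in the package.
#'
#' @param voxels 3D array (or a matrix, taken as a single Z slice) of
#'   non-negative integers, index order `(z, y, x)`.
#' @param spacing Numeric length-3 vector `(sz, sy, sx)`, micrometres per
#'   voxel along each axis; all strictly positive.  A single number is
#'   recycled to isotropic spacing.
#' @param label_names Optional named character vector or list mapping label
#'   ids (names, e.g. `"1"`) to scale names (e.g. `"M1"`, `"cytoplasm"`).
#' @return An object of class `label_volume`: a list with elements `voxels`,
#'   `spacing` and `label_names`.
#' @examples
#' v <- new_label_volume(array(0L, c(4, 4, 4)), spacing = 0.02)
#' dim(v$voxels)
#' @export
new_label_volume <- function(voxels, spacing, label_names = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort_format("voxels must be a 3D array in (z, y, x) order")
  if (anyNA(voxels) || any(voxels < 0) || any(voxels != round(voxels)))
    abort_format("voxels must be non-negative integers")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    abort_usage("spacing must be three strictly positive values (sz, sy, sx)")
  storage.mode(voxels) <- "integer"
  if (!is.null(label_names)) {
    label_names <- unlist(label_names)
    if (is.null(names(label_names)))
      abort_usage("label_names must be named by label id")
  }
  structure(list(voxels = voxels, spacing = spacing,
                 label_names = label_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- present_labels(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x), spacing %s um\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  %d label(s): %s\n", length(labs),
              paste(utils::head(labs, 12), collapse = ", ")))
  invisible(x)
}

#' Labels present in a volume
#'
#' @param vol A [new_label_volume()] object.
#' @param include_background Keep label 0 in the result?
#' @return Sorted integer vector of label ids present in `vol`.
#' @export
present_labels <- function(vol, include_background = FALSE) {
  labs <- sort(unique(as.vector(vol$voxels)))
  if (!include_background) labs <- labs[labs != 0L]
  labs
}

is_isotropic <- function(vol, tol = 1e-9) {
  s <- vol$spacing
  diff(range(s)) <= tol * max(s)
}

require_isotropic <- function(vol, what) {
  if (!is_isotropic(vol))
    abort_usage(paste0(what, " requires isotropic spacing; ",
                       "use resample_isotropic() first"))
  invisible(vol$spacing[1])
}

label_name_of <- function(vol, label) {
  nm <- vol$label_names[[as.character(label)]]
  if (is.null(nm)) as.character(label) else nm
}

#' Read a label volume from a multi-page TIFF stack
#'
#' Pages are taken as Z slices (page 1 = smallest Z).  Pixel values must be
#' stored as integers (8- or 16-bit grayscale); voxel spacing is supplied by
#' the caller, not read from TIFF tags.
#'
#' @param path Path to a TIFF file.
#' @param spacing Voxel spacing `(sz, sy, sx)` in micrometres (or one
#'   number for isotropic voxels).
#' @param label_names Optional label-name map, see [new_label_volume()].
#' @return A [new_label_volume()] object.
#' @export
read_label_volume <- function(path, spacing, label_names = NULL) {
  if (!file.exists(path)) abort_usage("file not found: %s", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) abort_format(
                      "cannot read TIFF '%s': %s", path, conditionMessage(e)))
  fmt <- attr(pages[[1]], "sample.format")
  if (!is.null(fmt) && !fmt %in% c("uint", "int"))
    abort_format("'%s' does not contain integer pixel data", path)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    abort_format("'%s' is not single-channel grayscale", path)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    abort_format("'%s' has inconsistent page shapes", path)
  vox <- array(0L, c(length(pages), shp[1, 1], shp[2, 1]))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (any(pg != round(pg)))
      abort_format("'%s' does not contain integer pixel data", path)
    vox[k, , ] <- as.integer(pg)
  }
  new_label_volume(vox, spacing, label_names)
}

#' Write a label volume as a multi-page TIFF stack
#'
#' Writes one grayscale page per Z slice, 16-bit by default, so that
#' `read_label_volume(write_label_volume(x))` restores `x$voxels` exactly.
#' Output bytes are deterministic for identical input.
#'
#' @param vol A [new_label_volume()] object.
#' @param path Output file path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, bits = 16L) {
  if (!inherits(vol, "label_volume")) abort_usage("vol must be a label_volume")
  if (!bits %in% c(8L, 16L)) abort_usage("bits must be 8 or 16")
  maxval <- 2^bits - 1
  if (max(vol$voxels) > maxval)
    abort_usage("labels up to %d do not fit %d-bit output", max(vol$voxels), bits)
  pages <- lapply(seq_len(dim(vol$voxels)[1]),
                  function(k) vol$voxels[k, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Resample a label volume to isotropic voxels
#'
#' Each label is resampled independently as a binary mask by trilinear
#' interpolation of its indicator function onto the target grid, then
#' thresholded at 0.5.  Where several labels claim the same output voxel the
#' one with the highest interpolated value wins; exact ties go to the
#' smaller label id.  A label whose mask vanishes at the target spacing
#' produces a warning naming the label, not an error.
#'
#' @param vol A [new_label_volume()] object.
#' @param target Target isotropic spacing in micrometres (> 0).
#' @return A [new_label_volume()] with spacing `(target, target, target)`.
#' @export
resample_isotropic <- function(vol, target) {
  if (!inherits(vol, "label_volume")) abort_usage("vol must be a label_volume")
  if (length(target) != 1L || !is.finite(target) || target <= 0)
    abort_usage("target spacing must be a single positive number")
  s <- vol$spacing
  if (all(abs(s - target) <= 1e-12 * target)) return(vol)

  din <- dim(vol$voxels)
  dout <- pmax(1L, as.integer(round(din * s / target)))
  out <- array(0L, dout)
  best <- array(0, dout)
  labs <- present_labels(vol)

  for (lab in labs) {
    hit <- which(vol$voxels == lab, arr.ind = TRUE)
    # input-index bbox, padded by one voxel of zeros for boundary support
    lo <- pmax(apply(hit, 2, min) - 1L, 0L)    # 0-based, inclusive of pad
    hi <- pmin(apply(hit, 2, max) + 1L, din)   # 1-based upper
    m <- array(0, hi - lo + 2L)                # extra zero border all round
    m[cbind(hit[, 1] - lo[1] + 1L, hit[, 2] - lo[2] + 1L,
            hit[, 3] - lo[3] + 1L)] <- 1
    # world extent of the label (+pad) maps to an output index range
    w_lo <- (lo - 1) * s          # world coord of lower pad voxel center - s
    o_lo <- pmax(1L, as.integer(floor(((lo - 1) * s) / target + 0.5)))
    o_hi <- pmin(dout, as.integer(ceiling((hi + 1) * s / target + 0.5)))
    if (any(o_lo > o_hi)) next
    ax <- function(a) {
      oi <- o_lo[a]:o_hi[a]
      wc <- (oi - 0.5) * target                 # output voxel center, world
      fi <- wc / s[a] + 0.5 - lo[a] + 1         # fractional index into m
      # clamp into the padded support: the border of m is zero, so points
      # outside the label's neighborhood interpolate to 0
      fi <- pmin(pmax(fi, 1), dim(m)[a])
      i0 <- pmin(floor(fi), dim(m)[a] - 1L)
      fr <- fi - i0
      list(oi = oi, i0 = as.integer(i0), fr = fr)
    }
    gz <- ax(1); gy <- ax(2); gx <- ax(3)
    val <- array(0, c(length(gz$oi), length(gy$oi), length(gx$oi)))
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wz <- if (cz) gz$fr else 1 - gz$fr
      wy <- if (cy) gy$fr else 1 - gy$fr
      wx <- if (cx) gx$fr else 1 - gx$fr
      val <- val + m[gz$i0 + cz, gy$i0 + cy, gx$i0 + cx, drop = FALSE] *
        (wz %o% wy %o% wx)
    }
    sub <- val >= 0.5 & val > best[gz$oi, gy$oi, gx$oi, drop = FALSE]
    if (!any(sub)) {
      warning(sprintf("label %s vanished at target spacing %g um",
                      label_name_of(vol, lab), target), call. = FALSE)
      next
    }
    idx <- which(sub, arr.ind = TRUE)
    gidx <- cbind(gz$oi[idx[, 1]], gy$oi[idx[, 2]], gx$oi[idx[, 3]])
    out[gidx] <- lab
    best[gidx] <- val[idx]
  }
  new_label_volume(out, target, vol$label_names)
}

# Exposed boundary faces of one label: matrix with one row per face,
# columns k, j, i (1-based voxel index) and d (direction 1..6:
# -z, +z, -y, +y, -x, +x).
label_faces <- function(vol, label) {
  mask <- vol$voxels == label
  faces <- vector("list", 6L)
  for (dnum in 1:6) {
    nb <- neighbor3(mask, dnum, outside = FALSE)
    f <- mask & !nb
    if (any(f)) {
      w <- which(f, arr.ind = TRUE)
      faces[[dnum]] <- cbind(w, d = dnum)
    }
  }
  do.call(rbind, faces)
}

#' Export one scale as a binary STL surface mesh
#'
#' The mesh is the exact exposed voxel boundary of the label: every voxel
#' face whose 6-neighbor belongs to a different label, to background, or
#' lies outside the volume becomes two triangles with outward normals.
#' Coordinates are in micrometres (world frame, voxel-corner positions).
#' No smoothing is applied, so the triangle count equals twice the exposed
#' face count.
#'
#' @param vol A [new_label_volume()] object.
#' @param label Label id to export (must be present).
#' @param path Output STL path.
#' @return `path`, invisibly (attribute `n_triangles` gives the count).
#' @export
export_scale_mesh <- function(vol, label, path) {
  if (!label %in% present_labels(vol))
    abort_usage("label %s not present in volume", label)
  faces <- label_faces(vol, label)
  s <- vol$spacing  # (sz, sy, sx)
  # voxel (k, j, i) spans world x in [(i-1)sx, i*sx], etc.
  # Corner offsets per direction, ordered counter-clockwise seen from
  # outside (right-hand rule gives the outward normal).
  quads <- list(
    `1` = list(n = c(0, 0, -1),
               v = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))),
    `2` = list(n = c(0, 0, 1),
               v = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))),
    `3` = list(n = c(0, -1, 0),
               v = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))),
    `4` = list(n = c(0, 1, 0),
               v = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0))),
    `5` = list(n = c(-1, 0, 0),
               v = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0))),
    `6` = list(n = c(1, 0, 0),
               v = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1))))
  ntri <- 2L * nrow(faces)
  # 12 floats + 2 attribute bytes per triangle
  buf <- matrix(0, nrow = 12, ncol = ntri)
  col <- 0L
  for (dnum in 1:6) {
    sel <- faces[, 4] == dnum
    if (!any(sel)) next
    fk <- faces[sel, 1, drop = TRUE]; fj <- faces[sel, 2, drop = TRUE]
    fi <- faces[sel, 3, drop = TRUE]
    q <- quads[[dnum]]
    # world corner coordinates (x, y, z) for each of the 4 quad corners
    cx <- function(c) (fi - 1 + q$v[c, 1]) * s[3]
    cy <- function(c) (fj - 1 + q$v[c, 2]) * s[2]
    cz <- function(c) (fk - 1 + q$v[c, 3]) * s[1]
    nrm <- q$n  # (x, y, z)
    for (tri in list(c(1, 2, 3), c(1, 3, 4))) {
      m <- rbind(nrm[1], nrm[2], nrm[3],
                 cx(tri[1]), cy(tri[1]), cz(tri[1]),
                 cx(tri[2]), cy(tri[2]), cz(tri[2]),
                 cx(tri[3]), cy(tri[3]), cz(tri[3]))
      buf[, col + seq_len(sum(sel))] <- m
      col <- col + sum(sel)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "shellmorph voxel-face surface (um)"))
  writeBin(header[1:80], con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  # interleave 48 float bytes + 2 attribute bytes per triangle
  fb <- writeBin(as.numeric(buf), raw(), size = 4, endian = "little")
  fb <- matrix(fb, nrow = 48L)
  rec <- rbind(fb, matrix(as.raw(0), nrow = 2L, ncol = ntri))
  writeBin(as.vector(rec), con)
  invisible(structure(path, n_triangles = ntri))
}
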