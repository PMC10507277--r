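#' Volume of one label
#'
#' Voxel count times the voxel volume, on an isotropic volume.
#'
#' @param vol A [new_label_volume()] object with isotropic spacing.
#' @param label Label id (must be present).
#' @return Volume in cubic micrometres.
#' @export
label_volume <- function(vol, label) {
  s <- require_isotropic(vol, "label_volume()")
  n <- sum(vol$voxels == label)
  if (n == 0L) abort_usage("label %s not present in volume", label)
  n * s^3
}

#' Centroid of one label
#'
#' Unweighted mean of the member voxel centers in world coordinates,
#' using the voxel-center convention of [new_label_volume()].
#'
#' @inheritParams label_volume
#' @return Named numeric vector `(x, y, z)` in micrometres.
#' @export
label_centroid <- function(vol, label) {
  s <- require_isotropic(vol, "label_centroid()")
  idx <- which(vol$voxels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort_usage("label %s not present in volume", label)
  c(x = mean(idx[, 3] - 0.5) * s,
    y = mean(idx[, 2] - 0.5) * s,
    z = mean(idx[, 1] - 0.5) * s)
}

#' Surface area of one label by exact face counting
#'
#' Counts voxel faces whose 6-neighbor is a different label, background, or
#' outside the volume, and multiplies by the face area.  Face counting
#' systematically overestimates the area of smooth surfaces (by up to a
#' factor 1.5 for oblique planes) but is exact, deterministic, and cancels
#' in contact/surface ratios, which is how it is used here.
#'
#' @inheritParams label_volume
#' @return Surface area in square micrometres.
#' @export
label_surface_area <- function(vol, label) {
  s <- require_isotropic(vol, "label_surface_area()")
  mask <- vol$voxels == label
  if (!any(mask)) abort_usage("label %s not present in volume", label)
  nfaces <- 0L
  for (dnum in 1:6)
    nfaces <- nfaces + sum(mask & neighbor3(vol$voxels, dnum) != label)
  nfaces * s^2
}

#' Contact area between two labels
#'
#' Total area of voxel faces where a voxel of label `a` is 6-adjacent to a
#' voxel of label `b`.  Symmetric in `(a, b)`; diagonal (edge or corner)
#' adjacency does not count.
#'
#' @param vol A [new_label_volume()] object with isotropic spacing.
#' @param a,b Two distinct label ids.
#' @return Contact area in square micrometres.
#' @export
contact_area <- function(vol, a, b) {
  s <- require_isotropic(vol, "contact_area()")
  if (a == b) abort_usage("contact_area() needs two distinct labels")
  mask <- vol$voxels == a
  nfaces <- 0L
  for (dnum in 1:6)
    nfaces <- nfaces + sum(mask & neighbor3(vol$voxels, dnum) == b)
  nfaces * s^2
}

#' Classify the cytoplasm-contact state of a scale
#'
#' The contact/surface ratio is clamped to 1 before thresholding: measured
#' contact can exceed the measured surface marginally when the two come
#' from independent segmentations.
#'
#' @param surface Surface area(s), square micrometres (> 0).
#' @param contact Contact area(s), square micrometres (>= 0).
#' @param full_threshold Ratio at or above which a scale counts as fully
#'   covered (default 0.99).
#' @return Character vector: `"none"` (zero contact), `"full"`
#'   (ratio >= `full_threshold`) or `"partial"`.
#' @examples
#' classify_contact(27.477, 27.479)  # "full": ratio clamps to 1
#' classify_contact(10.470, 0)       # "none"
#' classify_contact(27.621, 9.542)   # "partial"
#' @export
classify_contact <- function(surface, contact, full_threshold = 0.99) {
  if (any(surface <= 0)) abort_usage("surface area must be positive")
  if (any(contact < 0)) abort_usage("contact area must be non-negative")
  ratio <- pmin(contact / surface, 1)
  ifelse(contact == 0, "none",
         ifelse(ratio >= full_threshold, "full", "partial"))
}

#' Per-scale morphometrics of a label volume
#'
#' Computes, in one pass over the volume, the volume, centroid, surface
#' area, cytoplasm contact area and contact class of every non-background,
#' non-cytoplasm label.
#'
#' @param vol A [new_label_volume()] object with isotropic spacing.
#' @param cytoplasm_label Label id of the cytoplasm, or `NULL` if the
#'   volume has none (contact areas are then 0 and all classes `"none"`).
#' @param full_threshold Passed to [classify_contact()].
#' @return A `data.frame` with columns `label`, `name`, `volume_um3`,
#'   `centroid_x_um`, `centroid_y_um`, `centroid_z_um`, `surface_area_um2`,
#'   `contact_area_um2`, `contact_class`, one row per scale, ordered by
#'   label id.
#' @export
measure_scales <- function(vol, cytoplasm_label = NULL,
                           full_threshold = 0.99) {
  s <- require_isotropic(vol, "measure_scales()")
  vox <- vol$voxels
  fg <- vox != 0L
  if (!is.null(cytoplasm_label)) fg <- fg & vox != cytoplasm_label
  if (!any(fg)) abort_usage("volume contains no scale labels")
  idx <- which(fg)
  lab <- vox[idx]
  labs <- sort(unique(lab))
  nmax <- max(labs)
  counts <- tabulate(lab, nmax)
  d <- dim(vox)
  # decompose linear index into (k, j, i)
  i0 <- idx - 1L
  k <- i0 %% d[1]
  j <- (i0 %/% d[1]) %% d[2]
  i <- i0 %/% (d[1] * d[2])
  sx <- rowsum(i + 0.5, lab); sy <- rowsum(j + 0.5, lab)
  sz <- rowsum(k + 0.5, lab)
  surf <- numeric(nmax); cont <- numeric(nmax)
  for (dnum in 1:6) {
    nb <- neighbor3(vox, dnum)
    diffmask <- fg & nb != vox
    surf <- surf + tabulate(vox[diffmask], nmax)
    if (!is.null(cytoplasm_label)) {
      cmask <- fg & nb == cytoplasm_label
      cont <- cont + tabulate(vox[cmask], nmax)
    }
  }
  nm <- vapply(labs, function(l) label_name_of(vol, l), character(1))
  data.frame(
    label = labs,
    name = nm,
    volume_um3 = counts[labs] * s^3,
    centroid_x_um = as.vector(sx) / counts[labs] * s,
    centroid_y_um = as.vector(sy) / counts[labs] * s,
    centroid_z_um = as.vector(sz) / counts[labs] * s,
    surface_area_um2 = surf[labs] * s^2,
    contact_area_um2 = cont[labs] * s^2,
    contact_class = classify_contact(surf[labs] * s^2, cont[labs] * s^2,
                                     full_threshold),
    stringsAsFactors = FALSE
  )
}

#' Summarise cytoplasm contact over a set of scales
#'
#' @param records A `data.frame` with at least `surface_area_um2`,
#'   `contact_area_um2` and either `contact_class` or enough to classify
#'   (classes are recomputed if absent), plus `name` or `label`.
#' @param full_threshold Passed to [classify_contact()] when classes are
#'   recomputed.
#' @return A list of class `contact_summary`: `n_scales`, `n_in_contact`,
#'   `n_partial`, `n_full`, `max_partial_contact` (square micrometres; 0 if
#'   no partial scale) and `max_partial_label`.
#' @export
contact_summary <- function(records, full_threshold = 0.99) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    abort_usage("records must be a non-empty data.frame")
  cls <- if ("contact_class" %in% names(records)) records$contact_class
         else classify_contact(records$surface_area_um2,
                               records$contact_area_um2, full_threshold)
  nm <- if ("name" %in% names(records)) records$name
        else as.character(records$label)
  part <- cls == "partial"
  max_c <- if (any(part)) max(records$contact_area_um2[part]) else 0
  max_l <- if (any(part))
    nm[part][which.max(records$contact_area_um2[part])] else NA_character_
  structure(list(
    n_scales = nrow(records),
    n_in_contact = sum(cls != "none"),
    n_partial = sum(part),
    n_full = sum(cls == "full"),
    max_partial_contact = max_c,
    max_partial_label = max_l
  ), class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf(
    "%d scales: %d in contact with the cytoplasm (%d partial, %d full)\n",
    x$n_scales, x$n_in_contact, x$n_partial, x$n_full))
  if (!is.na(x$max_partial_label))
    cat(sprintf("largest partial contact: %s, %.3f um^2\n",
                x$max_partial_label, x$max_partial_contact))
  invisible(x)
}

#' Packaged surface/contact-area table of 25 daughter-shell scales
#'
#' The measured surface area and cytoplasm contact area (square
#' micrometres) of the 25 daughter-shell scales (D1-D25) of a
#' *Paulinella micropora* cell captured mid shell-construction, shipped
#' with the package as a plain-text fixture.
#'
#' @return A `data.frame` with columns `name`, `surface_area_um2`,
#'   `contact_area_um2`.
#' @examples
#' contact_summary(table1_scales())
#' @export
table1_scales <- function() {
  path <- system.file("extdata", "table1_daughter_scales.csv",
                      package = "shellmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a morphometry table as CSV
#'
#' Numeric columns are rounded to 3 decimals (the precision of the
#' published per-scale tables); output is byte-deterministic.
#'
#' @param records Data frame from [measure_scales()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(records, path) {
  num <- vapply(records, is.numeric, logical(1)) & names(records) != "label"
  records[num] <- lapply(records[num], round, digits = 3)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
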