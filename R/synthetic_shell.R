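# Synthetic egg-shell phantoms with full ground truth.
#
# The phantom stands in for raw FIB-SEM stacks, which are not publicly
# deposited: an ovoid shell of curved rectangular scales arranged in C
# helical columns of ~K scales each, with optional extra aperture scales,
# a cytoplasm body contacting a chosen subset of scales, and exactly
# line-symmetric mother/daughter pairs.

# fraction of the half-length actually occupied by scale rows; the ovoid
# tapers to r = 0 at |u| = 1, so rows stop short of the poles
BAND_U_MAX <- 0.92

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

circ_dist <- function(a, b) abs(wrap_angle(a - b))

#' Parametric specification of a synthetic egg-shell phantom
#'
#' Describes an ovoid shell of `columns * per_column + extra_aperture_scales`
#' curved rectangular scales arranged in helical columns, to be voxelized by
#' [generate_shell()].  All lengths in micrometres.  The aperture end of the
#' shell is at high Z.
#'
#' @param columns Number of helical columns C (>= 1); seen end-on these are
#'   the "rows" of scales and the petals of the centroid plot.
#' @param per_column Scales per column K (>= 2).
#' @param extra_aperture_scales Extra scales in a final short band at the
#'   aperture end (>= 0), continuing the helix.
#' @param half_length Half the pole-to-pole length L of the ovoid.
#' @param equator_radius Mid-surface radius R at the equator.
#' @param asymmetry Egg taper `a` in \[0, 0.6\]; the wide end lies at
#'   positive Z (the aperture end here).
#' @param shell_thickness Radial thickness t of each scale.
#' @param angular_gap Gap fraction g in \[0, 0.5) of the column pitch left
#'   open between neighboring scales (applied in angle, and as the same
#'   fraction of the row height in Z).
#' @param twist Net twist of each column in revolutions over the span of
#'   row centers; negative = left-handed under the package convention
#'   (angles counter-clockwise viewed from +Z).  `abs(twist) <= 2`.
#' @param spacing Isotropic voxel size.
#' @param grid_shape Integer `(nz, ny, nx)` of the output volume.
#' @param seed Integer seed; the only source of randomness (jitter, row
#'   heights, cytoplasm blob).
#' @param jitter Standard deviation of the per-scale placement perturbation
#'   (applied in angle, radius and, where the inter-row gap allows, Z).
#'   Placement jitter moves a scale without resizing it: the angular span
#'   compensates radial displacement so the arc length is preserved.
#' @param size_jitter Relative half-range of the per-scale thickness
#'   (hence volume) variation, drawn as `size_jitter * sin(2 pi U)` — a
#'   symmetric distribution with bounded support, so that an uninflated
#'   phantom carries no volume outliers by construction.
#' @param row_height_jitter Relative half-range of deterministic per-row
#'   height variation (rows of identical height are both unrealistic and
#'   create a degenerate sampling comb along Z).
#' @param profile_center,profile_sd Center and standard deviation, as
#'   fractions of `half_length`, of the Gaussian volume-versus-Z profile
#'   the scale sizes are designed to follow (scales are smallest near the
#'   aperture and the posterior pole and largest near the equator; the
#'   angular width of each row is sized so the per-scale volume tracks the
#'   Gaussian).  `profile_sd = NA` disables the sizing and keeps a constant
#'   angular span.
#' @param cytoplasm_plan `NULL` for no cytoplasm, or a list with `classes`
#'   (character vector of `"none"`/`"partial"`/`"full"`, one per scale,
#'   recycled) and `partial_fraction` (target contact/surface ratio of
#'   partial scales).
#' @param inflate Named numeric vector of volume multipliers keyed by label
#'   id, e.g. `c("45" = 1.8)`, used to plant volume outliers.
#' @param cytoplasm_label Label id reserved for the cytoplasm.
#' @param name_prefix Prefix of generated scale names (`"M"` gives M1..Mn).
#' @return A list of class `shell_spec`.
#' @seealso [paulinella_shell_spec()] for the study-scale preset.
#' @export
shell_spec <- function(columns,
                       per_column,
                       extra_aperture_scales = 0L,
                       half_length,
                       equator_radius,
                       asymmetry = 0,
                       shell_thickness,
                       angular_gap = 0.2,
                       twist = 0,
                       spacing,
                       grid_shape,
                       seed = 0L,
                       jitter = 0,
                       size_jitter = 0.06,
                       row_height_jitter = 0.15,
                       profile_center = 0.15,
                       profile_sd = 0.7,
                       cytoplasm_plan = NULL,
                       inflate = NULL,
                       cytoplasm_label = NULL,
                       name_prefix = "M") {
  if (columns < 1 || per_column < 2 || extra_aperture_scales < 0)
    abort_usage("need columns >= 1, per_column >= 2, extra_aperture_scales >= 0")
  if (extra_aperture_scales > columns)
    abort_usage("extra_aperture_scales cannot exceed columns")
  if (asymmetry < 0 || asymmetry > 0.6)
    abort_usage("asymmetry must be in [0, 0.6]")
  if (angular_gap < 0 || angular_gap >= 0.5)
    abort_usage("angular_gap must be in [0, 0.5)")
  if (abs(twist) > 2) abort_usage("abs(twist) must be <= 2 revolutions")
  if (spacing <= 0 || half_length <= 0 || equator_radius <= 0 ||
      shell_thickness <= 0)
    abort_usage("lengths and spacing must be positive")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    abort_usage("grid_shape must be three integers (nz, ny, nx) >= 4")
  n <- as.integer(columns * per_column + extra_aperture_scales)
  if (is.null(cytoplasm_label)) cytoplasm_label <- n + 1L
  spec <- structure(list(
    columns = as.integer(columns), per_column = as.integer(per_column),
    extra_aperture_scales = as.integer(extra_aperture_scales),
    half_length = half_length, equator_radius = equator_radius,
    asymmetry = asymmetry, shell_thickness = shell_thickness,
    angular_gap = angular_gap, twist = twist, spacing = spacing,
    grid_shape = grid_shape, seed = as.integer(seed), jitter = jitter,
    size_jitter = size_jitter, row_height_jitter = row_height_jitter,
    profile_center = profile_center, profile_sd = profile_sd,
    cytoplasm_plan = cytoplasm_plan, inflate = inflate,
    cytoplasm_label = as.integer(cytoplasm_label),
    name_prefix = name_prefix, n_scales = n
  ), class = "shell_spec")
  # the ovoid (plus thickness, inflation and jitter headroom) must fit the
  # grid with at least a 2-voxel margin
  u <- seq(-1, 1, length.out = 513)
  rmax <- max(egg_radius(u * half_length, spec))
  infl <- if (length(inflate)) max(1, inflate) else 1
  r_ext <- rmax + shell_thickness * infl / 2 + 2 * jitter
  z_ext <- BAND_U_MAX * half_length + 2 * jitter
  if (r_ext > (min(grid_shape[2:3]) / 2 - 2) * spacing ||
      z_ext > (grid_shape[1] / 2 - 2) * spacing)
    abort_usage("ovoid does not fit inside the grid with a 2-voxel margin")
  spec
}

#' @export
print.shell_spec <- function(x, ...) {
  cat(sprintf(
    "<shell_spec> %d scales (%d columns x %d + %d aperture), twist %.2f rev\n",
    x$n_scales, x$columns, x$per_column, x$extra_aperture_scales, x$twist))
  cat(sprintf("  L = %g um, R = %g um, a = %.2f, t = %g um; grid %s @ %g um\n",
              x$half_length, x$equator_radius, x$asymmetry,
              x$shell_thickness, paste(x$grid_shape, collapse = "x"),
              x$spacing))
  invisible(x)
}

#' Study-scale phantom preset
#'
#' A 52-scale phantom echoing the analysed *P. micropora* mother shell:
#' 5 columns of 10 scales plus 2 extra aperture scales, one left-handed
#' revolution of twist, egg asymmetry 0.35, voxelized on a 192^3 grid at
#' 0.08 um so the ovoid spans ~85% of the grid.
#'
#' @param seed Integer seed for the jitter and cytoplasm randomness.
#' @param ... Overrides passed to [shell_spec()].
#' @return A `shell_spec`.
#' @export
paulinella_shell_spec <- function(seed = 0L, ...) {
  args <- list(
    columns = 5L, per_column = 10L, extra_aperture_scales = 2L,
    half_length = 6.5, equator_radius = 4.0, asymmetry = 0.35,
    shell_thickness = 0.35, angular_gap = 0.2, twist = -1,
    spacing = 0.08, grid_shape = c(192L, 192L, 192L),
    seed = seed, jitter = 0.15
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(shell_spec, args)
}

#' Ovoid radius profile
#'
#' Mid-surface radius of the egg at height `z` from the egg center:
#' \eqn{r = R \sqrt{\max(0, 1 - u^2)} (1 + a u)} with \eqn{u = z / L}.
#' Zero at the poles and clamped to zero outside them; with `a > 0` the
#' wide end lies at positive z.
#'
#' @param z Height(s) relative to the egg center, micrometres.
#' @param spec A [shell_spec()].
#' @return Radius (radii) in micrometres.
#' @export
egg_radius <- function(z, spec) {
  u <- z / spec$half_length
  spec$equator_radius * sqrt(pmax(0, 1 - u^2)) * (1 + spec$asymmetry * u)
}

# Resolve the continuum geometry of every scale: row bands, angular
# centers, jitter, labels and names.  Deterministic given spec$seed.
shell_geometry <- function(spec) {
  C <- spec$columns; K <- spec$per_column
  extra <- spec$extra_aperture_scales
  nb <- K + (extra > 0L)
  span <- 2 * BAND_U_MAX * spec$half_length
  z_lo <- -BAND_U_MAX * spec$half_length

  rng <- with_seed(spec$seed, {
    hdev <- stats::runif(nb, -spec$row_height_jitter, spec$row_height_jitter)
    n <- spec$n_scales
    list(hdev = hdev,
         jr = stats::rnorm(n, 0, spec$jitter),
         jth = stats::rnorm(n, 0, spec$jitter),
         jz = stats::rnorm(n, 0, spec$jitter),
         jt = spec$size_jitter * sin(2 * pi * stats::runif(n)))
  })
  h <- span * (1 + rng$hdev) / sum(1 + rng$hdev)   # row heights, sum = span
  edges <- z_lo + c(0, cumsum(h))
  zc <- (edges[-1] + edges[-(nb + 1)]) / 2          # row centers
  omega <- if (nb > 1) 2 * pi * spec$twist / (zc[nb] - zc[1]) else 0

  # at most the column pitch minus the gap, and never more than a half
  # circle (a single column must still have a defined angular position)
  cap <- min((pi / C) * (1 - spec$angular_gap), pi / 2)
  ang_clip <- 0.45 * (2 * pi * spec$angular_gap / C)   # keep angular gaps open

  # Realized (voxel-snapped) row heights: band boundaries are axis-aligned
  # planes, so leaving them off the voxel grid would make the rendered
  # height of a row jump by a whole voxel layer from scale to scale.  The
  # snap origin follows the grid so that voxel centers never fall exactly
  # on a boundary.
  s <- spec$spacing
  snap0 <- (spec$grid_shape[1] / 2 - floor(spec$grid_shape[1] / 2)) * s
  snap <- function(z) snap0 + round((z - snap0) / s) * s
  h_real <- pmax(s, round(h * (1 - spec$angular_gap) / s) * s)

  # Row angular widths sized so per-scale volume ~ arc * t * h_real tracks
  # a Gaussian along z (the reported volume-versus-Z profile).  The profile
  # is normalized with headroom so that arc-preserving compensation of the
  # radial jitter (clipped at 2 sd) can never exceed the angular-gap cap.
  r_row <- pmax(egg_radius(zc, spec), 1e-9)
  room <- pmax(r_row - 2 * spec$jitter, 0.5 * r_row) / r_row
  if (is.na(spec$profile_sd)) {
    halfspans <- cap * room
  } else {
    L <- spec$half_length
    g_of_z <- exp(-(zc - spec$profile_center * L)^2 /
                    (2 * (spec$profile_sd * L)^2))
    f <- g_of_z / (r_row * h_real)
    halfspans <- f * min(cap * room / f)
  }

  scales <- list()
  lab <- 0L
  # aperture-first stacking order: top band down to the posterior
  for (b in nb:1) {
    ncol_b <- if (extra > 0L && b == nb) extra else C
    halfspan <- halfspans[b]
    gz <- spec$angular_gap * h[b] / 2
    # z-jitter clipped so that even after voxel snapping the worst-case
    # inter-row boundary gap stays >= one voxel (no face adjacency)
    z_clip <- max(0, gz - 1.25 * spec$spacing)
    for (j in seq_len(ncol_b) - 1L) {
      lab <- lab + 1L
      r_mid <- egg_radius(zc[b], spec)
      jth <- if (r_mid > 0) max(-ang_clip, min(ang_clip,
               rng$jth[lab] / max(r_mid, 1e-6))) else 0
      jz <- max(-z_clip, min(z_clip, rng$jz[lab]))
      dr <- max(-2 * spec$jitter, min(2 * spec$jitter, rng$jr[lab]))
      mult <- 1
      if (!is.null(spec$inflate)) {
        m <- spec$inflate[as.character(lab)]
        if (!is.na(m)) mult <- m
      }
      # radial displacement must not resize the scale: shrink/grow the
      # angular span so the arc length is unchanged (capped at the gap)
      hs <- if (r_mid > 0) min(cap, halfspan * r_mid / max(r_mid + dr, 1e-6))
            else halfspan
      z0 <- snap(edges[b] + gz + jz)
      scales[[lab]] <- list(
        label = lab, row = b, column = j + 1L,
        theta = wrap_angle(2 * pi * j / C + omega * (zc[b] - zc[1]) + jth),
        halfspan = hs,
        z0 = z0, z1 = z0 + h_real[b],
        zc = z0 + h_real[b] / 2,
        dr = dr,
        thick = spec$shell_thickness * mult * (1 + rng$jt[lab]),
        inflated = mult != 1
      )
    }
  }
  list(scales = scales, edges = edges, zc = zc, omega = omega,
       n_bands = nb, z_lo = z_lo, span = span)
}

# Vectorized continuum membership test: which scale (0 = none) contains the
# shell-centered world point (x, y, z).
scale_membership <- function(spec, geom, x, y, z) {
  lab <- integer(length(x))
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  band <- findInterval(z, geom$edges)
  for (s in geom$scales) {
    sel <- which(band >= s$row - 1L & band <= s$row + 1L)
    if (!length(sel)) next
    zs <- z[sel]
    ok <- zs >= s$z0 & zs < s$z1
    sel <- sel[ok]
    if (!length(sel)) next
    regg <- egg_radius(z[sel], spec) + s$dr
    hit <- abs(r[sel] - regg) < s$thick / 2 &
      circ_dist(th[sel], s$theta) < s$halfspan
    lab[sel[hit]] <- s$label
  }
  lab
}

# check that one label forms a single 6-connected component
is_connected6 <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  reach <- array(FALSE, dim(m))
  first <- which(m)[1]
  reach[first] <- TRUE
  repeat {
    grown <- reach
    for (dnum in 1:6) grown <- grown | neighbor3(reach, dnum, FALSE)
    grown <- grown & m
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  sum(reach) == sum(m)
}

#' Voxelize a synthetic shell phantom
#'
#' Renders the continuum shell model of a [shell_spec()] onto its voxel
#' grid and returns the label volume together with the full ground truth.
#' Scale labels are assigned in helical stacking order starting from the
#' aperture (label 1 = first aperture scale); every scale is checked to be
#' a single 6-connected component of at least one voxel.
#'
#' @param spec A [shell_spec()].
#' @param check Verify per-scale connectivity (default `TRUE`).
#' @return A list with elements `volume` (a [new_label_volume()]) and
#'   `truth` (see Details).  `truth$scales` is a data.frame with one row
#'   per scale: label, name, column, row (1 = posterior band), the design
#'   (continuum) centroid in world micrometres, the inflation flag and the
#'   planned contact class; `truth` also records the twist (revolutions),
#'   handedness, angular rate, and for mother/daughter volumes the
#'   symmetry axis.
#' @export
generate_shell <- function(spec, check = TRUE) {
  geom <- shell_geometry(spec)
  d <- spec$grid_shape
  s <- spec$spacing
  ctr <- d[c(3, 2, 1)] / 2 * s   # world (x, y, z) of the grid center
  vox <- array(0L, d)
  x1 <- (seq_len(d[3]) - 0.5) * s - ctr[1]
  y1 <- (seq_len(d[2]) - 0.5) * s - ctr[2]
  xs <- rep(x1, each = d[1] * d[2])
  ys <- rep(rep(y1, each = d[1]), times = d[3])
  zs <- rep((seq_len(d[1]) - 0.5) * s - ctr[3], times = d[2] * d[3])
  vox[] <- scale_membership(spec, geom, xs, ys, zs)

  truth <- shell_truth(spec, geom, ctr)
  present <- present_labels(new_label_volume(vox, s))
  missing <- setdiff(truth$scales$label, present)
  if (length(missing))
    sm_stop("shellmorph_degenerate_error",
            "scale(s) %s vanished at spacing %g um",
            paste(truth$scales$name[truth$scales$label %in% missing],
                  collapse = ", "), s)
  if (check) {
    for (lab in truth$scales$label) {
      if (!is_connected6(vox == lab))
        sm_stop("shellmorph_degenerate_error",
                "scale %s is not 6-connected", truth$scales$name[lab])
    }
  }
  nm <- stats::setNames(truth$scales$name, truth$scales$label)
  list(volume = new_label_volume(vox, s, label_names = nm), truth = truth)
}

shell_truth <- function(spec, geom, ctr) {
  sc <- geom$scales
  df <- data.frame(
    label = vapply(sc, `[[`, integer(1), "label"),
    name = paste0(spec$name_prefix, vapply(sc, `[[`, integer(1), "label")),
    column = vapply(sc, `[[`, integer(1), "column"),
    row = vapply(sc, `[[`, integer(1), "row"),
    stringsAsFactors = FALSE
  )
  r_mid <- egg_radius(vapply(sc, `[[`, numeric(1), "zc"), spec) +
    vapply(sc, `[[`, numeric(1), "dr")
  th <- vapply(sc, `[[`, numeric(1), "theta")
  df$centroid_x_um <- r_mid * cos(th) + ctr[1]
  df$centroid_y_um <- r_mid * sin(th) + ctr[2]
  df$centroid_z_um <- vapply(sc, `[[`, numeric(1), "zc") + ctr[3]
  df$inflated <- vapply(sc, `[[`, logical(1), "inflated")
  cls <- rep("none", nrow(df))
  if (!is.null(spec$cytoplasm_plan))
    cls <- rep(spec$cytoplasm_plan$classes, length.out = nrow(df))
  df$contact_class <- cls
  hand <- if (abs(spec$twist) < 0.05) "none"
          else if (spec$twist < 0) "left" else "right"
  list(scales = df, twist = spec$twist, handedness = hand,
       omega = geom$omega, center = ctr, axis = NULL,
       spacing = spec$spacing)
}

#' Add a cytoplasm body with planned per-scale contact states
#'
#' Adds a cytoplasm label to the background of a generated phantom: a blob
#' of fused balls near the aperture end of the cavity (touching no scale),
#' plus, per the plan in `spec$cytoplasm_plan`, full or partial coverage of
#' the background voxels 6-adjacent to chosen scales.  Partial coverage
#' claims a contiguous angular sector of the adjacent voxels sized to the
#' target contact/surface fraction.  Scales planned `"none"` receive no
#' adjacent cytoplasm.  Realized contact classes are measured on the result
#' and written back into the truth.
#'
#' @param vol Label volume from [generate_shell()].
#' @param truth Matching ground truth.
#' @param spec The generating [shell_spec()]; its `cytoplasm_plan` drives
#'   the coverage (a `NULL` plan adds only the blob).
#' @return A list `(volume, truth)` with the cytoplasm label added and
#'   `truth$scales$contact_class` updated to the realized classes.
#' @export
add_cytoplasm <- function(vol, truth, spec) {
  cyt <- spec$cytoplasm_label
  if (cyt %in% present_labels(vol))
    abort_usage("cytoplasm label %d already in use", cyt)
  plan <- spec$cytoplasm_plan
  classes <- truth$scales$contact_class
  if (!is.null(plan)) {
    if (!all(plan$classes %in% c("none", "partial", "full")))
      abort_usage("cytoplasm plan classes must be none/partial/full")
    if (length(plan$classes) > nrow(truth$scales))
      abort_usage("cytoplasm plan refers to more scales than generated")
    classes <- rep(plan$classes, length.out = nrow(truth$scales))
    frac <- plan$partial_fraction %||% (1 / 3)
  } else frac <- 1 / 3

  vox <- vol$voxels
  d <- dim(vox)
  s <- vol$spacing[1]
  ctr <- truth$center
  bg <- vox == 0L

  # which scales every background voxel touches (0 = none, -1 = several)
  touch <- array(0L, d)
  multi <- array(FALSE, d)
  for (dnum in 1:6) {
    nb <- neighbor3(vox, dnum)
    sc <- bg & nb != 0L
    clash <- sc & touch != 0L & touch != nb
    multi <- multi | clash
    touch[sc] <- nb[sc]
  }

  cyto <- array(FALSE, d)

  # aperture blob: fused balls on the long axis, kept off the shell wall
  geom <- shell_geometry(spec)
  blob <- with_seed(spec$seed + 1L, {
    nball <- 3L
    zb <- stats::runif(nball, 0.35, 0.75) * BAND_U_MAX * spec$half_length
    rb <- stats::runif(nball, 0.2, 0.4)
    list(zb = zb, rb = rb)
  })
  x1 <- (seq_len(d[3]) - 0.5) * s - ctr[1]
  y1 <- (seq_len(d[2]) - 0.5) * s - ctr[2]
  z1 <- (seq_len(d[1]) - 0.5) * s - ctr[3]
  r2d <- sqrt(outer(y1^2, x1^2, `+`))          # (y, x)
  for (b in seq_along(blob$zb)) {
    rad <- blob$rb[b] * egg_radius(blob$zb[b], spec)
    ks <- which(abs(z1 - blob$zb[b]) < rad)
    for (k in ks) {
      rr <- sqrt(rad^2 - (z1[k] - blob$zb[b])^2)
      # stay clear of the wall: ball must not touch any scale
      lim <- egg_radius(z1[k], spec) - spec$shell_thickness - 2.5 * s
      sl <- r2d < min(rr, lim)
      if (any(sl)) {
        slice <- cyto[k, , ]
        slice[sl] <- TRUE
        cyto[k, , ] <- slice
      }
    }
  }
  cyto <- cyto & bg & touch == 0L & !multi

  surf_faces <- function(lab) {
    mask <- vox == lab
    nf <- 0L
    for (dnum in 1:6) nf <- nf + sum(mask & neighbor3(vox, dnum) != lab)
    nf
  }
  faces_to <- function(cand_idx, lab) {
    # number of faces each candidate (linear index) shares with label lab
    nf <- integer(length(cand_idx))
    for (dnum in 1:6) {
      nb <- neighbor3(vox, dnum)
      nf <- nf + (nb[cand_idx] == lab)
    }
    nf
  }
  lin_coords <- function(idx) {
    i0 <- idx - 1L
    k <- i0 %% d[1] + 1L
    j <- (i0 %/% d[1]) %% d[2] + 1L
    i <- i0 %/% (d[1] * d[2]) + 1L
    cbind(k, j, i)
  }

  for (srow in seq_len(nrow(truth$scales))) {
    cls <- classes[srow]
    if (cls == "none") next
    lab <- truth$scales$label[srow]
    adj <- which(bg & touch == lab & !(multi & cls == "partial"))
    if (cls == "full") {
      # everything adjacent, including voxels shared with other scales
      adj <- which(bg & (touch == lab | multi))
      adj <- adj[faces_to(adj, lab) > 0L]
      cyto[adj] <- TRUE
    } else {
      if (!length(adj)) next
      kji <- lin_coords(adj)
      thv <- atan2((kji[, 2] - 0.5) * s - ctr[2],
                   (kji[, 3] - 0.5) * s - ctr[1])
      off <- wrap_angle(thv - geom$scales[[lab]]$theta)
      o <- order(off)
      nf <- faces_to(adj[o], lab)
      target <- frac * surf_faces(lab)
      keep <- cumsum(nf) <= target
      if (any(keep)) cyto[adj[o][keep]] <- TRUE
    }
  }

  vox[cyto] <- cyt
  nm <- vol$label_names
  nm[as.character(cyt)] <- "cytoplasm"
  out <- new_label_volume(vox, vol$spacing, label_names = nm)

  rec <- measure_scales(out, cytoplasm_label = cyt)
  truth$scales$contact_class <-
    rec$contact_class[match(truth$scales$label, rec$label)]
  truth$cytoplasm_label <- cyt
  list(volume = out, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 180-degree rotation of points (rows of xyz matrix) about the affine line
# through `point` with unit direction `dir`
rotate_pi_about <- function(xyz, point, dir) {
  dir <- dir / sqrt(sum(dir^2))
  rel <- sweep(xyz, 2, point)
  ax <- rel %*% dir
  sweep(2 * (ax %*% t(dir)) - rel, 2, point, `+`)
}

#' Generate an exactly line-symmetric mother/daughter shell pair
#'
#' The daughter shell is the mother rotated 180 degrees about `axis`; the
#' rotation is applied to the continuum scale model before voxelization, so
#' the two-fold symmetry is exact in the continuum and the midpoints of
#' homologous design centroids lie exactly on the axis.  Homologous scales
#' share their index: mother scales are named `M1..Mn` and daughter scales
#' `D1..Dn` with labels `n + 1 .. 2n`.
#'
#' @param spec A [shell_spec()] describing the mother shell; its
#'   `grid_shape` must be tall enough along Z to hold both shells (the
#'   default chosen by `axis = NULL` doubles the single-shell grid).
#' @param axis `NULL` for the default placement (axis through a point just
#'   past the mother's aperture, direction `(1, 0, 0)`), or a list with
#'   `point` (x, y, z world micrometres) and `direction` (length-3).
#' @param grid_shape Optional override of the combined grid `(nz, ny, nx)`.
#' @return A list `(volume, truth)`; `truth$axis` holds the symmetry axis
#'   (`point`, unit `direction`), and `truth$scales` contains both shells'
#'   rows with a `shell` column (`"mother"`/`"daughter"`).
#' @export
generate_mother_daughter <- function(spec, axis = NULL, grid_shape = NULL) {
  geom <- shell_geometry(spec)
  d1 <- spec$grid_shape
  d <- if (!is.null(grid_shape)) as.integer(grid_shape)
       else c(2L * d1[1], d1[2], d1[3])
  s <- spec$spacing
  # mother centered in the lower half of the grid
  ctr <- c(d[3] / 2 * s, d[2] / 2 * s, d1[1] / 2 * s)
  if (is.null(axis)) {
    z_top <- BAND_U_MAX * spec$half_length + 2 * spec$jitter + 3 * s
    axis <- list(point = c(ctr[1], ctr[2], ctr[3] + z_top),
                 direction = c(1, 0, 0))
  }
  dir <- axis$direction / sqrt(sum(axis$direction^2))

  x1 <- (seq_len(d[3]) - 0.5) * s
  y1 <- (seq_len(d[2]) - 0.5) * s
  z1 <- (seq_len(d[1]) - 0.5) * s
  xs <- rep(x1, each = d[1] * d[2])
  ys <- rep(rep(y1, each = d[1]), times = d[3])
  zs <- rep(z1, times = d[2] * d[3])

  lab_m <- scale_membership(spec, geom, xs - ctr[1], ys - ctr[2], zs - ctr[3])
  # a daughter voxel at p corresponds to the mother point rot(p) (the
  # rotation is an involution)
  rot <- rotate_pi_about(cbind(xs, ys, zs), axis$point, dir)
  lab_d <- scale_membership(spec, geom,
                            rot[, 1] - ctr[1], rot[, 2] - ctr[2],
                            rot[, 3] - ctr[3])
  if (any(lab_m > 0L & lab_d > 0L))
    sm_stop("shellmorph_degenerate_error",
            "mother and daughter shells overlap after voxelization; move the axis")
  n <- spec$n_scales
  vox <- array(lab_m + ifelse(lab_d > 0L, lab_d + n, 0L), d)

  truth <- shell_truth(spec, geom, ctr)
  mdf <- truth$scales
  mdf$name <- paste0("M", mdf$label)
  mdf$shell <- "mother"
  ddf <- mdf
  ddf$label <- ddf$label + n
  ddf$name <- paste0("D", mdf$label)
  ddf$shell <- "daughter"
  rc <- rotate_pi_about(as.matrix(mdf[, c("centroid_x_um", "centroid_y_um",
                                          "centroid_z_um")]),
                        axis$point, dir)
  ddf$centroid_x_um <- rc[, 1]; ddf$centroid_y_um <- rc[, 2]
  ddf$centroid_z_um <- rc[, 3]
  truth$scales <- rbind(mdf, ddf)
  truth$axis <- list(point = axis$point, direction = dir)
  nm <- stats::setNames(truth$scales$name, truth$scales$label)

  present <- sort(unique(vox[vox != 0L]))
  missing <- setdiff(truth$scales$label, present)
  if (length(missing))
    sm_stop("shellmorph_degenerate_error", "scale(s) %s vanished at spacing %g um",
            paste(truth$scales$name[truth$scales$label %in% missing],
                  collapse = ", "), s)
  list(volume = new_label_volume(vox, s, label_names = nm), truth = truth)
}
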