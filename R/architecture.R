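# Shell-architecture quantification from aligned scale centroids:
# cylindrical coordinates, angular order parameters, helical column
# assignment with twist/handedness, and volume-profile outliers.
#
# Angle convention used throughout: theta is measured counter-clockwise
# viewed from +Z (the aperture side).  "Left-handed" means theta decreases
# from the posterior (low Z) toward the aperture, i.e. negative twist.

#' Cylindrical coordinates of centroids about the Z axis
#'
#' The axis is taken parallel to Z through the mean `(x, y)` of the
#' centroids (the volume is assumed aligned, see [align_long_axis()]).
#'
#' @param centroids Matrix or data.frame with columns x, y, z (micrometres);
#'   data frames from [measure_scales()] (`centroid_*_um` columns) are
#'   accepted directly.
#' @return A data.frame with columns `r` (um), `theta` (radians in
#'   `(-pi, pi]`), `z` (um).  A point exactly on the axis gets `theta = 0`.
#' @export
to_cylindrical <- function(centroids) {
  xyz <- as_xyz(centroids)
  if (nrow(xyz) < 1L) abort_usage("need at least one centroid")
  dx <- xyz[, 1] - mean(xyz[, 1])
  dy <- xyz[, 2] - mean(xyz[, 2])
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r == 0, 0, atan2(dy, dx))
  data.frame(r = r, theta = theta, z = xyz[, 3])
}

as_xyz <- function(p) {
  if (is.data.frame(p)) {
    cn <- names(p)
    if (all(c("centroid_x_um", "centroid_y_um", "centroid_z_um") %in% cn))
      return(as.matrix(p[, c("centroid_x_um", "centroid_y_um",
                             "centroid_z_um")]))
    if (all(c("x", "y", "z") %in% cn)) return(as.matrix(p[, c("x", "y", "z")]))
    abort_usage("centroids must have x/y/z or centroid_*_um columns")
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) abort_usage("centroids must have three columns (x, y, z)")
  p
}

#' Radius-weighted angular spectrum
#'
#' Circular order parameters
#' `S(m) = |sum_k r_k exp(i m theta_k)| / sum_k r_k` for harmonics
#' `m = 1..max_m`.  For points on a perfect C-column grid (no twist) every
#' `S(m)` with `m` not a multiple of C vanishes identically.
#'
#' @param cyl Data frame from [to_cylindrical()] (columns `r`, `theta`).
#' @param max_m Highest harmonic (default 12).
#' @return Named numeric vector `S1..S<max_m>`.
#' @export
angular_spectrum <- function(cyl, max_m = 12L) {
  if (nrow(cyl) < 3L) abort_usage("need at least 3 points for a spectrum")
  if (all(cyl$r == 0)) abort_degenerate("all points on the axis: no angles")
  S <- vapply(seq_len(max_m), function(m)
    Mod(sum(cyl$r * exp(1i * m * cyl$theta))) / sum(cyl$r), numeric(1))
  stats::setNames(S, paste0("S", seq_len(max_m)))
}

# amplitude of the rate-compensated order parameter at harmonic m and
# angular rate beta (radians per um of z)
helix_amp <- function(cyl, m, beta) {
  Mod(sum(cyl$r * exp(1i * (m * cyl$theta - beta * cyl$z)))) / sum(cyl$r)
}

best_rate <- function(cyl, m, max_twist = 2.2) {
  zspan <- diff(range(cyl$z))
  if (zspan == 0) return(list(beta = 0, amp = helix_amp(cyl, m, 0)))
  bmax <- max_twist * 2 * pi * m / zspan
  grid <- seq(-bmax, bmax, length.out = 1001L)
  amps <- vapply(grid, function(b) helix_amp(cyl, m, b), numeric(1))
  b0 <- grid[which.max(amps)]
  step <- grid[2] - grid[1]
  opt <- stats::optimize(function(b) -helix_amp(cyl, m, b),
                         c(b0 - step, b0 + step))
  list(beta = opt$minimum, amp = -opt$objective)
}

#' Helically compensated angular spectrum
#'
#' `S(m) = max_beta |sum_k r_k exp(i (m theta_k - beta z_k))| / sum_k r_k`:
#' the harmonic content of the centroid angles after allowing a linear
#' angular drift along Z.  A twisted column arrangement moves power away
#' from the column-count harmonic of the plain [angular_spectrum()] (a full
#' revolution of twist across ~K rows pushes it toward the `2C` harmonic);
#' compensating the drift restores the column count as the dominant — and,
#' for an exact C-column helix, tie-broken smallest — harmonic.
#'
#' @inheritParams angular_spectrum
#' @param max_twist Largest |twist| in revolutions scanned over (sanity
#'   bound 2.2).
#' @return Named numeric vector `S1..S<max_m>` with attribute `rates`
#'   (the maximizing angular rate per harmonic, radians/um).
#' @export
helical_spectrum <- function(cyl, max_m = 12L, max_twist = 2.2) {
  if (nrow(cyl) < 3L) abort_usage("need at least 3 points for a spectrum")
  if (all(cyl$r == 0)) abort_degenerate("all points on the axis: no angles")
  fits <- lapply(seq_len(max_m), function(m) best_rate(cyl, m, max_twist))
  S <- vapply(fits, `[[`, numeric(1), "amp")
  structure(stats::setNames(S, paste0("S", seq_len(max_m))),
            rates = vapply(fits, `[[`, numeric(1), "beta"))
}

#' Petal (column) count from an angular spectrum
#'
#' The harmonic maximizing `S(m)`; exact ties go to the smaller harmonic.
#'
#' @param S Spectrum from [angular_spectrum()] or [helical_spectrum()].
#' @return Integer harmonic number.
#' @export
petal_count <- function(S) {
  as.integer(unname(which(S >= max(S) - 1e-12)[1]))
}

#' Assign helical columns and estimate twist and handedness
#'
#' Centroid angles are modelled as `theta = theta0 + 2 pi j / C + omega z`
#' (column `j`, angular rate `omega`).  The rate is found by maximizing the
#' rate-compensated order parameter at harmonic C (multiplying angles by C
#' collapses all columns onto one phase ramp in z); columns are then read
#' off the detrended angles, each column's angles are unwrapped and fitted
#' by least squares against z, and the twist is the mean fitted slope times
#' the centroid z range, in revolutions.  Handedness: `"left"` for twist
#' below -0.05 revolutions, `"right"` above +0.05, `"none"` between.
#'
#' @param cyl Data frame from [to_cylindrical()].
#' @param C Number of columns, or `"auto"` to use
#'   `petal_count(helical_spectrum(cyl))`.
#' @return A list: `columns` (1-based column index per point), `twist`
#'   (revolutions, signed), `twist_ci` (95% half-width across column
#'   slopes; `NA` with fewer than 2 columns), `handedness`, `rate`
#'   (radians/um) and `theta0`.
#' @export
assign_columns_and_twist <- function(cyl, C = "auto") {
  if (identical(C, "auto")) C <- petal_count(helical_spectrum(cyl))
  C <- as.integer(C)
  if (nrow(cyl) < 2L * C)
    abort_usage("need at least 2C points to assign %d columns", C)
  zspan <- diff(range(cyl$z))
  if (zspan == 0) abort_degenerate("z span is zero: twist undefined")

  fit <- best_rate(cyl, C, max_twist = 2.2)
  omega <- fit$beta / C
  zbar <- mean(cyl$z)
  rho <- cyl$theta - omega * (cyl$z - zbar)
  # common phase of the detrended angles, then nearest-column binning
  phi0 <- Arg(sum(cyl$r * exp(1i * C * rho))) / C
  colidx <- as.integer(round((rho - phi0) * C / (2 * pi))) %% C
  # unwrap each angle onto the model and refit per column
  slopes <- numeric(0)
  for (j in sort(unique(colidx))) {
    sel <- colidx == j
    if (sum(sel) < 2L) next
    model <- phi0 + 2 * pi * j / C + omega * (cyl$z[sel] - zbar)
    th_u <- cyl$theta[sel] + 2 * pi * round((model - cyl$theta[sel]) / (2 * pi))
    slopes <- c(slopes, stats::coef(stats::lm(th_u ~ cyl$z[sel]))[2])
  }
  if (!length(slopes)) abort_degenerate("no column has 2 or more scales")
  twist <- mean(slopes) * zspan / (2 * pi)
  ci <- if (length(slopes) >= 2)
    stats::qt(0.975, length(slopes) - 1) * stats::sd(slopes) /
      sqrt(length(slopes)) * zspan / (2 * pi)
  else NA_real_
  hand <- if (abs(twist) < 0.05) "none"
          else if (twist < 0) "left" else "right"
  list(columns = colidx + 1L, twist = unname(twist), twist_ci = unname(ci),
       handedness = hand, rate = omega, theta0 = phi0)
}

#' Volume-versus-Z profile fit and robust outliers
#'
#' Scale volumes along an egg-shaped shell follow a bell-shaped profile:
#' small near aperture and posterior, largest at the equator.  A Gaussian
#' `V(z) = a exp(-(z - mu)^2 / (2 sigma^2))` is fitted by nonlinear least
#' squares (falling back to a quadratic in z if the fit is singular) and
#' scales whose absolute residual exceeds `k` times the robust residual
#' scale (1.4826 * MAD) are reported as outliers.  A zero MAD (e.g. all
#' volumes equal) degrades the threshold to `1e-9 * max |residual|` so only
#' exact outliers are flagged.
#'
#' @param records Data frame with columns `volume_um3`, `centroid_z_um` and
#'   `name` (at least 8 rows with distinct z).
#' @param k Outlier threshold in robust standard deviations (default 3).
#' @return A list: `fit` (named parameters), `method` (`"gaussian"` or
#'   `"quadratic"`), `fitted`, `residuals`, and `outliers` (names sorted by
#'   their numeric suffix where present).
#' @export
volume_profile_outliers <- function(records, k = 3) {
  if (nrow(records) < 8L || length(unique(records$centroid_z_um)) < 8L)
    abort_usage("need >= 8 records with distinct z for a profile fit")
  v <- records$volume_um3
  z <- records$centroid_z_um
  w <- v / sum(v)
  start <- list(a = max(v), mu = sum(w * z),
                sig = sqrt(max(sum(w * (z - sum(w * z))^2), 1e-12)))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-(z - mu)^2 / (2 * sig^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    method <- "gaussian"
    pars <- stats::coef(fit)
    pred <- stats::fitted(fit)
  } else {
    method <- "quadratic"
    qf <- stats::lm(v ~ z + I(z^2))
    pars <- stats::coef(qf)
    pred <- stats::fitted(qf)
  }
  e <- v - pred
  madv <- stats::median(abs(e - stats::median(e)))
  thr <- if (madv > 0) k * 1.4826 * madv else 1e-9 * max(abs(e), 0)
  # numerical floor: a near-perfect fit leaves only rounding noise, which
  # must not be promoted to outliers
  thr <- max(thr, 1e-12 * max(abs(v)))
  out <- records$name[abs(e) > thr]
  num <- suppressWarnings(as.numeric(gsub("\\D", "", out)))
  out <- if (all(!is.na(num))) out[order(num)] else sort(out)
  list(fit = pars, method = method, fitted = as.numeric(pred),
       residuals = as.numeric(e), outliers = out)
}

#' Full architecture analysis of one aligned shell
#'
#' Chains [to_cylindrical()], [angular_spectrum()], [helical_spectrum()],
#' [petal_count()], [assign_columns_and_twist()] and
#' [volume_profile_outliers()] on a morphometry table.
#'
#' @param records Data frame from [measure_scales()] (aligned volume).
#' @param C Column count or `"auto"`.
#' @param max_m Highest harmonic examined.
#' @param outlier_k Threshold for [volume_profile_outliers()].
#' @param exclude_aperture Drop this many scales with the highest and
#'   lowest labels (aperture extras) from the petal/twist analysis; 0 keeps
#'   all.
#' @return A list of class `shell_architecture` with `cylindrical`,
#'   `spectrum` (plain), `spectrum_helical`, `petal_count`, `columns`,
#'   `twist`, `twist_ci`, `handedness`, `volume_profile` and `outliers`.
#' @export
shell_architecture <- function(records, C = "auto", max_m = 12L,
                               outlier_k = 3, exclude_aperture = 0L) {
  rec <- records
  if (exclude_aperture > 0L) {
    ord <- order(rec$label)
    drop <- c(utils::head(ord, exclude_aperture),
              utils::tail(ord, exclude_aperture))
    rec <- rec[-drop, , drop = FALSE]
  }
  cyl <- to_cylindrical(rec)
  spec_plain <- angular_spectrum(cyl, max_m)
  spec_heli <- helical_spectrum(cyl, max_m)
  pc <- petal_count(spec_heli)
  cols <- assign_columns_and_twist(cyl, if (identical(C, "auto")) pc else C)
  prof <- volume_profile_outliers(rec, k = outlier_k)
  structure(list(
    cylindrical = cbind(rec["name"], cyl),
    spectrum = spec_plain,
    spectrum_helical = spec_heli,
    petal_count = pc,
    columns = cols$columns,
    twist = cols$twist,
    twist_ci = cols$twist_ci,
    handedness = cols$handedness,
    volume_profile = prof[c("fit", "method")],
    outliers = prof$outliers
  ), class = "shell_architecture")
}

#' @export
print.shell_architecture <- function(x, ...) {
  cat(sprintf(
    "<shell_architecture> %d petals; twist %.3f rev (%s-handed)\n",
    x$petal_count, x$twist,
    if (x$handedness == "none") "un" else x$handedness))
  if (length(x$outliers))
    cat("volume outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
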