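test_that("cylindrical conversion matches per-point arithmetic", {
  pts <- data.frame(x = c(1, -1), y = c(0, 0), z = c(0, 3))
  cyl <- to_cylindrical(pts)
  expect_equal(cyl$r, c(1, 1))
  expect_setequal(cyl$theta, c(0, pi))
  one <- to_cylindrical(data.frame(x = 2, y = 5, z = 1))
  expect_equal(one$r, 0)
  expect_equal(one$theta, 0)   # on-axis convention
  set.seed(8)
  rnd <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  cyl2 <- to_cylindrical(rnd)
  dx <- rnd$x - mean(rnd$x); dy <- rnd$y - mean(rnd$y)
  expect_equal(cyl2$r, sqrt(dx^2 + dy^2))
  expect_equal(cyl2$theta, atan2(dy, dx))
  expect_equal(cyl2$z, rnd$z)
})

test_that("angular spectrum of a perfect 4-fold pattern", {
  th <- c(0, pi / 2, pi, 3 * pi / 2)
  cyl <- data.frame(r = 1, theta = th, z = 0)
  S <- angular_spectrum(cyl, max_m = 8)
  expect_equal(unname(S[4]), 1)
  expect_equal(unname(S[1:3]), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(S[8]), 1)   # harmonics of 4 also peak
  expect_equal(petal_count(S), 4L) # tie 4 vs 8 broken toward smaller m
})

test_that("spectrum of an untwisted C-column grid peaks at C", {
  C <- 5; K <- 8
  grid <- expand.grid(j = 0:(C - 1), i = 0:(K - 1))
  cyl <- data.frame(r = 1 + 0.3 * sin(grid$i), theta = 2 * pi * grid$j / C,
                    z = grid$i)
  S <- angular_spectrum(cyl)
  expect_equal(petal_count(S), 5L)
  expect_equal(max(S[setdiff(1:12, c(5, 10))]), 0, tolerance = 1e-12)
})

test_that("uniform random angles give a near-flat spectrum", {
  set.seed(99)
  n <- 4000
  cyl <- data.frame(r = 1, theta = runif(n, -pi, pi), z = 0)
  S <- angular_spectrum(cyl)
  expect_lt(max(S), 4 / sqrt(n))
})

test_that("spectrum is invariant under global angle rotation", {
  set.seed(3)
  cyl <- data.frame(r = runif(15, 0.5, 2), theta = runif(15, -pi, pi),
                    z = runif(15))
  for (shift in c(0.3, 1.7, -2.2)) {
    rot <- transform(cyl, theta = theta + shift)
    expect_equal(angular_spectrum(rot), angular_spectrum(cyl),
                 tolerance = 1e-12)
  }
})

test_that("helical spectrum restores the column count under twist", {
  C <- 5; K <- 10
  grid <- expand.grid(j = 0:(C - 1), i = 0:(K - 1))
  z <- grid$i / (K - 1) * 10
  th <- 2 * pi * grid$j / C - 2 * pi * z / 10   # one left-handed revolution
  cyl <- data.frame(r = 1, theta = shellmorph:::wrap_angle(th), z = z)
  plain <- angular_spectrum(cyl)
  heli <- helical_spectrum(cyl)
  expect_equal(petal_count(heli), 5L)
  expect_gt(unname(heli[5]), 0.99)
  # the plain spectrum loses the C peak under a full revolution of twist
  expect_lt(unname(plain[5]), 0.5)
})

test_that("column assignment and twist recover generated ground truth", {
  for (phi in c(-1, -0.5, 0, 0.5, 1)) {
    gen <- generate_shell(mid_shell_spec(twist = phi, seed = 11))
    rec <- measure_scales(gen$volume)
    cyl <- to_cylindrical(rec)
    fit <- assign_columns_and_twist(cyl, C = 5)
    expect_lt(abs(fit$twist - phi), 0.05)
    expect_equal(fit$handedness,
                 if (abs(phi) < 0.05) "none" else if (phi < 0) "left"
                 else "right")
    # columns agree with truth up to a cyclic relabeling
    truthcol <- gen$truth$scales$column[match(rec$label,
                                              gen$truth$scales$label)]
    tab <- table(fit$columns, truthcol)
    expect_equal(sum(apply(tab, 1, max)), nrow(rec))
  }
})

test_that("petal count of the twisted phantom is robust to jitter", {
  gen <- generate_shell(mid_shell_spec(seed = 21))
  rec <- measure_scales(gen$volume)
  cyl <- to_cylindrical(rec)
  expect_equal(petal_count(helical_spectrum(cyl)), 5L)
  # add centroid jitter worth 10% of the mean radius
  set.seed(7)
  for (rep in 1:3) {
    pert <- rec
    amp <- 0.10 * mean(cyl$r)
    pert$centroid_x_um <- pert$centroid_x_um + rnorm(nrow(pert), 0, amp)
    pert$centroid_y_um <- pert$centroid_y_um + rnorm(nrow(pert), 0, amp)
    expect_equal(petal_count(helical_spectrum(to_cylindrical(pert))), 5L)
  }
})

test_that("handedness flips under mirror reflection", {
  gen <- generate_shell(mid_shell_spec(seed = 13))
  rec <- measure_scales(gen$volume)
  fit <- assign_columns_and_twist(to_cylindrical(rec), C = 5)
  mirrored <- rec
  mirrored$centroid_x_um <- -mirrored$centroid_x_um
  fit_m <- assign_columns_and_twist(to_cylindrical(mirrored), C = 5)
  expect_equal(fit_m$twist, -fit$twist, tolerance = 1e-9)
  expect_equal(sort(c(fit$handedness, fit_m$handedness)),
               c("left", "right"))
})

test_that("volume-profile outliers: planted, absent, and degenerate cases", {
  set.seed(1)
  z <- seq(-5, 5, length.out = 40)
  v <- 2 * exp(-z^2 / (2 * 3^2)) + 0.06 * sin(2 * pi * runif(40))
  rec <- data.frame(name = paste0("M", 1:40), volume_um3 = v,
                    centroid_z_um = z)
  expect_length(volume_profile_outliers(rec)$outliers, 0)
  rec$volume_um3[c(7, 31)] <- rec$volume_um3[c(7, 31)] * 1.8
  out <- volume_profile_outliers(rec)
  expect_equal(out$outliers, c("M7", "M31"))
  expect_equal(out$method, "gaussian")
  # all-equal volumes: MAD = 0 handled, nothing flagged
  flat <- data.frame(name = paste0("M", 1:10), volume_um3 = 1,
                     centroid_z_um = 1:10)
  expect_length(volume_profile_outliers(flat)$outliers, 0)
  expect_error(volume_profile_outliers(flat[1:5, ]),
               class = "shellmorph_usage_error")
})

test_that("shell_architecture composes the analysis end to end", {
  gen <- generate_shell(mid_shell_spec(seed = 17,
                                       inflate = c("45" = 1.8, "51" = 1.8)))
  rec <- measure_scales(gen$volume)
  arch <- shell_architecture(rec)
  expect_s3_class(arch, "shell_architecture")
  expect_equal(arch$petal_count, 5L)
  expect_lt(abs(arch$twist + 1), 0.05)
  expect_equal(arch$handedness, "left")
  expect_equal(arch$outliers, c("M45", "M51"))
  expect_length(arch$spectrum, 12L)
})
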