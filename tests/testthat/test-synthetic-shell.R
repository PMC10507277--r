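test_that("egg radius profile has the stated shape", {
  spec <- small_shell_spec(asymmetry = 0)
  L <- spec$half_length; R <- spec$equator_radius
  expect_equal(egg_radius(0, spec), R)
  expect_equal(egg_radius(c(-L, L), spec), c(0, 0))
  u <- seq(0.1, 0.9, by = 0.2)
  expect_equal(egg_radius(u * L, spec), egg_radius(-u * L, spec))
  spec_a <- small_shell_spec(asymmetry = 0.3)
  expect_gt(egg_radius(0.3 * L, spec_a), egg_radius(-0.3 * L, spec_a))
  expect_equal(egg_radius(2 * L, spec_a), 0)   # clamped beyond the poles
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(small_shell_spec(twist = 3), class = "shellmorph_usage_error")
  expect_error(small_shell_spec(angular_gap = 0.6),
               class = "shellmorph_usage_error")
  expect_error(small_shell_spec(half_length = 50),
               "fit inside the grid")
  expect_error(small_shell_spec(per_column = 1),
               class = "shellmorph_usage_error")
})

test_that("a single untwisted column stacks at one angular position", {
  spec <- shell_spec(columns = 1L, per_column = 3L, half_length = 2,
                     equator_radius = 1.2, shell_thickness = 0.3,
                     spacing = 0.06, grid_shape = c(80L, 64L, 64L),
                     twist = 0, jitter = 0, seed = 0L)
  gen <- generate_shell(spec)
  expect_equal(length(present_labels(gen$volume)), 3L)
  rec <- measure_scales(gen$volume)
  # angles about the known shell axis (grid center)
  ctr <- gen$truth$center
  th <- atan2(rec$centroid_y_um - ctr[2], rec$centroid_x_um - ctr[1])
  spread <- diff(range(th)) * 180 / pi
  expect_lt(spread, 1)
})

test_that("generation is deterministic given the seed", {
  g1 <- generate_shell(small_shell_spec(seed = 4))
  g2 <- generate_shell(small_shell_spec(seed = 4))
  expect_identical(g1$volume$voxels, g2$volume$voxels)
  g3 <- generate_shell(small_shell_spec(seed = 5))
  expect_false(identical(g1$volume$voxels, g3$volume$voxels))
})

test_that("scales are disjoint, 6-connected, and never touch face-to-face", {
  gen <- generate_shell(small_shell_spec(grid_shape = c(64L, 64L, 64L),
                                         spacing = 0.105, seed = 2))
  arr <- gen$volume$voxels
  expect_equal(length(unique(arr[arr > 0])), 20L)
  expect_length(bf_touching_labels(arr), 0L)
})

test_that("scale volumes follow a unimodal bell along z", {
  gen <- generate_shell(mid_shell_spec(seed = 3))
  rec <- measure_scales(gen$volume)
  rows <- gen$truth$scales$row[match(rec$label, gen$truth$scales$label)]
  med <- tapply(rec$volume_um3, rows, stats::median)
  med <- med[order(as.integer(names(med)))]
  d <- sign(diff(med))
  expect_lte(sum(diff(d[d != 0]) != 0), 1)   # at most one direction change
})

test_that("ground-truth centroids agree with measured voxel centroids", {
  gen <- generate_shell(small_shell_spec(seed = 6))
  rec <- measure_scales(gen$volume)
  tr <- gen$truth$scales[match(rec$label, gen$truth$scales$label), ]
  dev <- sqrt((rec$centroid_x_um - tr$centroid_x_um)^2 +
              (rec$centroid_y_um - tr$centroid_y_um)^2 +
              (rec$centroid_z_um - tr$centroid_z_um)^2)
  # design center vs voxel centroid differ by curvature effects only
  expect_lt(max(dev), 3 * gen$volume$spacing[1])
})

test_that("cytoplasm plans realize the requested contact classes", {
  classes <- rep("none", 20)
  classes[3] <- "full"; classes[11] <- "partial"
  spec <- small_shell_spec(seed = 1,
    cytoplasm_plan = list(classes = classes, partial_fraction = 1 / 3))
  gen <- generate_shell(spec)
  wc <- add_cytoplasm(gen$volume, gen$truth, spec)
  arr <- wc$volume$voxels
  cyt <- spec$cytoplasm_label
  rec <- measure_scales(wc$volume, cytoplasm_label = cyt)

  # full coverage: every boundary face is a cytoplasm contact (oracle count)
  expect_equal(bf_contact_faces(arr, 3L, cyt), bf_surface_faces(arr, 3L))
  expect_equal(rec$contact_class[rec$label == 3L], "full")
  # partial coverage: contiguous sector close to the target fraction
  frac <- rec$contact_area_um2[rec$label == 11L] /
    rec$surface_area_um2[rec$label == 11L]
  expect_gt(frac, 1 / 3 - 0.10)
  expect_lt(frac, 1 / 3 + 0.10)
  expect_equal(rec$contact_class[rec$label == 11L], "partial")
  # none-class scales have zero contact
  none_labs <- which(classes == "none")
  expect_true(all(rec$contact_area_um2[rec$label %in% none_labs] == 0))
  # truth updated with realized classes
  expect_equal(wc$truth$scales$contact_class[3], "full")
  expect_equal(wc$truth$scales$contact_class[11], "partial")
})

test_that("all-none plan gives zero contact everywhere", {
  spec <- small_shell_spec(seed = 8,
    cytoplasm_plan = list(classes = "none", partial_fraction = 1 / 3))
  gen <- generate_shell(spec)
  wc <- add_cytoplasm(gen$volume, gen$truth, spec)
  rec <- measure_scales(wc$volume, cytoplasm_label = spec$cytoplasm_label)
  expect_true(all(rec$contact_area_um2 == 0))
  expect_true(all(rec$contact_class == "none"))
  # but the blob itself exists
  expect_true(spec$cytoplasm_label %in% present_labels(wc$volume))
})

test_that("mother/daughter pairs are exactly line-symmetric", {
  spec <- shell_spec(columns = 3L, per_column = 4L, half_length = 2.5,
                     equator_radius = 1.6, shell_thickness = 0.3,
                     spacing = 0.08, grid_shape = c(80L, 64L, 64L),
                     twist = -0.5, jitter = 0.03, seed = 2L)
  md <- generate_mother_daughter(spec)
  tr <- md$truth
  n <- spec$n_scales
  labs <- present_labels(md$volume)
  expect_equal(sum(labs <= n), sum(labs > n))   # equal label counts
  expect_equal(length(labs), 2L * n)

  dist_axis <- function(p) {
    rel <- sweep(p, 2, tr$axis$point)
    a <- rel %*% tr$axis$direction
    sqrt(pmax(rowSums(rel^2) - a^2, 0))
  }
  m <- tr$scales[tr$scales$shell == "mother", ]
  d <- tr$scales[tr$scales$shell == "daughter", ]
  mid_true <- homologous_midpoints(m, d)
  expect_lt(max(dist_axis(mid_true)), 1e-9)     # exact in the continuum

  rec <- measure_scales(md$volume)
  midv <- homologous_midpoints(rec[grepl("^M", rec$name), ],
                               rec[grepl("^D", rec$name), ])
  expect_lt(max(dist_axis(midv)), 2 * spec$spacing)
})
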