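test_that("constructor validates voxels and spacing", {
  expect_error(new_label_volume(array(0L, c(2, 2, 2)), c(0, 1, 1)),
               class = "shellmorph_usage_error")
  expect_error(new_label_volume(array(-1L, c(2, 2, 2)), 1),
               class = "shellmorph_format_error")
  v <- new_label_volume(matrix(0L, 8, 8), 1)   # single slice promotes to 3D
  expect_equal(dim(v$voxels), c(1L, 8L, 8L))
  expect_equal(new_label_volume(array(0L, c(2, 2, 2)), 0.5)$spacing,
               rep(0.5, 3))
})

test_that("TIFF round trip preserves voxels, spacing and label set", {
  set.seed(42)
  arr <- array(sample(0:6, 4^3, TRUE), c(4, 4, 4))
  v <- new_label_volume(arr, c(0.02, 0.0073, 0.0073))
  f <- withr::local_tempfile(fileext = ".tif")
  write_label_volume(v, f)
  r <- read_label_volume(f, v$spacing)
  expect_identical(r$voxels, v$voxels)
  expect_identical(r$spacing, v$spacing)
  # independent scan of the written file for the label set
  pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
  expect_setequal(unique(unlist(lapply(pages, as.vector))), 0:6)
})

test_that("single-page TIFF reads as a one-slice volume", {
  f <- withr::local_tempfile(fileext = ".tif")
  v <- new_label_volume(matrix(c(0L, 1L), 8, 8), 1)
  write_label_volume(v, f)
  r <- read_label_volume(f, 1)
  expect_equal(dim(r$voxels), c(1L, 8L, 8L))
  expect_identical(r$voxels, v$voxels)
})

test_that("writes are byte-stable and capacity is enforced", {
  arr <- array(sample(0:52, 6^3, TRUE), c(6, 6, 6))
  v <- new_label_volume(arr, 0.08)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_label_volume(v, f1); write_label_volume(v, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  big <- new_label_volume(array(70000L, c(1, 1, 1)), 1)
  expect_error(write_label_volume(big, f1),
               class = "shellmorph_usage_error")
  r <- read_label_volume(f1, 0.08)
  expect_identical(r$voxels, v$voxels)  # error must not clobber the file
})

test_that("read rejects non-grayscale and inconsistent stacks", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), f)  # RGB page
  expect_error(read_label_volume(f, 1), class = "shellmorph_format_error")
  tiff::writeTIFF(list(matrix(0, 4, 4), matrix(0, 3, 5)), f,
                  bits.per.sample = 16L)
  expect_error(read_label_volume(f, 1), class = "shellmorph_format_error")
  expect_error(read_label_volume(withr::local_tempfile(), 1),
               class = "shellmorph_usage_error")
})

test_that("resampling an isotropic volume to its own spacing is identity", {
  arr <- random_blob(10, seed = 3)
  v <- new_label_volume(arr, 0.05)
  r <- resample_isotropic(v, 0.05)
  expect_identical(r$voxels, v$voxels)
})

test_that("anisotropic cube resamples to the expected bounding box", {
  # 10x10x10 voxels at (0.02, 0.01, 0.01) um -> about 20x10x10 at 0.01 um
  v <- new_label_volume(array(1L, c(10, 10, 10)), c(0.02, 0.01, 0.01))
  r <- resample_isotropic(v, 0.01)
  expect_equal(r$spacing, rep(0.01, 3))
  idx <- which(r$voxels == 1L, arr.ind = TRUE)
  bbox <- apply(idx, 2, function(x) diff(range(x)) + 1L)
  expect_true(abs(bbox[1] - 20) <= 1)
  expect_true(abs(bbox[2] - 10) <= 1)
  expect_true(abs(bbox[3] - 10) <= 1)
})

test_that("resampling conserves blob volume within 5%", {
  arr <- random_blob(14, seed = 7)
  v <- new_label_volume(arr, c(0.02, 0.01, 0.01))
  vol_in <- bf_count(arr, 1L) * 0.02 * 0.01 * 0.01
  r <- resample_isotropic(v, 0.008)
  vol_out <- sum(r$voxels == 1L) * 0.008^3
  expect_lt(abs(vol_out / vol_in - 1), 0.05)
  # and back to a coarser grid
  r2 <- resample_isotropic(r, 0.012)
  vol_back <- sum(r2$voxels == 1L) * 0.012^3
  expect_lt(abs(vol_back / vol_in - 1), 0.05)
})

test_that("multi-label resampling keeps labels disjoint and warns on loss", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:5, 2:3, 2:5] <- 1L
  arr[2:5, 4:5, 2:5] <- 2L
  arr[1, 1, 1] <- 3L   # single voxel: vanishes at a coarse target
  v <- new_label_volume(arr, 0.01)
  expect_warning(r <- resample_isotropic(v, 0.03), "label 3 vanished")
  expect_true(all(unique(as.vector(r$voxels)) %in% c(0L, 1L, 2L)))
})

test_that("mesh export: cube and bar triangle counts, and oracle equality", {
  v1 <- new_label_volume(array(1L, c(1, 1, 1)), 1)
  f <- withr::local_tempfile(fileext = ".stl")
  expect_equal(attr(export_scale_mesh(v1, 1, f), "n_triangles"), 12L)
  bar <- new_label_volume(array(1L, c(1, 1, 2)), 1)
  expect_equal(attr(export_scale_mesh(bar, 1, f), "n_triangles"), 20L)
  blob <- random_blob(10, seed = 5)
  vb <- new_label_volume(blob, 0.5)
  nt <- attr(export_scale_mesh(vb, 1, f), "n_triangles")
  expect_equal(nt, 2L * bf_surface_faces(blob, 1L))
  expect_error(export_scale_mesh(vb, 9, f), class = "shellmorph_usage_error")
})

test_that("exported meshes are closed with outward unit normals", {
  blob <- random_blob(10, seed = 11, nballs = 1)
  vb <- new_label_volume(blob, 0.25)
  f <- withr::local_tempfile(fileext = ".stl")
  export_scale_mesh(vb, 1, f)
  m <- read_stl(f)
  expect_equal(m$n, 2L * bf_surface_faces(blob, 1L))
  expect_true(all(abs(rowSums(m$normal^2) - 1) < 1e-6))
  # each undirected edge is used by exactly two triangles
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  vkey <- function(v) apply(round(v, 6), 1, paste, collapse = ",")
  k1 <- vkey(m$v1); k2 <- vkey(m$v2); k3 <- vkey(m$v3)
  edges <- c(key(k1, k2), key(k2, k3), key(k3, k1))
  expect_true(all(table(edges) == 2L))
  # orientation: right-hand rule of each triangle reproduces its normal
  e1 <- m$v2 - m$v1; e2 <- m$v3 - m$v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cr <- cr / sqrt(rowSums(cr^2))
  expect_true(all(abs(cr - m$normal) < 1e-6))
})
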