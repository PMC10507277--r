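# Brute-force oracles, written independently of the package internals:
# plain loops over voxels with explicit 6-neighbor checks.

bf_count <- function(arr, label) sum(arr == label)

bf_centroid <- function(arr, label, s) {
  acc <- c(0, 0, 0); n <- 0
  d <- dim(arr)
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3]) {
    if (arr[k, j, i] == label) {
      acc <- acc + c((i - 0.5) * s, (j - 0.5) * s, (k - 0.5) * s)
      n <- n + 1
    }
  }
  acc / n  # (x, y, z)
}

bf_neighbor <- function(arr, k, j, i, dk, dj, di) {
  d <- dim(arr)
  kk <- k + dk; jj <- j + dj; ii <- i + di
  if (kk < 1 || kk > d[1] || jj < 1 || jj > d[2] || ii < 1 || ii > d[3])
    return(0L)
  arr[kk, jj, ii]
}

bf_offsets <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                    c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))

bf_surface_faces <- function(arr, label) {
  d <- dim(arr); n <- 0L
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3]) {
    if (arr[k, j, i] != label) next
    for (o in 1:6)
      if (bf_neighbor(arr, k, j, i, bf_offsets[o, 1], bf_offsets[o, 2],
                      bf_offsets[o, 3]) != label) n <- n + 1L
  }
  n
}

bf_contact_faces <- function(arr, a, b) {
  d <- dim(arr); n <- 0L
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3]) {
    if (arr[k, j, i] != a) next
    for (o in 1:6)
      if (bf_neighbor(arr, k, j, i, bf_offsets[o, 1], bf_offsets[o, 2],
                      bf_offsets[o, 3]) == b) n <- n + 1L
  }
  n
}

# any pair of distinct nonzero labels sharing a face?
bf_touching_labels <- function(arr) {
  d <- dim(arr)
  pairs <- character(0)
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3]) {
    v <- arr[k, j, i]
    if (v == 0) next
    for (o in 1:6) {
      w <- bf_neighbor(arr, k, j, i, bf_offsets[o, 1], bf_offsets[o, 2],
                       bf_offsets[o, 3])
      if (w != 0 && w != v) pairs <- c(pairs, paste(min(v, w), max(v, w)))
    }
  }
  unique(pairs)
}

# random blob: union of a few balls on a small grid
random_blob <- function(n = 12, seed = 1, label = 1L, nballs = 3) {
  set.seed(seed)
  arr <- array(0L, c(n, n, n))
  for (b in seq_len(nballs)) {
    c0 <- runif(3, n * 0.3, n * 0.7)
    r <- runif(1, n * 0.12, n * 0.25)
    for (k in 1:n) for (j in 1:n) for (i in 1:n)
      if ((k - c0[1])^2 + (j - c0[2])^2 + (i - c0[3])^2 <= r^2)
        arr[k, j, i] <- label
  }
  arr
}

# digital prolate ellipsoid along an arbitrary axis
make_ellipsoid <- function(n = 48, axis = c(0, 0, 1), semi = c(16, 7),
                           s = 1) {
  axis <- axis / sqrt(sum(axis^2))
  arr <- array(0L, c(n, n, n))
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(k = 1:n, j = 1:n, i = 1:n))
  p <- cbind(co[, "i"] - ctr, co[, "j"] - ctr, co[, "k"] - ctr)
  ax <- p %*% axis
  pr2 <- rowSums(p^2) - ax^2
  arr[(ax / semi[1])^2 + pr2 / semi[2]^2 <= 1] <- 1L
  new_label_volume(arr, s)
}

# parse a binary STL file: list(n, normals, v1, v2, v3) as n x 3 matrices
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- matrix(NA_real_, n, 12)
  for (t in seq_len(n)) {
    dat[t, ] <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
  }
  list(n = n, normal = dat[, 1:3], v1 = dat[, 4:6], v2 = dat[, 7:9],
       v3 = dat[, 10:12])
}

# small, fast phantom spec used across tests
small_shell_spec <- function(...) {
  args <- list(columns = 4L, per_column = 5L, half_length = 3,
               equator_radius = 2, asymmetry = 0.3, shell_thickness = 0.3,
               spacing = 0.07, grid_shape = c(96L, 96L, 96L), twist = -0.5,
               jitter = 0.05, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(shell_spec, args)
}

# half-scale version of the study preset (same architecture, lighter grid)
mid_shell_spec <- function(...) {
  args <- list(columns = 5L, per_column = 10L, extra_aperture_scales = 2L,
               half_length = 3.25, equator_radius = 2, asymmetry = 0.35,
               shell_thickness = 0.3, spacing = 0.08,
               grid_shape = c(96L, 96L, 96L), twist = -1, jitter = 0.075,
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(shell_spec, args)
}
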