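# Shift a 3D array by one voxel along an axis, filling vacated entries.
# shift = +1 returns an array whose element [k] holds the input at [k - 1]
# along `axis` (i.e. the neighbor on the low side); outside the volume the
# fill value is used.  Works for logical, integer and double arrays.
shift3 <- function(arr, axis, shift, fill) {
  d <- dim(arr)
  out <- array(fill, d)
  n <- d[axis]
  if (n <= abs(shift)) return(out)
  src <- if (shift > 0) 1:(n - shift) else (1 - shift):n
  dst <- if (shift > 0) (1 + shift):n else 1:(n + shift)
  if (axis == 1L) out[dst, , ] <- arr[src, , , drop = FALSE]
  else if (axis == 2L) out[, dst, ] <- arr[, src, , drop = FALSE]
  else out[, , dst] <- arr[, , src, drop = FALSE]
  out
}

# The six face directions: axis, sign, and unit world direction (x, y, z).
face_dirs <- function() {
  list(list(axis = 1L, sgn = -1L, n = c(0, 0, -1)),
       list(axis = 1L, sgn = +1L, n = c(0, 0, 1)),
       list(axis = 2L, sgn = -1L, n = c(0, -1, 0)),
       list(axis = 2L, sgn = +1L, n = c(0, 1, 0)),
       list(axis = 3L, sgn = -1L, n = c(-1, 0, 0)),
       list(axis = 3L, sgn = +1L, n = c(1, 0, 0)))
}

# Neighbor labels of every voxel in direction dir (index into face_dirs());
# voxels outside the volume read as `outside` (background by default).
# nb[k] = arr[k + sgn] along the axis, i.e. a shift by -sgn.
neighbor3 <- function(arr, dir, outside = 0L) {
  d <- face_dirs()[[dir]]
  shift3(arr, d$axis, -d$sgn, outside)
}
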