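# Geometry: world/voxel maps and trilinear sampling.
#
# Convention: voxel indices are 0-based; the affine is axis-aligned with
# positive spacing, world = origin + spacing * index (mm).

#' NIfTI-style affine of a field's grid
#'
#' @param field a [velocity_field()] or [phase_field()].
#' @return 4 x 4 voxel-to-world affine (mm), 0-based voxel indices.
#' @export
field_affine <- function(field) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(field$voxel_spacing)
  A[1:3, 4] <- field$origin
  A
}

#' Map world coordinates to continuous 0-based voxel indices
#'
#' @param field a [velocity_field()] or [phase_field()].
#' @param xyz n x 3 matrix of world mm.
#' @return n x 3 matrix of continuous voxel indices (0-based).
#' @export
world_to_voxel <- function(field, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, field$origin, "-"), 2, field$voxel_spacing, "/")
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param field a [velocity_field()] or [phase_field()].
#' @param ijk n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @return n x 3 matrix of world mm.
#' @export
voxel_to_world <- function(field, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk, 2, field$voxel_spacing, "*"), 2, field$origin, "+")
}

# World-coordinate axis vectors of all voxel centres (separable grid)
grid_world_axes <- function(field) {
  d <- dim(field$velocities %||% field$phases)
  lapply(1:3, function(a) field$origin[a] + (seq_len(d[a]) - 1) * field$voxel_spacing[a])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trilinear interpolation of a 3-D volume at continuous 0-based indices.
# Points with any coordinate outside [0, n-1] return NA.
sample_trilinear <- function(vol, ijk) {
  d <- dim(vol)
  ijk <- rbind(ijk)
  n <- nrow(ijk)
  out <- rep(NA_real_, n)
  ok <- ijk[, 1] >= 0 & ijk[, 1] <= d[1] - 1 &
        ijk[, 2] >= 0 & ijk[, 2] <= d[2] - 1 &
        ijk[, 3] >= 0 & ijk[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  p <- ijk[ok, , drop = FALSE]
  # degenerate singleton axes: base index 0 and zero fraction
  base <- function(a) if (d[a] > 1) pmax(0, pmin(floor(p[, a]), d[a] - 2)) else rep(0, nrow(p))
  i0 <- base(1); j0 <- base(2); k0 <- base(3)
  fx <- if (d[1] > 1) p[, 1] - i0 else 0
  fy <- if (d[2] > 1) p[, 2] - j0 else 0
  fz <- if (d[3] > 1) p[, 3] - k0 else 0
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  lin <- function(i, j, k) vol[1 + i + d[1] * (j + d[2] * k)]
  v000 <- lin(i0, j0, k0); v100 <- lin(i1, j0, k0)
  v010 <- lin(i0, j1, k0); v110 <- lin(i1, j1, k0)
  v001 <- lin(i0, j0, k1); v101 <- lin(i1, j0, k1)
  v011 <- lin(i0, j1, k1); v111 <- lin(i1, j1, k1)
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Even-odd (ray-crossing) point-in-polygon with a half-open edge rule:
# a point exactly on a left/bottom edge is inside, on a right/top edge
# outside, so abutting contours tile the plane without double counting.
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area of a polygon (mm^2), sign-free
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
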