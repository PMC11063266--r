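#' Tetrahedron volume
#'
#' Volume of the tetrahedron spanned by four vertices,
#' `|det(v1 - v0, v2 - v0, v3 - v0)| / 6`. Invariant under vertex permutation
#' and rigid motion; degenerate (coplanar) vertices give exactly 0.
#'
#' @param vertices 4 x 3 numeric matrix, one vertex per row, mm.
#' @return Volume in mm^3.
#' @export
#' @examples
#' tetra_volume(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))  # 1/6
tetra_volume <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(nrow(vertices) == 4L, ncol(vertices) == 3L)
  if (any(!is.finite(vertices))) stop("tetrahedron vertices must be finite")
  m <- sweep(vertices[2:4, , drop = FALSE], 2, vertices[1, ])
  abs(det(m)) / 6
}

# Barycentric coordinates of points relative to a tetrahedron.
# pts: n x 3. Returns n x 4 matrix (coordinates sum to 1 per row), or NULL if
# the tetrahedron is degenerate (|det| below tol relative to edge scale).
barycentric_coords <- function(pts, vertices) {
  vertices <- as.matrix(vertices)
  m <- t(sweep(vertices[2:4, , drop = FALSE], 2, vertices[1, ]))  # 3x3 columns = edges
  scale <- max(abs(m))
  if (scale == 0 || abs(det(m)) < 1e-12 * scale^3) return(NULL)
  rel <- sweep(as.matrix(pts), 2, vertices[1, ])
  b <- t(solve(m, t(rel)))                       # n x 3: coords on v1..v3
  cbind(1 - rowSums(b), b)
}

#' Point-in-tetrahedron test
#'
#' A point is inside iff all four barycentric coordinates are `>= -eps`
#' (boundary points, faces and vertices count as inside).
#'
#' @param p Numeric length-3 point, or an n x 3 matrix of points.
#' @param vertices 4 x 3 vertex matrix.
#' @param eps Relative tolerance on the barycentric coordinates.
#' @return Logical scalar or vector.
#' @export
point_in_tetra <- function(p, vertices, eps = 1e-9) {
  pts <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  b <- barycentric_coords(pts, vertices)
  if (is.null(b)) stop("degenerate tetrahedron: vertices are coplanar")
  res <- rowSums(b < -eps) == 0
  if (is.null(dim(p))) res[1] else res
}

#' Per-tissue-class volumes inside a tetrahedron
#'
#' Counts label-map voxels whose *centers* fall inside the tetrahedron
#' (boundary-inclusive) and converts counts to mm^3 with the voxel volume.
#' Only the bounding box of the tetrahedron is scanned. A degenerate
#' tetrahedron, or one that misses the grid, contributes all-zero volumes.
#'
#' @param labelmap A [label_map()].
#' @param vertices 4 x 3 vertex matrix (mm, same frame as the label map).
#' @param eps Barycentric boundary tolerance, see [point_in_tetra()].
#' @return Named numeric vector of volumes (mm^3), one entry per tissue class.
#' @export
tissue_volumes_in_tetra <- function(labelmap, vertices, eps = 1e-9) {
  stopifnot(inherits(labelmap, "label_map"))
  vertices <- as.matrix(vertices)
  zero <- stats::setNames(numeric(8), tissue_names())
  dims <- dim(labelmap$grid)
  sp <- labelmap$spacing_mm
  org <- labelmap$origin_mm

  # index range of the tetra bounding box, clipped to the grid
  lo <- pmax(1L, ceiling((apply(vertices, 2, min) - org) / sp - eps) + 1L)
  hi <- pmin(dims, floor((apply(vertices, 2, max) - org) / sp + eps) + 1L)
  if (any(lo > hi)) return(zero)

  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- org[1] + (ix - 1) * sp[1]
  cy <- org[2] + (iy - 1) * sp[2]
  cz <- org[3] + (iz - 1) * sp[3]
  n <- length(ix) * length(iy) * length(iz)
  pts <- cbind(rep(cx, times = length(iy) * length(iz)),
               rep(rep(cy, each = length(ix)), times = length(iz)),
               rep(cz, each = length(ix) * length(iy)))
  b <- barycentric_coords(pts, vertices)
  if (is.null(b)) return(zero)   # degenerate: zero volumes by design
  inside <- rowSums(b < -eps) == 0
  if (!any(inside)) return(zero)

  labs <- labelmap$grid[ix, iy, iz]
  counts <- tabulate(as.vector(labs)[inside] + 1L, nbins = 8L)
  stats::setNames(counts * voxel_volume(labelmap), tissue_names())
}

# Resolve a path's four landmark ids into a 4x3 vertex matrix.
resolve_tetra <- function(landmarks, ids) {
  missing <- setdiff(ids, rownames(landmarks))
  if (length(missing))
    stop("cannot resolve landmark id(s): ", paste(missing, collapse = ", "))
  unclass(landmarks)[ids, , drop = FALSE]
}
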