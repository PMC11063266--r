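# Shared fixtures, built in code. Small phantoms use a 64^3 grid at 1.5 mm
# so they still contain the full anatomical layout but rasterize fast.

small_params <- function(...) {
  phantom_params(grid_shape = c(64L, 64L, 64L),
                 spacing_mm = c(1.5, 1.5, 1.5), ...)
}

# memoised default small phantom (built once per test file)
.fixture_env <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(.fixture_env$ph))
    .fixture_env$ph <- generate_phantom(small_params())
  .fixture_env$ph
}

# a tiny all-space label map
uniform_map <- function(code = 0L, n = 24L, spacing = 1) {
  label_map(array(as.integer(code), dim = rep(n, 3L)),
            spacing_mm = rep(spacing, 3),
            origin_mm = rep(-(n - 1) * spacing / 2, 3))
}

# the smallest legal topology: one tetrahedron, two of its faces as windows
minimal_topology_config <- function() {
  list(
    schema = 1,
    landmarks = list("p", "q", "r", "s"),
    tubercle_landmark = "q",
    start_window = "in",
    end_window = "out",
    windows = list(list(id = "in", landmarks = list("p", "q", "r")),
                   list(id = "out", landmarks = list("q", "r", "s"))),
    paths = list(list(id = "pqrs", landmarks = list("p", "q", "r", "s"),
                      entry_window = "in", exit_window = "out")),
    plans = list(list(id = "only", paths = list("pqrs")))
  )
}

# Monte-Carlo oracle: classify n uniform points in the tetra by nearest-voxel
# label, scale by the analytic volume. Returns per-class volume estimates and
# standard errors. Independent of the voxel-counting implementation.
mc_tissue_volumes <- function(labelmap, verts, n = 1e5) {
  v0 <- verts[1, ]
  e <- sweep(verts[2:4, , drop = FALSE], 2, v0)
  # uniform sampling in a tetrahedron by folded barycentric coordinates
  u <- matrix(stats::runif(3 * n), ncol = 3)
  s <- u[, 1]; t <- u[, 2]; w <- u[, 3]
  flip <- s + t > 1
  s[flip] <- 1 - s[flip]; t[flip] <- 1 - t[flip]
  c1 <- t + w > 1
  tmp <- w[c1]
  w[c1] <- 1 - s[c1] - t[c1]
  t[c1] <- 1 - tmp
  c2 <- !c1 & (s + t + w > 1)
  tmp <- w[c2]
  w[c2] <- s[c2] + t[c2] + tmp - 1
  s[c2] <- 1 - t[c2] - tmp
  pts <- cbind(v0[1] + s * e[1, 1] + t * e[2, 1] + w * e[3, 1],
               v0[2] + s * e[1, 2] + t * e[2, 2] + w * e[3, 2],
               v0[3] + s * e[1, 3] + t * e[2, 3] + w * e[3, 3])
  idx <- sapply(1:3, function(ax)
    pmin(pmax(round((pts[, ax] - labelmap$origin_mm[ax]) /
                      labelmap$spacing_mm[ax]) + 1, 1),
         dim(labelmap$grid)[ax]))
  labs <- labelmap$grid[cbind(idx[, 1], idx[, 2], idx[, 3])]
  vol <- tetra_volume(verts)
  frac <- tabulate(labs + 1L, nbins = 8L) / n
  list(volumes = stats::setNames(frac * vol, cliviplan:::tissue_names()),
       se = stats::setNames(sqrt(frac * (1 - frac) / n) * vol,
                            cliviplan:::tissue_names()))
}

# random non-degenerate tetrahedron inside a bounding box
random_tetra <- function(lo = -40, hi = 40, min_vol = 500) {
  repeat {
    v <- matrix(stats::runif(12, lo, hi), 4, 3)
    if (tetra_volume(v) >= min_vol) return(v)
  }
}
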