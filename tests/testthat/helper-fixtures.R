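## Shared fixtures, built in code and cached per test run. Unit tests
## use small discretizations; the full paper-sized meshes are only
## assembled by test-acceptance.R (and cached here so criteria can
## share them).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

## small sphere benchmark (N = 256) for unit tests
small_sphere <- function() {
  cached("small_sphere", make_sphere_scenario(n_theta = 16, n_phi = 16))
}

small_sphere_system <- function() {
  cached("small_sphere_system", build_system(small_sphere()$mesh))
}

## small channel (about 200 tiles) for unit tests
small_channel_mesh <- function() {
  cached("small_channel_mesh", {
    m <- tile_channel(n_tiles_target = 200)
    assign_dielectrics(m, eps_ahead = 6, eps_behind = 80)
  })
}

## paper-sized fixtures (acceptance suite)
paper_sphere <- function() {
  cached("paper_sphere", make_sphere_scenario(n_theta = 32, n_phi = 32))
}

paper_sphere_system <- function() {
  cached("paper_sphere_system", build_system(paper_sphere()$mesh))
}

paper_channel_sweep <- function() {
  cached("paper_channel_sweep",
         trajectory_sweep(radial_offsets = c(0, 1.5, 3.0, 4.5),
                          z_values = seq(-40, 0, by = 0.5),
                          n_tiles_target = 860))
}

## independent oracle: matrix entry (i, j) recomputed by k x k sub-tile
## quadrature of the same integral (>= 16 points)
entry_by_subquadrature <- function(mesh, i, j, k = 4L) {
  sub <- iccbem:::subdivide_tile(mesh, j, k)
  d <- cbind(mesh$center[i, 1] - sub$center[, 1],
             mesh$center[i, 2] - sub$center[, 2],
             mesh$center[i, 3] - sub$center[, 3])
  r <- sqrt(rowSums(d * d))
  coef <- mesh$delta_eps[i] / (4 * pi * mesh$mean_eps[i])
  coef * sum((d %*% mesh$normal[i, ]) / r^3 * sub$area)
}

## does a rigid transform map the tile-center set onto itself?
maps_onto_itself <- function(centers, transformed, tol = 1e-8) {
  nn <- apply(transformed, 1, function(p)
    min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
               (centers[, 3] - p[3])^2)))
  max(nn) < tol
}

rot_z <- function(pts, angle) {
  cbind(cos(angle) * pts[, 1] - sin(angle) * pts[, 2],
        sin(angle) * pts[, 1] + cos(angle) * pts[, 2], pts[, 3])
}
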