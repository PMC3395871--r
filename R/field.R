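## Potential and field evaluation by superposition of Coulombic
## contributions: the screened source term sum_k q_k/(eps_k |r - r_k|)
## plus the induced term sum_i h_i a_i / |r - r_i| (the solved surface
## densities treated as point charges at the collocation points, the
## same quadrature used during the solve). Reduced units throughout;
## the profile carries a volts column via REDUCED_TO_VOLTS.

## 1/r sum helpers; dist-proximity guarded by the callers
inv_dist_matrix <- function(pts, src) {
  dx <- outer(pts[, 1], src[, 1], "-")
  dy <- outer(pts[, 2], src[, 2], "-")
  dz <- outer(pts[, 3], src[, 3], "-")
  1 / sqrt(dx * dx + dy * dy + dz * dz)
}

check_proximity <- function(pts, src, min_dist, what) {
  if (!nrow(src)) return(invisible())
  dx <- outer(pts[, 1], src[, 1], "-")
  dy <- outer(pts[, 2], src[, 2], "-")
  dz <- outer(pts[, 3], src[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < min_dist^2)) {
    ij <- which(r2 < min_dist^2, arr.ind = TRUE)[1, ]
    stop_bem("proximity",
             "evaluation point %d is %.3g A from %s %d (minimum %.3g A)",
             ij[1], sqrt(r2[ij[1], ij[2]]), what, ij[2], min_dist)
  }
  invisible()
}

## induced-charge potential sum_i h_i a_i / |r - r_i|, with optional
## sub-tile quadrature for tiles within near_factor tile-widths of an
## evaluation point (the same refinement the solver applies to the
## source vector; needed for accurate values close to the boundary)
induced_potential <- function(pts, h, mesh, refine_near = TRUE,
                              n_sub = 8L, near_factor = 4) {
  val <- as.numeric(inv_dist_matrix(pts, mesh$center) %*% (h * mesh$area))
  if (!isTRUE(refine_near)) return(val)
  w <- pmax(mesh$widths[, 1], mesh$widths[, 2])
  dx <- outer(mesh$center[, 1], pts[, 1], "-")
  dy <- outer(mesh$center[, 2], pts[, 2], "-")
  dz <- outer(mesh$center[, 3], pts[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  near <- which(r2 < (near_factor * w)^2, arr.ind = TRUE)
  if (!nrow(near)) return(val)
  subs <- list()
  for (m in seq_len(nrow(near))) {
    i <- near[m, 1]; p <- near[m, 2]
    key <- as.character(i)
    if (is.null(subs[[key]])) subs[[key]] <- subdivide_tile(mesh, i, n_sub)
    sub <- subs[[key]]
    dd <- sqrt((pts[p, 1] - sub$center[, 1])^2 +
               (pts[p, 2] - sub$center[, 2])^2 +
               (pts[p, 3] - sub$center[, 3])^2)
    val[p] <- val[p] - h[i] * mesh$area[i] / sqrt(r2[i, p]) +
      h[i] * sum(sub$area / dd)
  }
  val
}

new_profile <- function(pts, source_part, induced_part) {
  total <- source_part + induced_part
  structure(data.frame(
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    potential_reduced = total,
    potential_V = total * REDUCED_TO_VOLTS,
    source_part = source_part,
    induced_part = induced_part
  ), class = c("potential_profile", "data.frame"))
}

#' Total electrostatic potential at a set of points
#'
#' Superposition of the screened Coulomb potential of the source
#' charges and the potential of the solved induced surface charges. The
#' `potential_reduced` column equals `source_part + induced_part`
#' exactly.
#'
#' @param points evaluation points (`n x 3` matrix, Angstrom); each
#'   point must be at least `min_dist` from every tile collocation
#'   point and every source charge.
#' @param charges a [charge_set()].
#' @param solution an `induced_solution` solved on `mesh`.
#' @param mesh the `bem_mesh`.
#' @param min_dist proximity guard in Angstrom.
#' @param refine_near logical; sub-tile quadrature of the induced term
#'   for tiles close to an evaluation point (matches the source-side
#'   refinement of [build_source()]).
#' @return A `potential_profile` data frame (reduced units and volts).
#' @export
potential_at <- function(points, charges, solution, mesh, min_dist = 0.05,
                         refine_near = TRUE) {
  pts <- as_points(points)
  check_proximity(pts, mesh$center, min_dist, "tile")
  src <- numeric(nrow(pts))
  if (nrow(charges)) {
    cpos <- charge_positions(charges)
    check_proximity(pts, cpos, min_dist, "charge")
    src <- as.numeric(inv_dist_matrix(pts, cpos) %*% (charges$q / charges$eps))
  }
  ind <- induced_potential(pts, solution$h, mesh, refine_near)
  new_profile(pts, src, ind)
}

#' Reaction potential (induced charges only) at a set of points
#'
#' The part of the potential due to the induced surface charges alone;
#' for a single ion this is the dielectric self-energy landscape that
#' repels ions from low-permittivity regions. Points may coincide with
#' source charges (only tile proximity is checked).
#'
#' @inheritParams potential_at
#' @return A `potential_profile` with zero `source_part`.
#' @export
reaction_potential_at <- function(points, solution, mesh, min_dist = 0.05,
                                  refine_near = TRUE) {
  pts <- as_points(points)
  check_proximity(pts, mesh$center, min_dist, "tile")
  ind <- induced_potential(pts, solution$h, mesh, refine_near)
  new_profile(pts, numeric(nrow(pts)), ind)
}

#' Electric field at a set of points
#'
#' Gradient superposition of the source and induced Coulomb terms, in
#' reduced units of e/(4 pi eps0 A^2).
#'
#' @inheritParams potential_at
#' @return A data frame with Ex, Ey, Ez columns.
#' @export
field_at <- function(points, charges, solution, mesh, min_dist = 0.05) {
  pts <- as_points(points)
  check_proximity(pts, mesh$center, min_dist, "tile")
  acc <- matrix(0, nrow(pts), 3)
  addsrc <- function(src, qeff) {
    dx <- outer(pts[, 1], src[, 1], "-")
    dy <- outer(pts[, 2], src[, 2], "-")
    dz <- outer(pts[, 3], src[, 3], "-")
    r3 <- (dx * dx + dy * dy + dz * dz)^1.5
    cbind((dx / r3) %*% qeff, (dy / r3) %*% qeff, (dz / r3) %*% qeff)
  }
  if (nrow(charges)) {
    cpos <- charge_positions(charges)
    check_proximity(pts, cpos, min_dist, "charge")
    acc <- acc + addsrc(cpos, charges$q / charges$eps)
  }
  acc <- acc + addsrc(mesh$center, solution$h * mesh$area)
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             Ex = acc[, 1], Ey = acc[, 2], Ez = acc[, 3])
}

#' Gauss's-law audit of an induced solution
#'
#' Compares the total induced charge on the boundary with the
#' closed-form value implied by the enclosed source charges
#' ([gauss_expected_charge()]); an audit that should accompany every
#' boundary-element electrostatics calculation. For sphere meshes the
#' enclosed region is the interior ball; for channel meshes it is the
#' membrane slab bounded by the tiled interface (a moving ion in the
#' water phase is exterior and the expected total is zero).
#'
#' @param solution an `induced_solution`.
#' @param mesh the `bem_mesh` it was solved on (dielectrics assigned).
#' @param charges the source [charge_set()].
#' @return A `gauss_report` list: `total_induced_e`, `expected_e`,
#'   `abs_error_e`, and `error_pct_of_e` (in percent of one elementary
#'   charge).
#' @export
gauss_check <- function(solution, mesh, charges) {
  eps <- enclosed_eps(mesh)
  inside <- if (nrow(charges))
    region_enclosed(mesh$geometry, charge_positions(charges))
  else logical(0)
  expected <- gauss_expected_charge(charges, inside,
                                    eps[["inside"]], eps[["outside"]])
  total <- solution$total_induced_e
  structure(list(total_induced_e = total, expected_e = expected,
                 abs_error_e = abs(total - expected),
                 error_pct_of_e = 100 * abs(total - expected)),
            class = "gauss_report")
}

#' @export
print.gauss_report <- function(x, ...) {
  cat(sprintf(
    "<gauss_report> induced %.6g e, expected %.6g e, error %.3g e (%.3g%% of e)\n",
    x$total_induced_e, x$expected_e, x$abs_error_e, x$error_pct_of_e))
  invisible(x)
}

#' Total potential on a square grid inside the pore cross-section
#'
#' Evaluates the total potential on a regular `grid_n x grid_n` grid in
#' the plane `z = plane_z`. Grid points outside the pore interior
#' (radius larger than the pore radius minus a small margin) get `NA`.
#'
#' @param plane_z z of the evaluation plane, Angstrom.
#' @param grid_half_width half-width of the square grid, Angstrom.
#' @param grid_n points per side.
#' @param charges a [charge_set()].
#' @param solution an `induced_solution`.
#' @param mesh a channel `bem_mesh`.
#' @param margin exclusion margin from the pore wall, Angstrom.
#' @return A `potential_profile` with one row per grid point (row-major
#'   over y within x); out-of-pore rows carry `NA` potentials.
#' @export
potential_map <- function(plane_z, grid_half_width, grid_n, charges,
                          solution, mesh, margin = 0.25) {
  if (mesh$geometry$type != "channel")
    stop_bem("config", "potential maps are defined for channel meshes")
  xs <- seq(-grid_half_width, grid_half_width, length.out = grid_n)
  g <- expand.grid(y = xs, x = xs)[, c("x", "y")]
  pts <- cbind(g$x, g$y, plane_z)
  rmax <- mesh$geometry$pore_radius - margin
  ok <- sqrt(pts[, 1]^2 + pts[, 2]^2) <= rmax
  prof <- new_profile(pts, rep(NA_real_, nrow(pts)), rep(NA_real_, nrow(pts)))
  if (any(ok)) {
    sub <- potential_at(pts[ok, , drop = FALSE], charges, solution, mesh)
    prof[ok, ] <- sub
  }
  prof
}

#' Write a potential profile to CSV
#'
#' Columns: x, y, z, potential_reduced, potential_V, source_part,
#' induced_part, 17 significant digits.
#'
#' @param profile a `potential_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write_csv17(as.data.frame(profile), path)
}

#' Write a potential map as a dense matrix CSV plus a JSON sidecar
#'
#' The matrix holds `potential_reduced` with rows indexed by y and
#' columns by x; grid metadata (plane z, half-width, n) goes to
#' `<path>.json`.
#'
#' @param profile a `potential_profile` from [potential_map()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(profile, path) {
  n <- as.integer(sqrt(nrow(profile)))
  m <- matrix(profile$potential_reduced, nrow = n)   # y fast within x
  utils::write.table(matrix(fmt_num(m), nrow = n), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(plane_z = profile$z[1], grid_n = n,
               half_width = max(abs(profile$x)),
               units = "e/(4 pi eps0 Angstrom)")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
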