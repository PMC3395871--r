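## Analytic tile generators for the two supported boundary families:
## spheres (uniform theta/phi bands) and axisymmetric membrane-channel
## profiles (cylindrical pore wall, toroidal rounded corners, flat
## annular membrane faces). Every tile is a curved patch of an analytic
## surface; its area is exact, its collocation point is the parameter
## area centroid projected onto the surface, and its signed principal
## curvatures (relative to the tile normal) are stored so that the
## solver can apply a curved-tile self-interaction correction.

## ---- analytic patch primitives ---------------------------------------
## Each patch function is vectorized over parameter rectangles
## (u1,u2) x (v1,v2) and returns center, unit normal, exact area, the
## signed principal curvatures (k1 along u, k2 along v; positive when
## the surface bends away from the normal), and the two arc widths used
## by the self-term quadrature.

patch_sphere <- function(R, u1, u2, v1, v2) {
  ## u = colatitude theta, v = azimuth phi; normal radially outward
  area <- R^2 * (cos(u1) - cos(u2)) * (v2 - v1)
  thc <- acos(pmin(1, pmax(-1, (cos(u1) + cos(u2)) / 2)))  # band area centroid
  phc <- (v1 + v2) / 2
  st <- sin(thc)
  center <- cbind(R * st * cos(phc), R * st * sin(phc), R * cos(thc))
  list(center = center, normal = center / R, area = area,
       curv = cbind(rep(1 / R, length(u1)), rep(1 / R, length(u1))),
       widths = cbind(R * (u2 - u1), R * st * (v2 - v1)))
}

patch_cylinder <- function(Rc, u1, u2, v1, v2) {
  ## u = axial z, v = azimuth phi; normal +r (away from the axis)
  area <- Rc * (u2 - u1) * (v2 - v1)
  zc <- (u1 + u2) / 2
  phc <- (v1 + v2) / 2
  n <- cbind(cos(phc), sin(phc), rep(0, length(u1)))
  list(center = cbind(Rc * cos(phc), Rc * sin(phc), zc), normal = n,
       area = area,
       curv = cbind(rep(0, length(u1)), rep(1 / Rc, length(u1))),
       widths = cbind(u2 - u1, Rc * (v2 - v1)))
}

patch_annulus <- function(z0, nz, u1, u2, v1, v2) {
  ## u = radius r, v = azimuth phi; flat, normal (0, 0, nz)
  area <- 0.5 * (u2^2 - u1^2) * (v2 - v1)
  rc <- (2 / 3) * (u2^3 - u1^3) / (u2^2 - u1^2)   # sector area centroid radius
  phc <- (v1 + v2) / 2
  k <- length(u1)
  list(center = cbind(rc * cos(phc), rc * sin(phc), rep(z0, k)),
       normal = cbind(rep(0, k), rep(0, k), rep(nz, k)), area = area,
       curv = cbind(rep(0, k), rep(0, k)),
       widths = cbind(u2 - u1, rc * (v2 - v1)))
}

patch_torus <- function(Rt, rc, zc, u1, u2, v1, v2) {
  ## u = tube angle alpha, v = azimuth phi; profile point
  ## (r, z) = (Rt + rc cos a, zc + rc sin a); normal points toward the
  ## tube center (into the rounded membrane corner)
  arc <- Rt * (u2 - u1) + rc * (sin(u2) - sin(u1))
  area <- rc * (v2 - v1) * arc
  num <- Rt * (u2^2 - u1^2) / 2 +
    rc * ((u2 * sin(u2) + cos(u2)) - (u1 * sin(u1) + cos(u1)))
  ac <- num / arc                                  # area-centroid tube angle
  phc <- (v1 + v2) / 2
  rs <- Rt + rc * cos(ac)
  list(center = cbind(rs * cos(phc), rs * sin(phc), zc + rc * sin(ac)),
       normal = cbind(-cos(ac) * cos(phc), -cos(ac) * sin(phc), -sin(ac)),
       area = area,
       ## tube direction is concave w.r.t. the inward normal (k = -1/rc);
       ## azimuthal normal curvature is n_r / r_s with n_r = -cos(ac)
       curv = cbind(rep(-1 / rc, length(u1)), -cos(ac) / rs),
       widths = cbind(rc * (u2 - u1), rs * (v2 - v1)))
}

eval_patch <- function(surface, u1, u2, v1, v2) {
  switch(surface$type,
    sphere   = patch_sphere(surface$R, u1, u2, v1, v2),
    cylinder = patch_cylinder(surface$R, u1, u2, v1, v2),
    annulus  = patch_annulus(surface$z0, surface$nz, u1, u2, v1, v2),
    torus    = patch_torus(surface$Rt, surface$rc, surface$zc, u1, u2, v1, v2),
    stop_bem("parameter", "unknown surface type '%s'", surface$type))
}

## ---- mesh container --------------------------------------------------

new_bem_mesh <- function(center, normal, area, part, param, curv, widths,
                         surfaces, geometry, closed) {
  structure(list(
    center = center, normal = normal, area = as.numeric(area),
    part = part, param = param, curv = curv, widths = widths,
    surfaces = surfaces, geometry = geometry, closed = closed,
    nsign = 1,
    delta_eps = rep(NA_real_, length(area)),
    mean_eps = rep(NA_real_, length(area)),
    eps_ahead = NA_real_, eps_behind = NA_real_,
    orientation = "unassigned"
  ), class = "bem_mesh")
}

#' Number of tiles in a boundary mesh
#' @param mesh a `bem_mesh`.
#' @return Integer tile count.
#' @export
n_tiles <- function(mesh) length(mesh$area)

#' Total surface area of a boundary mesh
#' @param mesh a `bem_mesh`.
#' @return Sum of tile areas in square Angstrom.
#' @export
mesh_area <- function(mesh) sum(mesh$area)

#' @export
print.bem_mesh <- function(x, ...) {
  cat(sprintf("<bem_mesh> %s, %d tiles, area %.4g A^2, orientation: %s\n",
              x$geometry$type, n_tiles(x), mesh_area(x), x$orientation))
  invisible(x)
}

#' Tiles of a mesh as a data frame
#'
#' One row per tile with collocation point, unit normal, exact area and,
#' if [assign_dielectrics()] has been called, the permittivity jump
#' `delta_eps` and mean `mean_eps`.
#'
#' @param mesh a `bem_mesh`.
#' @return A data frame with columns cx, cy, cz, nx, ny, nz, area,
#'   delta_eps, mean_eps, part.
#' @export
as_tile_frame <- function(mesh) {
  data.frame(cx = mesh$center[, 1], cy = mesh$center[, 2],
             cz = mesh$center[, 3],
             nx = mesh$normal[, 1], ny = mesh$normal[, 2],
             nz = mesh$normal[, 3],
             area = mesh$area, delta_eps = mesh$delta_eps,
             mean_eps = mesh$mean_eps, part = mesh$part)
}

## ---- sphere ----------------------------------------------------------

#' Tile a sphere by uniform discretization of spherical coordinates
#'
#' The surface of a sphere of the given radius (centered at the origin)
#' is divided into `n_theta` uniform colatitude bands times `n_phi`
#' uniform azimuthal sectors. Tile areas are the exact spherical-patch
#' areas `R^2 (cos t1 - cos t2) dphi` (their sum telescopes to
#' `4 pi R^2` exactly); the collocation point of each tile is its area
#' centroid projected onto the sphere, and normals point radially
#' outward.
#'
#' @param radius sphere radius in Angstrom (> 0).
#' @param n_theta number of colatitude bands (>= 2).
#' @param n_phi number of azimuthal sectors (>= 3).
#' @return A `bem_mesh` with `n_theta * n_phi` tiles, closed, with
#'   outward normals ("ahead" side = exterior).
#' @export
tile_sphere <- function(radius, n_theta, n_phi) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop_bem("parameter", "radius must be a positive number, got %s",
             deparse(radius))
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  if (n_theta < 2L || n_phi < 3L)
    stop_bem("parameter",
             "insufficient subdivision: need n_theta >= 2 and n_phi >= 3")
  th <- seq(0, pi, length.out = n_theta + 1L)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)
  u1 <- rep(th[-(n_theta + 1L)], each = n_phi)
  u2 <- rep(th[-1L], each = n_phi)
  v1 <- rep(ph[-(n_phi + 1L)], times = n_theta)
  v2 <- rep(ph[-1L], times = n_theta)
  p <- patch_sphere(radius, u1, u2, v1, v2)
  new_bem_mesh(p$center, p$normal, p$area,
               part = rep("sphere", length(u1)),
               param = cbind(u1, u2, v1, v2), curv = p$curv,
               widths = p$widths,
               surfaces = list(sphere = list(type = "sphere", R = radius)),
               geometry = list(type = "sphere", radius = radius,
                               n_theta = n_theta, n_phi = n_phi),
               closed = TRUE)
}

## ---- channel ---------------------------------------------------------

## Band layout along the channel profile: fixed fractions of the total
## band budget go to the pore wall and the two rounded corners, the rest
## to the two membrane faces (geometrically graded coarser away from the
## pore). For the default 860-tile target this yields
## 20 azimuthal sectors x (9 wall + 2x4 corner + 2x13 face) bands = 860.
channel_layout <- function(n_tiles_target) {
  n_phi <- max(8L, as.integer(round(sqrt(n_tiles_target / 2.15))))
  bands <- max(7L, as.integer(round(n_tiles_target / n_phi)))
  n_corner <- max(1L, as.integer(round(0.09 * bands)))
  n_wall <- max(1L, as.integer(round(0.21 * bands)))
  rem <- bands - n_wall - 2L * n_corner
  n_face <- max(1L, rem %/% 2L)
  n_wall <- n_wall + (rem - 2L * n_face)   # absorb rounding leftover
  list(n_phi = n_phi, n_wall = n_wall, n_corner = n_corner, n_face = n_face)
}

#' Tile the water/membrane boundary of an axisymmetric channel
#'
#' The boundary of a cylindrical pore through a membrane slab, with
#' toroidal rounded corners at the pore mouths and flat annular membrane
#' faces, all axisymmetric about z with the membrane centered on the
#' mid-plane z = 0. Four surface parts are tiled: the pore wall
#' (cylinder of `pore_radius`, spanning `|z| <= membrane_width/2 -
#' corner_radius`), two quarter-torus corners, and two annular faces at
#' `z = +/- membrane_width/2` extending to `lateral_extent`, with radial
#' band widths graded geometrically coarser away from the pore. Normals
#' point from the water phase into the membrane.
#'
#' @param pore_radius pore radius in Angstrom (> 0).
#' @param membrane_width slab thickness in Angstrom
#'   (> `2 * corner_radius`).
#' @param corner_radius rounding radius of the pore mouths, Angstrom.
#' @param lateral_extent outer radius of the membrane faces, Angstrom
#'   (> `pore_radius + corner_radius`).
#' @param n_tiles_target requested tile count; the realized count is
#'   within 10 percent (exactly 860 for the default target).
#' @param face_grading geometric ratio between successive radial band
#'   widths on the membrane faces (1 = uniform).
#' @return A `bem_mesh` ("ahead" side = membrane interior).
#' @export
tile_channel <- function(pore_radius = 6.5, membrane_width = 30,
                         corner_radius = 5, lateral_extent = 40,
                         n_tiles_target = 860, face_grading = 1.15) {
  if (pore_radius <= 0)
    stop_bem("parameter", "pore_radius must be positive")
  if (membrane_width <= 2 * corner_radius)
    stop_bem("parameter",
             "corner radius too large: need membrane_width > 2*corner_radius")
  if (lateral_extent <= pore_radius + corner_radius)
    stop_bem("parameter",
             "lateral_extent must exceed pore_radius + corner_radius")
  lay <- channel_layout(n_tiles_target)
  hw <- membrane_width / 2
  Rt <- pore_radius + corner_radius     # torus center-circle radius
  zc <- hw - corner_radius              # |z| of the torus centers

  ph <- seq(0, 2 * pi, length.out = lay$n_phi + 1L)
  pv1 <- ph[-(lay$n_phi + 1L)]
  pv2 <- ph[-1L]

  surfaces <- list(
    wall = list(type = "cylinder", R = pore_radius),
    corner_top = list(type = "torus", Rt = Rt, rc = corner_radius, zc = zc),
    corner_bot = list(type = "torus", Rt = Rt, rc = corner_radius, zc = -zc),
    face_top = list(type = "annulus", z0 = hw, nz = -1),
    face_bot = list(type = "annulus", z0 = -hw, nz = 1)
  )

  ## band edges along the profile, per part
  zed <- seq(-zc, zc, length.out = lay$n_wall + 1L)
  a_top <- seq(pi / 2, pi, length.out = lay$n_corner + 1L)
  a_bot <- seq(pi, 3 * pi / 2, length.out = lay$n_corner + 1L)
  g <- face_grading
  L <- lateral_extent - Rt
  w1 <- if (abs(g - 1) < 1e-12) L / lay$n_face else
    L * (g - 1) / (g^lay$n_face - 1)
  red <- Rt + c(0, cumsum(w1 * g^(seq_len(lay$n_face) - 1L)))
  red[lay$n_face + 1L] <- lateral_extent

  bands <- list(
    wall = cbind(zed[-(lay$n_wall + 1L)], zed[-1L]),
    corner_top = cbind(a_top[-(lay$n_corner + 1L)], a_top[-1L]),
    corner_bot = cbind(a_bot[-(lay$n_corner + 1L)], a_bot[-1L]),
    face_top = cbind(red[-(lay$n_face + 1L)], red[-1L]),
    face_bot = cbind(red[-(lay$n_face + 1L)], red[-1L])
  )

  pieces <- lapply(names(bands), function(pt) {
    b <- bands[[pt]]
    nb <- nrow(b)
    u1 <- rep(b[, 1], each = lay$n_phi)
    u2 <- rep(b[, 2], each = lay$n_phi)
    v1 <- rep(pv1, times = nb)
    v2 <- rep(pv2, times = nb)
    p <- eval_patch(surfaces[[pt]], u1, u2, v1, v2)
    list(p = p, part = rep(pt, length(u1)), param = cbind(u1, u2, v1, v2))
  })
  center <- do.call(rbind, lapply(pieces, function(x) x$p$center))
  normal <- do.call(rbind, lapply(pieces, function(x) x$p$normal))
  area <- unlist(lapply(pieces, function(x) x$p$area))
  curv <- do.call(rbind, lapply(pieces, function(x) x$p$curv))
  widths <- do.call(rbind, lapply(pieces, function(x) x$p$widths))
  part <- unlist(lapply(pieces, function(x) x$part))
  param <- do.call(rbind, lapply(pieces, function(x) x$param))

  new_bem_mesh(center, normal, area, part, param, curv, widths, surfaces,
               geometry = list(type = "channel", pore_radius = pore_radius,
                               membrane_width = membrane_width,
                               corner_radius = corner_radius,
                               lateral_extent = lateral_extent,
                               n_phi = lay$n_phi, layout = lay),
               closed = FALSE)
}

## ---- dielectric assignment -------------------------------------------

#' Assign permittivities to the two sides of a boundary mesh
#'
#' Sets, on every tile, the permittivity jump
#' `delta_eps = eps_ahead - eps_behind` and the mean
#' `mean_eps = (eps_ahead + eps_behind)/2`, where "ahead" is the side
#' the tile normals point into (sphere meshes: the exterior; channel
#' meshes: the membrane interior).
#'
#' @param mesh a `bem_mesh`.
#' @param eps_ahead relative permittivity on the normal side (>= 1).
#' @param eps_behind relative permittivity on the opposite side (>= 1).
#' @return The mesh with `delta_eps`, `mean_eps` and the orientation
#'   label (`into_low_eps` or `into_high_eps`) filled in.
#' @export
assign_dielectrics <- function(mesh, eps_ahead, eps_behind) {
  if (!inherits(mesh, "bem_mesh"))
    stop_bem("parameter", "mesh must be a bem_mesh")
  if (eps_ahead < 1 || eps_behind < 1)
    stop_bem("parameter", "relative permittivities must be >= 1")
  n <- n_tiles(mesh)
  mesh$delta_eps <- rep(eps_ahead - eps_behind, n)
  mesh$mean_eps <- rep((eps_ahead + eps_behind) / 2, n)
  mesh$eps_ahead <- eps_ahead
  mesh$eps_behind <- eps_behind
  mesh$orientation <- if (eps_ahead <= eps_behind) "into_low_eps"
                      else "into_high_eps"
  mesh
}

#' Flip the orientation convention of a mesh
#'
#' Negates every tile normal, swaps the ahead/behind permittivities
#' (hence negates `delta_eps`) and negates the signed principal
#' curvatures, which are defined relative to the normal. All solver
#' results are invariant under this flip.
#'
#' @param mesh a `bem_mesh`.
#' @return The flipped mesh.
#' @export
flip_orientation <- function(mesh) {
  mesh$normal <- -mesh$normal
  mesh$curv <- -mesh$curv
  mesh$nsign <- -mesh$nsign
  if (!is.na(mesh$eps_ahead)) {
    tmp <- mesh$eps_ahead
    mesh <- assign_dielectrics(mesh, mesh$eps_behind, tmp)
  }
  mesh
}

## ---- region predicates (used by the Gauss audit and scenarios) -------

## TRUE for points strictly inside the region the mesh normals face away
## from or toward; the callers only need "enclosed region" membership.
## sphere: enclosed = interior ball. channel: enclosed = membrane slab
## (the region bounded by the tiled water/membrane interface).
region_enclosed <- function(geometry, pts) {
  pts <- as_points(pts)
  if (geometry$type == "sphere") {
    row_norms(pts) < geometry$radius
  } else if (geometry$type == "channel") {
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    z <- abs(pts[, 3])
    hw <- geometry$membrane_width / 2
    rc <- geometry$corner_radius
    Rt <- geometry$pore_radius + rc
    inside <- z < hw & r > geometry$pore_radius & r < geometry$lateral_extent
    ## carve out the rounded corner (water side of the torus)
    incorner <- inside & r < Rt & z > hw - rc
    d2 <- (r[incorner] - Rt)^2 + (z[incorner] - (hw - rc))^2
    inside[incorner] <- d2 > rc^2
    inside
  } else {
    stop_bem("parameter", "no enclosed-region definition for geometry '%s'",
             geometry$type)
  }
}

## permittivity of the enclosed phase, robust to orientation flips:
## probe a short step along the normal of a reference tile
enclosed_eps <- function(mesh) {
  if (is.na(mesh$eps_ahead))
    stop_bem("config", "mesh has no dielectric assignment")
  i <- which.max(mesh$area)
  probe <- mesh$center[i, ] + 0.25 * mesh$normal[i, ]
  if (region_enclosed(mesh$geometry, probe))
    c(inside = mesh$eps_ahead, outside = mesh$eps_behind)
  else
    c(inside = mesh$eps_behind, outside = mesh$eps_ahead)
}

## ---- sub-tile quadrature ---------------------------------------------

## Split tile i of a mesh into a k x k grid of parameter-space
## sub-patches of the same analytic surface; returns exact sub-areas and
## projected centroids. Used as the refinement quadrature and as the
## independent oracle for the one-point kernel in the tests.
subdivide_tile <- function(mesh, i, k = 4L) {
  pr <- mesh$param[i, ]
  us <- seq(pr[1], pr[2], length.out = k + 1L)
  vs <- seq(pr[3], pr[4], length.out = k + 1L)
  u1 <- rep(us[-(k + 1L)], each = k)
  u2 <- rep(us[-1L], each = k)
  v1 <- rep(vs[-(k + 1L)], times = k)
  v2 <- rep(vs[-1L], times = k)
  p <- eval_patch(mesh$surfaces[[mesh$part[i]]], u1, u2, v1, v2)
  p$normal <- mesh$nsign * p$normal       # honour orientation flips
  p$curv <- mesh$nsign * p$curv
  p
}

## ---- charges ---------------------------------------------------------

#' Construct a set of source point charges
#'
#' @param q charges in elementary-charge units (vector).
#' @param pos positions, an `n x 3` matrix (or 3-vector for n = 1), in
#'   Angstrom.
#' @param eps relative permittivity of the phase each charge sits in
#'   (recycled).
#' @return A `charge_set` data frame with columns q, x, y, z, eps.
#' @export
charge_set <- function(q = numeric(), pos = matrix(0, 0, 3), eps = numeric()) {
  pos <- as_points(pos, "charge positions")
  if (length(q) != nrow(pos))
    stop_bem("parameter", "q has %d entries but pos has %d rows",
             length(q), nrow(pos))
  eps <- rep_len(as.numeric(eps), length(q))
  if (length(q) && any(eps < 1))
    stop_bem("parameter", "eps at each charge must be >= 1")
  structure(data.frame(q = as.numeric(q), x = pos[, 1], y = pos[, 2],
                       z = pos[, 3], eps = eps),
            class = c("charge_set", "data.frame"))
}

#' Concatenate charge sets
#' @param ... `charge_set` objects.
#' @return A single `charge_set`.
#' @export
combine_charges <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, class = c("charge_set", "data.frame"))
}

charge_positions <- function(charges) {
  cbind(charges$x, charges$y, charges$z)
}

## ---- exporters -------------------------------------------------------

#' Write a mesh to CSV (one row per tile)
#'
#' Columns: cx, cy, cz, nx, ny, nz, area, delta_eps, mean_eps. Floats
#' are written with 17 significant digits so that identical meshes
#' produce byte-identical files.
#'
#' @param mesh a `bem_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_csv <- function(mesh, path) {
  df <- as_tile_frame(mesh)[, c("cx", "cy", "cz", "nx", "ny", "nz",
                                "area", "delta_eps", "mean_eps")]
  write_csv17(df, path)
}

#' Export tile quads as a Wavefront OBJ file (visualization aid)
#'
#' Each tile is written as the quad of its four parameter-space corners
#' projected on the analytic surface. Approximate: for inspection only.
#'
#' @param mesh a `bem_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  n <- n_tiles(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# iccbem tile quads", con)
  for (i in seq_len(n)) {
    pr <- mesh$param[i, ]
    s <- mesh$surfaces[[mesh$part[i]]]
    corners <- rbind(
      surf_point(s, pr[1], pr[3]), surf_point(s, pr[2], pr[3]),
      surf_point(s, pr[2], pr[4]), surf_point(s, pr[1], pr[4]))
    writeLines(sprintf("v %.8g %.8g %.8g", corners[, 1], corners[, 2],
                       corners[, 3]), con)
  }
  idx <- matrix(seq_len(4L * n), nrow = 4L)
  writeLines(sprintf("f %d %d %d %d", idx[1, ], idx[2, ], idx[3, ], idx[4, ]),
             con)
  invisible(path)
}

surf_point <- function(s, u, v) {
  switch(s$type,
    sphere = s$R * c(sin(u) * cos(v), sin(u) * sin(v), cos(u)),
    cylinder = c(s$R * cos(v), s$R * sin(v), u),
    annulus = c(u * cos(v), u * sin(v), s$z0),
    torus = {
      r <- s$Rt + s$rc * cos(u)
      c(r * cos(v), r * sin(v), s$zc + s$rc * sin(u))
    })
}

write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
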