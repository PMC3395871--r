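## Parameterized benchmark scenarios: the dielectric sphere (high-eps
## sphere in a low-eps medium with an off-center elementary charge) and
## the toy ion channel (water-filled cylindrical pore through a low-eps
## membrane slab), optionally decorated with rings of membrane dipoles
## and/or a mobile cation.

#' Dielectric-sphere benchmark scenario
#'
#' A water-like sphere (radius 5 A, eps_in = 80) embedded in a
#' low-permittivity medium (eps_out = 2) with one +1 e point charge
#' 4 A off-center on the +z axis (inside the sphere, in the eps = 80
#' phase). The returned [sphere_problem()] feeds the analytic series
#' oracle with identical parameters.
#'
#' @param n_theta,n_phi sphere discretization (see [tile_sphere()]).
#' @param radius,eps_in,eps_out,charge,charge_offset scenario
#'   parameters; defaults are the benchmark values.
#' @return A list with `mesh`, `charges`, and `problem`.
#' @export
make_sphere_scenario <- function(n_theta = 32, n_phi = 32, radius = 5,
                                 eps_in = 80, eps_out = 2, charge = 1,
                                 charge_offset = 4) {
  mesh <- tile_sphere(radius, n_theta, n_phi)
  mesh <- assign_dielectrics(mesh, eps_ahead = eps_out, eps_behind = eps_in)
  charges <- charge_set(charge, c(0, 0, charge_offset), eps_in)
  list(mesh = mesh, charges = charges,
       problem = sphere_problem(radius, eps_in, eps_out, charge,
                                charge_offset))
}

#' Specify rings of membrane dipoles
#'
#' Two (or more) rings of radially oriented dipoles placed inside the
#' membrane to mimic an ion channel's charged groups: the negative
#' partial charge of each dipole sits `radial_depth_neg` Angstrom from
#' the water/membrane boundary (i.e. at cylindrical radius
#' `pore_radius + radial_depth_neg`), the positive charge
#' `axial_extra_pos` Angstrom further inside the membrane (radially
#' deeper). Individual dipoles can be switched off to break the
#' azimuthal symmetry.
#'
#' @param n_dipoles dipoles per ring (>= 1), equally spaced in azimuth.
#' @param z_positions ring planes, Angstrom.
#' @param radial_depth_neg negative-charge depth from the boundary, A.
#' @param axial_extra_pos additional radial depth of the positive
#'   charge, A.
#' @param dipole_charge partial-charge magnitude, e.
#' @param disabled_indices zero-based ring positions switched off (in
#'   every ring).
#' @return A `dipole_ring_spec` list.
#' @export
dipole_ring_spec <- function(n_dipoles = 20, z_positions = c(-3, 3),
                             radial_depth_neg = 2, axial_extra_pos = 2,
                             dipole_charge = 1,
                             disabled_indices = integer()) {
  n_dipoles <- as.integer(n_dipoles)
  if (n_dipoles < 1L) stop_bem("parameter", "n_dipoles must be >= 1")
  disabled_indices <- as.integer(disabled_indices)
  if (length(disabled_indices) &&
      (min(disabled_indices) < 0L || max(disabled_indices) >= n_dipoles))
    stop_bem("parameter", "disabled_indices must lie in [0, n_dipoles)")
  structure(list(n_dipoles = n_dipoles, z_positions = z_positions,
                 radial_depth_neg = radial_depth_neg,
                 axial_extra_pos = axial_extra_pos,
                 dipole_charge = dipole_charge,
                 disabled_indices = disabled_indices),
            class = "dipole_ring_spec")
}

#' Toy ion-channel benchmark scenario
#'
#' Two water baths (eps_W = 80) connected by a cylindrical pore (6.5 A
#' radius) through a membrane slab (eps_M = 6) 30 A wide, the boundary
#' tiled by [tile_channel()]. Optionally adds a mobile cation (+1 e, in
#' the water phase) and/or rings of membrane dipoles per
#' [dipole_ring_spec()].
#'
#' @param rings a [dipole_ring_spec()], or `NULL` for no dipoles.
#' @param ion_position 3-vector (Angstrom), or `NULL` for no ion; must
#'   lie in a water region.
#' @param n_tiles_target requested tile count (realized 860 for the
#'   default).
#' @param ion_charge ion charge, e.
#' @param eps_water,eps_membrane phase permittivities.
#' @param pore_radius,membrane_width,corner_radius,lateral_extent
#'   geometry parameters, Angstrom.
#' @return A list with `mesh` and `charges`.
#' @export
make_channel_scenario <- function(rings = NULL, ion_position = NULL,
                                  n_tiles_target = 860, ion_charge = 1,
                                  eps_water = 80, eps_membrane = 6,
                                  pore_radius = 6.5, membrane_width = 30,
                                  corner_radius = 5, lateral_extent = 40) {
  mesh <- tile_channel(pore_radius, membrane_width, corner_radius,
                       lateral_extent, n_tiles_target)
  mesh <- assign_dielectrics(mesh, eps_ahead = eps_membrane,
                             eps_behind = eps_water)
  charges <- charge_set()
  if (!is.null(ion_position)) {
    ion_position <- as_points(ion_position, "ion_position")
    if (any(region_enclosed(mesh$geometry, ion_position)))
      stop_bem("config", "ion placed inside the membrane dielectric")
    charges <- combine_charges(charges,
                               charge_set(ion_charge, ion_position, eps_water))
  }
  if (!is.null(rings)) {
    if (!inherits(rings, "dipole_ring_spec"))
      stop_bem("parameter", "rings must be a dipole_ring_spec")
    keep <- setdiff(seq_len(rings$n_dipoles) - 1L, rings$disabled_indices)
    if (length(keep)) {
      phi <- 2 * pi * keep / rings$n_dipoles
      r_neg <- pore_radius + rings$radial_depth_neg
      r_pos <- r_neg + rings$axial_extra_pos
      for (zr in rings$z_positions) {
        pn <- cbind(r_neg * cos(phi), r_neg * sin(phi), zr)
        pp <- cbind(r_pos * cos(phi), r_pos * sin(phi), zr)
        if (!all(region_enclosed(mesh$geometry, rbind(pn, pp))))
          stop_bem("config", "dipole charges must lie inside the membrane")
        charges <- combine_charges(
          charges,
          charge_set(rep(-rings$dipole_charge, length(phi)), pn, eps_membrane),
          charge_set(rep(+rings$dipole_charge, length(phi)), pp, eps_membrane))
      }
    }
  }
  list(mesh = mesh, charges = charges)
}

#' Sweep a cation along trajectories parallel to the channel axis
#'
#' For every (radial offset, z) position of a +1 e cation, solves the
#' boundary problem and records the reaction potential felt by the ion
#' and the Gauss's-law audit (the ion is outside the dielectric
#' boundary, so the total induced charge should be close to zero).
#' The geometric coupling matrix is factored exactly once and reused
#' for every position (the ICC reuse pattern).
#'
#' @param radial_offsets cylindrical radii of the trajectories, A.
#' @param z_values axial ion positions, A (all must be in water).
#' @param n_tiles_target channel tile budget.
#' @param ion_charge ion charge, e.
#' @param ... further arguments to [make_channel_scenario()].
#' @return A data frame with columns offset, z,
#'   reaction_potential_reduced, reaction_potential_V, total_induced_e,
#'   gauss_error_pct_e.
#' @export
trajectory_sweep <- function(radial_offsets = 0,
                             z_values = seq(-40, 0, by = 0.5),
                             n_tiles_target = 860, ion_charge = 1, ...) {
  scen <- make_channel_scenario(rings = NULL, ion_position = NULL,
                                n_tiles_target = n_tiles_target, ...)
  mesh <- scen$mesh
  eps_water <- mesh$eps_behind
  fac <- icc_factor(build_system(mesh))
  rows <- vector("list", length(radial_offsets) * length(z_values))
  k <- 0L
  for (off in radial_offsets) {
    for (z in z_values) {
      pos <- c(off, 0, z)
      if (region_enclosed(mesh$geometry, pos))
        stop_bem("config",
                 "trajectory point (%.3g, 0, %.3g) lies inside the membrane",
                 off, z)
      ch <- charge_set(ion_charge, pos, eps_water)
      sol <- solve_icc(fac, build_source(mesh, ch))
      phi <- reaction_potential_at(pos, sol, mesh)$potential_reduced
      g <- gauss_check(sol, mesh, ch)
      k <- k + 1L
      rows[[k]] <- data.frame(offset = off, z = z,
                              reaction_potential_reduced = phi,
                              reaction_potential_V = phi * REDUCED_TO_VOLTS,
                              total_induced_e = g$total_induced_e,
                              gauss_error_pct_e = g$error_pct_of_e)
    }
  }
  do.call(rbind, rows)
}
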