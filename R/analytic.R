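## Closed-form reference solutions used as test oracles.
##
## Point charge q at distance a < R from the center of a dielectric
## sphere (eps_in inside, eps_out outside), charge on the +z axis.
## Writing the total potential in reduced units (e / (4 pi eps0 A)) as
## the screened Coulomb term q/(eps_in |r - r_q|) plus the
## induced-charge (reaction) part, the reaction part is the classical
## Legendre series with coefficients
##   c_l = q (l+1) (eps_in - eps_out) / (eps_in (l eps_in + (l+1) eps_out))
##   Phi_R(r, mu) = sum_l c_l (a r / R^2)^l P_l(mu) / R      (r <  R)
##   Phi_R(r, mu) = sum_l c_l (a / r)^l  P_l(mu) / r         (r >= R)
## where mu = cos(angle from the charge axis). For a = 0 only l = 0
## survives and the interior reaction potential is the constant
## (q/R)(1/eps_out - 1/eps_in).

#' Describe a point-charge-in-dielectric-sphere reference problem
#'
#' @param radius sphere radius, Angstrom.
#' @param eps_in relative permittivity inside the sphere.
#' @param eps_out relative permittivity outside.
#' @param charge source charge in e.
#' @param charge_offset distance of the charge from the center (on the
#'   +z axis by convention), `0 <= charge_offset < radius`.
#' @return A `sphere_problem` list.
#' @export
sphere_problem <- function(radius, eps_in, eps_out, charge, charge_offset) {
  if (radius <= 0) stop_bem("parameter", "radius must be positive")
  if (charge_offset < 0 || charge_offset >= radius)
    stop_bem("parameter", "need 0 <= charge_offset < radius")
  structure(list(radius = radius, eps_in = eps_in, eps_out = eps_out,
                 charge = charge, charge_offset = charge_offset),
            class = "sphere_problem")
}

sphere_series_eval <- function(problem, pts, l_max) {
  R <- problem$radius
  a <- problem$charge_offset
  e1 <- problem$eps_in
  e2 <- problem$eps_out
  q <- problem$charge
  r <- row_norms(pts)
  mu <- ifelse(r > 0, pts[, 3] / r, 1)
  inside <- r < R
  ## per-point geometric ratio and prefactor
  t <- ifelse(inside, a * r / R^2, ifelse(r > 0, a / r, 0))
  pref <- ifelse(inside, 1 / R, 1 / pmax(r, .Machine$double.xmin))
  val <- numeric(length(r))
  Pm1 <- rep(1, length(r))      # P_0
  P0 <- mu                      # P_1
  tl <- rep(1, length(r))       # t^l
  for (l in 0:l_max) {
    cl <- q * (l + 1) * (e1 - e2) / (e1 * (l * e1 + (l + 1) * e2))
    Pl <- if (l == 0) Pm1 else if (l == 1) P0 else {
      Pn <- ((2 * l - 1) * mu * P0 - (l - 1) * Pm1) / l
      Pm1 <- P0; P0 <- Pn
      Pn
    }
    val <- val + cl * tl * Pl
    tl <- tl * t
  }
  val * pref
}

#' Reaction potential of a point charge in a dielectric sphere (series)
#'
#' Evaluates the induced-charge part of the potential from the
#' truncated Legendre image series, in reduced units
#' (e/(4 pi eps0 Angstrom)). For points with `|r| >= 0.95 R` (where
#' convergence is slowest) the series is recomputed at `2 * l_max` and
#' the two truncations are required to agree to 1e-8; a disagreement
#' raises a numeric error rather than returning an unconverged value.
#'
#' @param problem a [sphere_problem()].
#' @param points evaluation points, `n x 3` matrix in Angstrom; must
#'   not coincide with the charge location.
#' @param l_max truncation order (>= 1).
#' @param check_convergence logical; perform the doubling check.
#' @return Numeric vector of reaction-potential values (reduced units).
#' @export
sphere_reaction_potential <- function(problem, points, l_max = 100,
                                      check_convergence = TRUE) {
  pts <- as_points(points)
  if (l_max < 1) stop_bem("parameter", "l_max must be >= 1")
  dq <- pts
  dq[, 3] <- dq[, 3] - problem$charge_offset
  if (any(row_norms(dq) < 1e-9))
    stop_bem("domain", "evaluation point coincides with the source charge")
  val <- sphere_series_eval(problem, pts, l_max)
  if (isTRUE(check_convergence)) {
    slow <- row_norms(pts) >= 0.95 * problem$radius
    if (any(slow)) {
      v2 <- sphere_series_eval(problem, pts[slow, , drop = FALSE], 2 * l_max)
      err <- max(abs(v2 - val[slow]))
      if (err > 1e-8 * max(1, max(abs(v2))))
        stop_bem("numeric",
                 "series not converged at l_max = %d (doubling check: %.3g)",
                 l_max, err)
    }
  }
  val
}

#' Expected total induced charge from Gauss's law
#'
#' For a closed boundary with permittivity `eps_in` on the enclosed side
#' and `eps_out` outside, the total induced charge under the
#' `q/eps(r_k)` source-potential convention is
#' `sum(q_enclosed) * (1/eps_out - 1/eps_in)`; charges outside the
#' boundary contribute nothing.
#'
#' @param charges a [charge_set()].
#' @param inside logical vector (recycled) classifying each charge as
#'   enclosed by the boundary or not. `NA` (unclassifiable, e.g. a
#'   charge lying on the boundary) is an error.
#' @param eps_in relative permittivity of the enclosed phase.
#' @param eps_out relative permittivity of the exterior phase.
#' @return Expected total induced charge in e.
#' @export
gauss_expected_charge <- function(charges, inside, eps_in, eps_out) {
  inside <- rep_len(inside, nrow(charges))
  if (anyNA(inside))
    stop_bem("domain", "charge on the boundary cannot be classified")
  sum(charges$q[inside]) * (1 / eps_out - 1 / eps_in)
}
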