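## Discretized integral equation for the induced surface-charge density
## h on a dielectric boundary. Collocation at tile centroids turns the
## equation into A h = b with
##   A[i,j] = delta_ij + (deps_i / (4 pi meps_i)) n_i.(r_i - r_j)/|r_i - r_j|^3 a_j
##   b[i]   = -(deps_i / (4 pi meps_i)) n_i . sum_k (q_k/eps_k) (r_i - r_k)/|r_i - r_k|^3
## where deps/meps are the jump and mean of the permittivity across the
## boundary along the tile normal. Units: h in e/A^2, b likewise, A
## dimensionless.
##
## The diagonal carries the self-interaction of a curved tile. Three
## treatments are provided (see build_system): for closed surfaces the
## default is the solid-angle sum rule, which makes the discrete
## operator exact on constant densities. This matters because at high
## dielectric contrast the uniform mode of the system has eigenvalue
## 2 eps_low/(eps_low + eps_high) (~0.05 for 80/2), so any quadrature
## error in the kernel sums is amplified ~20x in the total induced
## charge; the sum rule removes that error channel entirely.

## leading-order principal-curvature self term, integrated exactly over
## the w1 x w2 parameter rectangle:
## F(wa, wb) = int int u^2/(u^2+v^2)^(3/2) du dv = 2 wb asinh(wa/wb),
## I_self = (k1 F(w1,w2) + k2 F(w2,w1)) / 2  (dimensionless).
self_term_curvature <- function(curv, widths) {
  w1 <- pmax(widths[, 1], 1e-300)
  w2 <- pmax(widths[, 2], 1e-300)
  Fa <- 2 * w2 * asinh(w1 / w2)
  Fb <- 2 * w1 * asinh(w2 / w1)
  0.5 * (curv[, 1] * Fa + curv[, 2] * Fb)
}

## signed solid angle a closed mesh subtends at interior points:
## +2 pi for outward normals, -2 pi for inward (sign from the
## divergence-theorem volume estimate sum a_i n_i . r_i / 3)
closed_solid_angle <- function(mesh) {
  v3 <- sum(mesh$area * rowSums(mesh$normal * mesh$center))
  2 * pi * sign(v3)
}

#' Assemble the geometric coupling matrix of the boundary
#'
#' Builds the dense N x N collocation matrix whose off-diagonal entries
#' couple the induced charge on tile j to the normal field at tile i;
#' the matrix depends only on the geometry and the dielectric contrast,
#' not on the source charges, so it can be factored once and reused.
#'
#' The diagonal self-interaction term is controlled by `self_term`:
#' \describe{
#'   \item{auto}{(default) `"sumrule"` for closed meshes, `"curvature"`
#'     for open ones.}
#'   \item{sumrule}{closed surfaces only: the self term of tile j is
#'     fixed by the exact solid-angle identity so that the
#'     area-weighted kernel column sums equal 2 pi; the discretization
#'     is then exact on constant densities and the Gauss's-law error is
#'     decoupled from the kernel quadrature.}
#'   \item{curvature}{analytic leading-order curved-tile
#'     self-interaction from the tile's principal curvatures.}
#'   \item{flat}{flat-tile approximation, diagonal exactly 1.}
#' }
#'
#' @param mesh a `bem_mesh` with dielectrics assigned.
#' @param self_term one of `"auto"`, `"sumrule"`, `"curvature"`,
#'   `"flat"` (see Details).
#' @param adjacent_refine if `TRUE`, entries for tile pairs closer than
#'   `near_factor` times the mean of their widths are recomputed with
#'   `n_sub^2`-point sub-tile quadrature over the source tile.
#' @param n_sub sub-division count per direction for the refinement.
#' @param near_factor proximity multiplier selecting refined pairs.
#' @return A `bem_system` holding the matrix and the mesh.
#' @export
build_system <- function(mesh, self_term = c("auto", "sumrule", "curvature",
                                             "flat"),
                         adjacent_refine = FALSE, n_sub = 4L,
                         near_factor = 1.5) {
  self_term <- match.arg(self_term)
  if (!inherits(mesh, "bem_mesh"))
    stop_bem("parameter", "mesh must be a bem_mesh")
  if (anyNA(mesh$delta_eps))
    stop_bem("config",
             "mesh has no dielectric assignment; call assign_dielectrics()")
  n <- n_tiles(mesh)
  if (n < 2L) stop_bem("parameter", "mesh must have at least 2 tiles")
  if (self_term == "auto")
    self_term <- if (mesh$closed) "sumrule" else "curvature"
  if (self_term == "sumrule" && !mesh$closed)
    stop_bem("parameter", "sum-rule self term requires a closed mesh")

  cx <- mesh$center[, 1]; cy <- mesh$center[, 2]; cz <- mesh$center[, 3]
  dx <- outer(cx, cx, "-"); dy <- outer(cy, cy, "-"); dz <- outer(cz, cz, "-")
  r2 <- dx * dx + dy * dy + dz * dz
  diag(r2) <- Inf
  if (any(r2 < 1e-18)) {
    ij <- which(r2 < 1e-18, arr.ind = TRUE)[1, ]
    stop_bem("assembly", "coincident tile centers: tiles %d and %d",
             ij[1], ij[2])
  }
  ## n_i . (r_i - r_j): column-major recycling applies normal of row i
  ndot <- dx * mesh$normal[, 1] + dy * mesh$normal[, 2] + dz * mesh$normal[, 3]
  Kw <- ndot / (r2 * sqrt(r2)) * rep(mesh$area, each = n)  # kernel * a_j
  diag(Kw) <- 0

  if (isTRUE(adjacent_refine)) {
    w <- pmax(mesh$widths[, 1], mesh$widths[, 2])
    for (j in seq_len(n)) {
      near <- which(r2[, j] < (near_factor * (w + w[j]) / 2)^2)
      if (!length(near)) next
      sub <- subdivide_tile(mesh, j, n_sub)
      for (i in near) {
        d <- cbind(cx[i] - sub$center[, 1], cy[i] - sub$center[, 2],
                   cz[i] - sub$center[, 3])
        rr <- row_norms(d)
        Kw[i, j] <- sum((d %*% mesh$normal[i, ]) / rr^3 * sub$area)
      }
    }
  }

  i_self <- switch(self_term,
    flat = numeric(n),
    curvature = self_term_curvature(mesh$curv, mesh$widths),
    sumrule = closed_solid_angle(mesh) - colSums(Kw * mesh$area) / mesh$area)

  coef <- mesh$delta_eps / (4 * pi * mesh$mean_eps)
  A <- coef * Kw
  diag(A) <- 1 + coef * i_self

  structure(list(A = A, mesh = mesh, self_term = self_term),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("<bem_system> N = %d, self_term = %s\n",
              nrow(x$A), x$self_term))
  invisible(x)
}

#' Build the source vector from a set of point charges
#'
#' Evaluates the (dielectric-scaled) normal field of the source charges
#' at every tile centroid; this is the right-hand side of the
#' discretized boundary integral equation and is linear in the charges.
#' For tiles lying close to a charge (within `near_factor` times the
#' tile width), the point evaluation is replaced by the tile average of
#' the normal field over an `n_sub^2` sub-tile quadrature, which keeps
#' the discrete surface flux (and hence the Gauss audit) accurate when
#' sources approach the boundary.
#'
#' @param mesh a `bem_mesh` with dielectrics assigned.
#' @param charges a [charge_set()].
#' @param min_distance minimum allowed charge-to-collocation-point
#'   distance in Angstrom; closer charges raise a proximity error
#'   because the quadrature silently degrades.
#' @param refine_near logical; apply the near-charge tile averaging.
#' @param n_sub sub-division count per direction.
#' @param near_factor proximity multiplier selecting refined tiles.
#' @return Numeric vector of length `n_tiles(mesh)` (units e/A^2).
#' @export
build_source <- function(mesh, charges, min_distance = 0.1,
                         refine_near = TRUE, n_sub = 8L, near_factor = 4) {
  if (anyNA(mesh$delta_eps))
    stop_bem("config",
             "mesh has no dielectric assignment; call assign_dielectrics()")
  n <- n_tiles(mesh)
  if (!nrow(charges)) return(numeric(n))
  pos <- charge_positions(charges)
  dx <- outer(mesh$center[, 1], pos[, 1], "-")
  dy <- outer(mesh$center[, 2], pos[, 2], "-")
  dz <- outer(mesh$center[, 3], pos[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  if (any(r2 < min_distance^2)) {
    ik <- which(r2 < min_distance^2, arr.ind = TRUE)[1, ]
    stop_bem("proximity",
             "charge %d is %.3g A from tile %d (minimum %.3g A)",
             ik[2], sqrt(r2[ik[1], ik[2]]), ik[1], min_distance)
  }
  ndot <- dx * mesh$normal[, 1] + dy * mesh$normal[, 2] + dz * mesh$normal[, 3]
  qe <- charges$q / charges$eps
  fld <- (ndot / (r2 * sqrt(r2)))             # n_i.(r_i-r_k)/r^3 per charge

  if (isTRUE(refine_near)) {
    w <- pmax(mesh$widths[, 1], mesh$widths[, 2])
    near <- which(r2 < (near_factor * w)^2, arr.ind = TRUE)
    subs <- list()
    for (m in seq_len(nrow(near))) {
      i <- near[m, 1]; k <- near[m, 2]
      key <- as.character(i)
      if (is.null(subs[[key]])) subs[[key]] <- subdivide_tile(mesh, i, n_sub)
      sub <- subs[[key]]
      d <- cbind(sub$center[, 1] - pos[k, 1], sub$center[, 2] - pos[k, 2],
                 sub$center[, 3] - pos[k, 3])
      rr <- row_norms(d)
      fld[i, k] <- sum(rowSums(sub$normal * d) / rr^3 * sub$area) /
        mesh$area[i]
    }
  }
  coef <- mesh$delta_eps / (4 * pi * mesh$mean_eps)
  as.numeric(-coef * (fld %*% qe))
}

## ---- solution container ----------------------------------------------

new_solution <- function(h, mesh, method, iterations = 0L,
                         final_update = NA_real_, cond = NA_real_) {
  structure(list(h = as.numeric(h), method = method,
                 iterations = as.integer(iterations),
                 final_update = final_update,
                 total_induced_e = sum(h * mesh$area),
                 condition_estimate = cond),
            class = "induced_solution")
}

#' @export
print.induced_solution <- function(x, ...) {
  cat(sprintf(
    "<induced_solution> %s, N = %d, iterations = %d, total induced = %.6g e\n",
    x$method, length(x$h), x$iterations, x$total_induced_e))
  invisible(x)
}

## ---- ICC: direct solution --------------------------------------------

#' Factor the coupling matrix for reuse across many source vectors
#'
#' Computes the explicit inverse of the coupling matrix (the matrix
#' depends only on geometry, so in a particle simulation it is factored
#' once and each new charge configuration costs one matrix-vector
#' product). Also records a reciprocal-condition estimate.
#'
#' @param system a `bem_system` from [build_system()].
#' @return An `icc_factor` object.
#' @export
icc_factor <- function(system) {
  rc <- rcond(system$A)
  if (!is.finite(rc) || rc < 1e-14)
    stop_bem("numeric",
             "coupling matrix is singular or near-singular (rcond = %.3g)",
             rc, data = list(rcond = rc))
  Ainv <- solve(system$A)
  .bem_state$factorizations <- .bem_state$factorizations + 1L
  structure(list(Ainv = Ainv, mesh = system$mesh,
                 condition_estimate = 1 / rc),
            class = "icc_factor")
}

#' Solve for the induced charges by the direct (ICC) method
#'
#' @param system a `bem_system` or a pre-computed [icc_factor()] (the
#'   reuse pattern: factor once, apply to many source vectors).
#' @param source source vector from [build_source()].
#' @return An `induced_solution` with `method = "ICC"`,
#'   `iterations = 0`, and the total induced charge (Gauss audit input)
#'   always filled in.
#' @export
solve_icc <- function(system, source) {
  fac <- if (inherits(system, "icc_factor")) system else icc_factor(system)
  if (length(source) != nrow(fac$Ainv))
    stop_bem("parameter", "source length %d does not match system size %d",
             length(source), nrow(fac$Ainv))
  h <- as.numeric(fac$Ainv %*% source)
  new_solution(h, fac$mesh, "ICC", cond = fac$condition_estimate)
}

## ---- ITER: Jacobi-style refinement -----------------------------------

#' Solve for the induced charges by iterative refinement (ITER)
#'
#' Starts from the direct source-induced charge (h = b, no mutual
#' interaction) and repeatedly re-evaluates the charge induced on each
#' tile by the sources plus all other tiles' current induced charges:
#' `h^(m+1) = b - (A - I) h^m` (a full Jacobi sweep). Iteration stops
#' when the relative update on every tile falls below `delta_stop`;
#' tiles whose current density is below `floor` are excluded from the
#' criterion (the relative update is undefined at zero).
#'
#' @param mesh a `bem_mesh` with dielectrics assigned.
#' @param source source vector from [build_source()].
#' @param delta_stop per-tile relative-update stopping threshold.
#' @param max_iter maximum number of sweeps.
#' @param system optional pre-built `bem_system` (avoids re-assembly).
#' @param floor densities below this magnitude (e/A^2) are excluded
#'   from the relative-update maximum.
#' @return An `induced_solution` with `method = "ITER"`, the sweep
#'   count, and the last relative update.
#' @export
solve_iter <- function(mesh, source, delta_stop = 1e-4, max_iter = 500L,
                       system = NULL, floor = 1e-15) {
  if (delta_stop <= 0) stop_bem("parameter", "delta_stop must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop_bem("parameter", "max_iter must be >= 1")
  if (is.null(system)) system <- build_system(mesh)
  K <- system$A
  diag(K) <- diag(K) - 1
  b <- source
  h <- b
  upd <- NA_real_
  for (m in seq_len(max_iter)) {
    hn <- b - as.numeric(K %*% h)
    denom_ok <- abs(h) >= floor
    if (!any(denom_ok)) {                 # zero fixed point (e.g. b = 0)
      return(new_solution(hn, system$mesh, "ITER", iterations = m,
                          final_update = 0))
    }
    upd <- max(abs(hn - h)[denom_ok] / abs(h)[denom_ok])
    h <- hn
    if (upd < delta_stop)
      return(new_solution(h, system$mesh, "ITER", iterations = m,
                          final_update = upd))
  }
  stop_bem("convergence",
           "ITER did not converge in %d sweeps (last relative update %.3g)",
           max_iter, upd,
           data = list(final_update = upd, iterations = max_iter))
}

## ---- diagnostics ------------------------------------------------------

#' Solver diagnostics as a plain list (JSON-ready)
#'
#' @param solution an `induced_solution`.
#' @param mesh the mesh it was solved on.
#' @param charges the source [charge_set()] (for the Gauss audit).
#' @return A list with method, N, iterations, final_update,
#'   condition_estimate, total induced charge, the Gauss's-law expected
#'   charge and the audit error in e.
#' @export
solver_diagnostics <- function(solution, mesh, charges) {
  g <- gauss_check(solution, mesh, charges)
  list(method = solution$method, N = length(solution$h),
       iterations = solution$iterations,
       final_update = solution$final_update,
       condition_estimate = solution$condition_estimate,
       total_induced_charge_e = g$total_induced_e,
       gauss_expected_e = g$expected_e,
       gauss_error_e = g$abs_error_e)
}

#' Write an induced solution to CSV
#'
#' Columns: tile index, induced density h (e/A^2), tile area (A^2) and
#' induced charge per tile (e).
#'
#' @param solution an `induced_solution`.
#' @param mesh the mesh it was solved on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, mesh, path) {
  df <- data.frame(tile = seq_along(solution$h), h = solution$h,
                   area = mesh$area, induced_e = solution$h * mesh$area)
  write_csv17(df, path)
}
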