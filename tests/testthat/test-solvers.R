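test_that("no dielectric contrast: identity matrix, zero source, zero h", {
  mesh <- assign_dielectrics(tile_sphere(5, 8, 8), 80, 80)
  sys <- build_system(mesh)
  expect_equal(sys$A, diag(64), tolerance = 1e-15)
  b <- build_source(mesh, charge_set(1, c(0, 0, 2), 80))
  expect_equal(b, numeric(64))
  expect_equal(solve_icc(sys, b)$h, numeric(64))
  it <- solve_iter(mesh, b, system = sys)
  expect_equal(it$h, numeric(64))
  expect_equal(it$iterations, 1L)
})

test_that("off-diagonal entries match an independent sub-tile quadrature", {
  mesh <- small_sphere()$mesh
  sys <- build_system(mesh, self_term = "flat")  # isolate the kernel
  n <- n_tiles(mesh)
  set.seed(42)
  w <- pmax(mesh$widths[, 1], mesh$widths[, 2])
  checked <- 0L
  while (checked < 25L) {
    ij <- sample.int(n, 2)
    d <- sqrt(sum((mesh$center[ij[1], ] - mesh$center[ij[2], ])^2))
    if (d < 2 * max(w[ij])) next                 # skip adjacent pairs
    oracle <- entry_by_subquadrature(mesh, ij[1], ij[2], k = 4L)
    expect_equal(sys$A[ij[1], ij[2]], oracle, tolerance = 0.1)
    checked <- checked + 1L
  }
})

test_that("assembly errors: coincident centers, missing dielectrics", {
  mesh <- assign_dielectrics(tile_sphere(5, 8, 8), 2, 80)
  dup <- mesh
  dup$center[2, ] <- dup$center[1, ]
  expect_error(build_system(dup), class = "iccbem_assembly_error")
  expect_error(build_system(tile_sphere(5, 8, 8)),
               class = "iccbem_config_error")
})

test_that("source vector: empty set, central symmetry, linearity, proximity", {
  mesh <- assign_dielectrics(tile_sphere(5, 16, 16), 2, 80)
  expect_equal(build_source(mesh, charge_set()), numeric(256))

  ## charge at the center: all entries equal by symmetry
  b0 <- build_source(mesh, charge_set(1, c(0, 0, 0), 80))
  expect_lt(diff(range(b0)) / abs(mean(b0)), 1e-12)

  ## superposition to machine precision
  q1 <- charge_set(1, c(0, 0, 2), 80)
  q2 <- charge_set(-0.5, c(1, 0, -1), 80)
  expect_equal(build_source(mesh, combine_charges(q1, q2)),
               build_source(mesh, q1) + build_source(mesh, q2),
               tolerance = 1e-15)

  ## too-close charge is refused, naming charge and tile
  close_pos <- mesh$center[5, ] - 0.05 * mesh$normal[5, ]
  err <- expect_error(build_source(mesh, charge_set(1, close_pos, 80)),
                      class = "iccbem_proximity_error")
  expect_match(conditionMessage(err), "charge 1")
  expect_match(conditionMessage(err), "tile")
})

test_that("ICC solves the discrete system to solver tolerance", {
  scen <- small_sphere()
  sys <- small_sphere_system()
  b <- build_source(scen$mesh, scen$charges)
  sol <- solve_icc(sys, b)
  expect_identical(sol$iterations, 0L)
  res <- max(abs(sys$A %*% sol$h - b)) / max(abs(b))
  expect_lt(res, 1e-10)
  expect_true(is.finite(sol$condition_estimate))
})

test_that("Gauss's law: enclosed charge recovered from the solve", {
  scen <- small_sphere()          # N = 256
  b <- build_source(scen$mesh, scen$charges)
  sol <- solve_icc(small_sphere_system(), b)
  want <- 1 * (1 / 2 - 1 / 80)    # 0.4875 e
  expect_equal(sol$total_induced_e, want, tolerance = 0.01)
})

test_that("ICC factor reuse: one factorization, many sources", {
  scen <- small_sphere()
  bem_factorization_count(reset = TRUE)
  fac <- icc_factor(small_sphere_system())
  for (z in c(-3, 0, 2)) {
    b <- build_source(scen$mesh, charge_set(1, c(0, 0, z), 80))
    sol <- solve_icc(fac, b)
    expect_lt(max(abs(small_sphere_system()$A %*% sol$h - b)) /
                max(abs(b)), 1e-10)
  }
  expect_identical(bem_factorization_count(), 1L)
})

test_that("ITER converges to the ICC solution and reports sweeps", {
  scen <- small_sphere()
  sys <- small_sphere_system()
  b <- build_source(scen$mesh, scen$charges)
  icc <- solve_icc(sys, b)
  it <- solve_iter(scen$mesh, b, delta_stop = 1e-4, max_iter = 500,
                   system = sys)
  expect_identical(it$method, "ITER")
  expect_gt(it$iterations, 1L)
  expect_lt(it$final_update, 1e-4)
  ## agreement bounded by the Jacobi contraction limit rho/(1-rho) ~ 19
  ## at contrast 80/2 (see vignette); the 10x figure holds at the
  ## benchmark discretizations tested in test-acceptance.R
  expect_lt(max(abs(it$h - icc$h)) / max(abs(icc$h)), 19 * 1e-4)

  ## tighter delta_stop gives tighter agreement
  it2 <- solve_iter(scen$mesh, b, delta_stop = 1e-7, max_iter = 1000,
                    system = sys)
  expect_lt(max(abs(it2$h - icc$h)) / max(abs(icc$h)), 19 * 1e-7)
})

test_that("ITER failure to converge raises a convergence error", {
  scen <- small_sphere()
  b <- build_source(scen$mesh, scen$charges)
  err <- expect_error(
    solve_iter(scen$mesh, b, delta_stop = 1e-4, max_iter = 3,
               system = small_sphere_system()),
    class = "iccbem_convergence_error")
  expect_true(is.finite(err$final_update))
  expect_error(solve_iter(scen$mesh, b, delta_stop = -1),
               class = "iccbem_parameter_error")
})

test_that("orientation flip leaves h, totals and potentials unchanged", {
  scen <- small_sphere()
  b1 <- build_source(scen$mesh, scen$charges)
  s1 <- solve_icc(build_system(scen$mesh), b1)
  flipped <- flip_orientation(scen$mesh)
  b2 <- build_source(flipped, scen$charges)
  s2 <- solve_icc(build_system(flipped), b2)
  expect_equal(b2, b1, tolerance = 1e-13)
  expect_equal(s2$h, s1$h, tolerance = 1e-11)
  expect_equal(s2$total_induced_e, s1$total_induced_e, tolerance = 1e-11)
  pts <- rbind(c(0, 0, 0), c(0, 0, 3), c(2, 2, -1))
  expect_equal(reaction_potential_at(pts, s2, flipped)$potential_reduced,
               reaction_potential_at(pts, s1, scen$mesh)$potential_reduced,
               tolerance = 1e-11)
})

test_that("superposition: h of a union equals the sum of per-set h", {
  scen <- small_sphere()
  fac <- icc_factor(small_sphere_system())
  q1 <- charge_set(1, c(0, 0, 3), 80)
  q2 <- charge_set(0.5, c(0, 2, -2), 80)
  h_union <- solve_icc(fac, build_source(scen$mesh,
                                         combine_charges(q1, q2)))$h
  h_sum <- solve_icc(fac, build_source(scen$mesh, q1))$h +
    solve_icc(fac, build_source(scen$mesh, q2))$h
  expect_equal(h_union, h_sum, tolerance = 1e-12)
})

test_that("self-term options behave as documented", {
  mesh <- assign_dielectrics(tile_sphere(5, 12, 12), 2, 80)
  flat <- build_system(mesh, self_term = "flat")
  expect_true(all(diag(flat$A) == 1))
  curv <- build_system(mesh, self_term = "curvature")
  expect_true(all(diag(curv$A) != 1))
  auto <- build_system(mesh)               # closed -> sumrule
  expect_identical(auto$self_term, "sumrule")
  ## sum rule: area-weighted kernel column sums are exactly 2 pi
  colsum <- colSums((auto$A - diag(144)) /
                      (mesh$delta_eps / (4 * pi * mesh$mean_eps)) *
                      mesh$area) / mesh$area
  expect_equal(colsum, rep(2 * pi, 144), tolerance = 1e-10)
  ## open meshes cannot use the sum rule
  expect_error(build_system(small_channel_mesh(), self_term = "sumrule"),
               class = "iccbem_parameter_error")
  expect_identical(build_system(small_channel_mesh())$self_term, "curvature")
})

test_that("solver diagnostics report the Gauss audit", {
  scen <- small_sphere()
  sol <- solve_icc(small_sphere_system(),
                   build_source(scen$mesh, scen$charges))
  d <- solver_diagnostics(sol, scen$mesh, scen$charges)
  expect_named(d, c("method", "N", "iterations", "final_update",
                    "condition_estimate", "total_induced_charge_e",
                    "gauss_expected_e", "gauss_error_e"))
  expect_equal(d$gauss_expected_e, 0.4875)
  expect_lt(d$gauss_error_e, 0.01)
})
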