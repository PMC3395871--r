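test_that("sphere tiling: exact telescoping area, radial normals, centroid", {
  for (nt in c(8, 16, 32)) {
    mesh <- tile_sphere(5, nt, nt)
    expect_equal(n_tiles(mesh), nt * nt)
    ## patch areas telescope to 4 pi R^2 exactly
    expect_equal(mesh_area(mesh), 4 * pi * 25, tolerance = 1e-13)
    ## normals are radial and unit length
    rad <- mesh$center / sqrt(rowSums(mesh$center^2))
    expect_lt(max(abs(rowSums(mesh$normal * rad) - 1)), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(mesh$normal^2)) - 1)), 1e-12)
    ## centers lie on the sphere
    expect_lt(max(abs(sqrt(rowSums(mesh$center^2)) - 5)), 1e-12)
  }
  ## area-weighted centroid at the origin by symmetry
  mesh <- tile_sphere(5, 32, 32)
  cm <- colSums(mesh$center * mesh$area) / mesh_area(mesh)
  expect_lt(max(abs(cm)), 1e-10)
})

test_that("sphere tiling rejects bad parameters", {
  expect_error(tile_sphere(-1, 16, 16), class = "iccbem_parameter_error")
  expect_error(tile_sphere(5, 1, 16), class = "iccbem_parameter_error")
  expect_error(tile_sphere(5, 16, 2), class = "iccbem_parameter_error")
})

test_that("channel tiling: tile budget, bounds, symmetries", {
  mesh <- tile_channel(pore_radius = 6.5, membrane_width = 30,
                       n_tiles_target = 860)
  expect_equal(n_tiles(mesh), 860)          # layout lands exactly on target
  expect_lt(abs(n_tiles(mesh) - 860) / 860, 0.1)
  ## every tile center within the slab
  expect_true(all(abs(mesh$center[, 3]) <= 15 + 1e-9))
  ## mirror symmetry z -> -z
  flipped <- mesh$center
  flipped[, 3] <- -flipped[, 3]
  expect_true(maps_onto_itself(mesh$center, flipped, tol = 1e-8))
  ## azimuthal rotation invariance by one sector
  nphi <- mesh$geometry$n_phi
  expect_true(maps_onto_itself(mesh$center,
                               rot_z(mesh$center, 2 * pi / nphi), tol = 1e-8))
  ## a non-multiple angle must NOT map the mesh onto itself
  expect_false(maps_onto_itself(mesh$center,
                                rot_z(mesh$center, pi / nphi), tol = 1e-8))
})

test_that("channel tiling respects the target across budgets", {
  for (target in c(200, 500, 1500)) {
    mesh <- tile_channel(n_tiles_target = target)
    expect_lt(abs(n_tiles(mesh) - target) / target, 0.1)
  }
})

test_that("channel tiling rejects inconsistent geometry", {
  expect_error(tile_channel(membrane_width = 8, corner_radius = 5),
               class = "iccbem_parameter_error")
  expect_error(tile_channel(pore_radius = 30, lateral_extent = 32,
                            corner_radius = 5),
               class = "iccbem_parameter_error")
})

test_that("dielectric assignment and orientation flip", {
  mesh <- tile_sphere(5, 8, 8)
  mesh <- assign_dielectrics(mesh, eps_ahead = 2, eps_behind = 80)
  expect_true(all(mesh$delta_eps == -78))
  expect_true(all(mesh$mean_eps == 41))
  expect_identical(mesh$orientation, "into_low_eps")

  ## homogeneous limit
  hom <- assign_dielectrics(tile_sphere(5, 8, 8), 80, 80)
  expect_true(all(hom$delta_eps == 0))

  ## channel mean permittivity
  ch <- assign_dielectrics(tile_channel(n_tiles_target = 200), 6, 80)
  expect_true(all(ch$mean_eps == 43))

  ## flip negates delta_eps and normals, keeps mean_eps
  fl <- flip_orientation(mesh)
  expect_true(all(fl$delta_eps == 78))
  expect_true(all(fl$mean_eps == 41))
  expect_equal(fl$normal, -mesh$normal)
  expect_identical(fl$orientation, "into_high_eps")

  expect_error(assign_dielectrics(mesh, 0.5, 80),
               class = "iccbem_parameter_error")
})

test_that("sphere mesh area converges and channel area is sane", {
  ## sphere sum is exact at any N (telescoping); check the >= 1024 clause
  mesh <- tile_sphere(5, 32, 32)
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 25) / (4 * pi * 25), 0.01)
  ## channel: compare against the analytic profile area
  g <- tile_channel(n_tiles_target = 860)
  hw <- 15; rc <- 5; Rt <- 11.5
  exact <- 2 * pi * 6.5 * 2 * (hw - rc) +                  # pore wall
    2 * pi * (40^2 - Rt^2) +                               # two faces
    2 * (2 * pi * rc * (Rt * pi / 2 - rc))                 # two torus corners
  expect_equal(mesh_area(g), exact, tolerance = 1e-10)
})

test_that("region predicate identifies the membrane interior", {
  mesh <- small_channel_mesh()
  geo <- mesh$geometry
  inside <- rbind(c(20, 0, 0), c(8.5, 0, 3), c(10.5, 0, 3), c(12, 0, 14))
  outside <- rbind(c(0, 0, 0), c(0, 0, -25), c(4.5, 0, -8),
                   c(20, 0, 16), c(8, 0, 13))  # last: corner water pocket
  expect_true(all(iccbem:::region_enclosed(geo, inside)))
  expect_false(any(iccbem:::region_enclosed(geo, outside)))
})

test_that("charge sets validate and concatenate", {
  cs <- charge_set(1, c(0, 0, 4), 80)
  expect_equal(nrow(cs), 1L)
  expect_error(charge_set(c(1, 1), c(0, 0, 0), 80),
               class = "iccbem_parameter_error")
  expect_error(charge_set(1, c(0, 0, 0), 0.2),
               class = "iccbem_parameter_error")
  both <- combine_charges(cs, charge_set(-1, c(0, 0, -4), 80))
  expect_equal(sum(both$q), 0)
})

test_that("mesh exporters write well-formed files", {
  mesh <- assign_dielectrics(tile_sphere(5, 8, 8), 2, 80)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mesh_csv(mesh, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 64)
  expect_named(df, c("cx", "cy", "cz", "nx", "ny", "nz", "area",
                     "delta_eps", "mean_eps"))
  expect_equal(sum(df$area), 4 * pi * 25, tolerance = 1e-12)

  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 4 * 64)
  expect_equal(sum(startsWith(lines, "f ")), 64)
})
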