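# Synthetic ventricle: mesh, fibers, spring boundary conditions.

test_that("geometry construction is deterministic and validated", {
  g1 <- tiny_lv()
  g2 <- tiny_lv()
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$cavity_volume, g2$cavity_volume)
  expect_error(build_ellipsoid_lv(a_endo = 8, wall_thickness = 10),
               "degenerate")
  expect_error(build_ellipsoid_lv(z_base = 60), "basal truncation")
})

test_that("cavity volume agrees with the closed form in the sphere limit", {
  r <- 25; zb <- 15
  g <- build_ellipsoid_lv(a_endo = r, c_endo = r, wall_thickness = 8,
                          z_base = zb)
  cap_h <- r - zb
  v_exact <- (4 / 3 * pi * r^3 - pi * cap_h^2 * (3 * r - cap_h) / 3) / 1000
  expect_lt(abs(g$cavity_volume - v_exact) / v_exact, 0.01)
})

test_that("cavity volume is mesh-converged at the default resolution", {
  g1 <- build_ellipsoid_lv()
  g2 <- build_ellipsoid_lv(n_theta = 48, n_phi = 128)
  expect_lt(abs(g2$cavity_volume - g1$cavity_volume) / g1$cavity_volume,
            0.005)
})

test_that("landmarks and apex-base axis are well formed", {
  g <- tiny_lv()
  expect_equal(sqrt(sum(g$axis^2)), 1, tolerance = 1e-12)
  expect_lt(g$landmarks$apex_epi[3], g$landmarks$annulus_center[3])
  expect_equal(g$landmarks$annulus_center, c(0, 0, g$z_base))
  # aortic root sits on the septal side of the annulus plane
  expect_equal(g$landmarks$aortic_root[3], g$z_base)
  expect_gt(g$landmarks$aortic_root[1], 0)
})

test_that("fiber field is orthonormal with linear transmural helix", {
  g <- tiny_lv()
  mic <- assign_fiber_field(g, 60, -60)
  dots <- c(abs(rowSums(mic$f0 * mic$s0)), abs(rowSums(mic$f0 * mic$n0)),
            abs(rowSums(mic$s0 * mic$n0)))
  expect_lt(max(dots), 1e-10)
  norms <- c(rowSums(mic$f0^2), rowSums(mic$s0^2), rowSums(mic$n0^2))
  expect_equal(max(abs(norms - 1)), 0, tolerance = 1e-10)
  # linear interpolation: mid-wall helix angle near zero
  mid <- abs(mic$transmural - 0.5) < 0.26
  expect_lt(max(abs(mic$helix_deg[mid])), 31)
  expect_equal(mic$helix_deg, 60 * (1 - mic$transmural) - 60 * mic$transmural,
               tolerance = 1e-10)
  # circumferential fibers when both angles are zero
  mic0 <- assign_fiber_field(g, 0, 0)
  expect_lt(max(abs(mic0$f0 %*% g$axis)), 1e-10)
  expect_error(assign_fiber_field(g, 95, -60))
})

test_that("pericardial clusters partition the epicardium with a linear gradient", {
  g <- tiny_lv()
  spr <- build_pericardial_springs(g, k_apex = 2, k_base = 0.5,
                                   n_clusters = 49, seed = 3)
  expect_length(spr, 49)
  all_nodes <- unlist(lapply(spr, `[[`, "nodes"))
  expect_identical(sort(all_nodes), g$surfaces$epicardium)   # cover
  expect_identical(anyDuplicated(all_nodes), 0L)             # disjoint
  ax <- vapply(spr, `[[`, 0, "axial_position")
  k <- vapply(spr, `[[`, 0, "stiffness")
  expect_equal(k, 2 + (0.5 - 2) * ax, tolerance = 1e-12)     # interpolation
  expect_true(all(diff(k[order(ax)]) <= 1e-12))              # non-increasing
  # midpoint of the gradient
  expect_equal(2 + (0.5 - 2) * 0.5, (2 + 0.5) / 2)
  # equal endpoint stiffness collapses the gradient
  spr_eq <- build_pericardial_springs(g, k_apex = 1, k_base = 1)
  expect_true(all(vapply(spr_eq, `[[`, 0, "stiffness") == 1))
  expect_error(build_pericardial_springs(g, 2, 0.1,
                                         n_clusters = 1e5), "fewer")
  expect_error(build_pericardial_springs(g, 0.1, 2), "k_apex")
  # determinism under a fixed seed
  spr2 <- build_pericardial_springs(g, k_apex = 2, k_base = 0.5,
                                    n_clusters = 49, seed = 3)
  expect_identical(lapply(spr, `[[`, "nodes"), lapply(spr2, `[[`, "nodes"))
})

test_that("releasing the apex flags the distal clusters only", {
  g <- tiny_lv()
  spr <- build_pericardial_springs(g)
  freed <- free_apex(spr, 0.5)
  ax <- vapply(spr, `[[`, 0, "axial_position")
  act <- vapply(freed, `[[`, TRUE, "active")
  expect_identical(act, ax >= 0.5)
  expect_true(all(vapply(spr, `[[`, TRUE, "active")))   # input untouched
  expect_identical(free_apex(spr, 0), spr)
  expect_false(any(vapply(free_apex(spr, 1), `[[`, TRUE, "active")))
  expect_error(free_apex(spr, 1.2), "freed_fraction")
  expect_error(free_apex(list(), 0.5), "empty")
})

test_that("aortic spring acts axially at the root landmark", {
  g <- tiny_lv()
  ao <- build_aortic_spring(g, 0.5)
  expect_identical(ao$anchor, g$landmarks$aortic_root)
  expect_identical(ao$normal, g$axis)
  expect_error(build_aortic_spring(g, 0))
})

test_that("VTK export writes a readable unstructured grid", {
  g <- tiny_lv()
  f <- tempfile(fileext = ".vtk")
  write_vtk_mesh(g, f)
  head <- readLines(f, n = 5)
  expect_match(head[4], "UNSTRUCTURED_GRID")
  expect_match(head[5], sprintf("POINTS %d", nrow(g$nodes)))
  unlink(f)
})
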