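# Equilibrium solver, cavity volume, spring reactions.

test_that("surface volume obeys closed form, translation and scaling", {
  # lat-long unit sphere built in code
  nth <- 40; nph <- 80
  th <- seq(0, pi, length.out = nth + 1)
  verts <- rbind(c(0, 0, 1))
  for (j in 2:nth) for (k in seq_len(nph) - 1) {
    p <- 2 * pi * k / nph
    verts <- rbind(verts, c(sin(th[j]) * cos(p), sin(th[j]) * sin(p),
                            cos(th[j])))
  }
  verts <- rbind(verts, c(0, 0, -1))
  id <- function(j, k) 1 + (j - 2) * nph + (k %% nph) + 1
  faces <- list()
  for (k in seq_len(nph) - 1) faces[[length(faces) + 1]] <-
    c(1, id(2, k), id(2, k + 1))
  for (j in 2:(nth - 1)) for (k in seq_len(nph) - 1) {
    faces[[length(faces) + 1]] <- c(id(j, k), id(j + 1, k), id(j + 1, k + 1))
    faces[[length(faces) + 1]] <- c(id(j, k), id(j + 1, k + 1), id(j, k + 1))
  }
  for (k in seq_len(nph) - 1) faces[[length(faces) + 1]] <-
    c(id(nth, k + 1), id(nth, k), nrow(verts))
  faces <- do.call(rbind, faces)
  v <- surface_volume(verts, faces)
  expect_lt(abs(v - 4 * pi / 3) / (4 * pi / 3), 0.01)
  # rigid translation leaves the volume unchanged
  vt <- surface_volume(verts + matrix(c(13, -7, 5), nrow(verts), 3,
                                      byrow = TRUE), faces)
  expect_equal(vt, v, tolerance = 1e-10)
  # uniform scaling scales the volume by s^3
  expect_equal(surface_volume(2.5 * verts, faces), 2.5^3 * v,
               tolerance = 1e-12)
})

ctx <- tiny_context()

test_that("unloaded state is an equilibrium with zero displacement", {
  st <- solve_equilibrium(ctx, 0, -1)
  # displacement at the stress-free state is zero to micrometer scale
  expect_lt(max(abs(st$q) / ctx$scales), 2e-3)
  expect_true(st$converged)
  # quadrature cavity volume vs the triangulated mesh volume (coarse mesh)
  expect_equal(st$cavity_volume, ctx$geom$cavity_volume, tolerance = 0.03)
})

test_that("passive compliance is positive and volume-driven solves match", {
  s5 <- solve_equilibrium(ctx, 5, -1)
  s10 <- solve_equilibrium(ctx, 10, -1, state0 = s5)
  expect_gt(s10$cavity_volume, s5$cavity_volume)
  # volume-constrained solve recovers the pressure
  st <- pressure_for_volume(s10$cavity_volume, ctx, -1, state0 = s5)
  expect_equal(st$cavity_pressure, 10, tolerance = 0.05)
  # target at the unloaded volume needs (almost) no pressure
  v0 <- solve_equilibrium(ctx, 0, -1)$cavity_volume
  s0 <- pressure_for_volume(v0, ctx, -1, p_init = 1)
  expect_lt(abs(s0$cavity_pressure), 0.3)
})

test_that("sampled passive inflation curve is monotone", {
  v0 <- solve_equilibrium(ctx, 0, -1)$cavity_volume
  targets <- v0 * c(1.05, 1.15, 1.25, 1.35, 1.45)
  st <- NULL
  ps <- vapply(targets, function(vt) {
    st <<- pressure_for_volume(vt, ctx, -1, state0 = st)
    st$cavity_pressure
  }, 0)
  expect_true(all(diff(ps) > 0))
})

test_that("activation stiffens the chamber at equal volume", {
  vt <- ctx$geom$cavity_volume * 1.2
  passive <- pressure_for_volume(vt, ctx, -1)
  active <- pressure_for_volume(vt, ctx, activation_time = 0.2,
                                state0 = passive)
  expect_gt(active$cavity_pressure, passive$cavity_pressure + 5)
})

test_that("myocardial volume is conserved through loading", {
  ref <- ctx$wall_volume_ref / 1000
  st <- solve_equilibrium(ctx, 12, -1)
  expect_lt(abs(wall_volume(st, ctx) - ref) / ref, 0.02)
  sta <- pressure_for_volume(ctx$geom$cavity_volume * 0.85, ctx, 0.25,
                             state0 = st)
  expect_lt(abs(wall_volume(sta, ctx) - ref) / ref, 0.02)
})

test_that("spring reactions follow -k times extension", {
  g <- tiny_lv()
  mic <- assign_fiber_field(g)
  ao <- build_aortic_spring(g, 0.5, tissue_stiffness = 1e9)
  cx <- mechanics_context(g, mic, passive_params(), active_params(),
                          aortic_spring = ao, septal_tie = NULL)
  zero <- structure(list(q = rep(0, cx$n_modes)), class = "mechanical_state")
  r0 <- axial_reaction(zero, cx)
  expect_equal(max(abs(r0$force)), 0)
  # root displaced 11 mm toward the apex against a 0.5 N/mm spring
  st <- zero; st$q[6] <- -11
  r <- axial_reaction(st, cx)
  expect_equal(abs(r$force[r$type == "aortic"]), 5.5, tolerance = 1e-6)
  # doubling the stiffness doubles the force
  ao2 <- build_aortic_spring(g, 1.0, tissue_stiffness = 1e9)
  cx2 <- mechanics_context(g, mic, passive_params(), active_params(),
                           aortic_spring = ao2, septal_tie = NULL)
  r2 <- axial_reaction(st, cx2)
  expect_equal(abs(r2$force[r2$type == "aortic"]), 11, tolerance = 1e-5)
})

test_that("axial force balance holds at convergence", {
  st <- solve_equilibrium(ctx, 10, -1)
  r <- axial_reaction(st, ctx)
  # rigid axial translation is in the mode space, so the net axial spring
  # force must vanish at equilibrium (pressure on the closed cavity surface
  # contributes no net axial force)
  expect_lt(abs(sum(r$fz)), 0.05)
})
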