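# Passive law, active elastance model and the empirical filling curve.

vp <- passive_params()
ap <- active_params()

state_of <- function(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  kinematics_state(F, f0, s0)

test_that("deviatoric energy takes its closed-form values", {
  id <- state_of(diag(3))
  expect_identical(psi_dev(id, vp), vp$a / (2 * vp$b))
  expect_equal(psi_dev(id, vp), 5.27027027027027e-05, tolerance = 1e-12)

  # isochoric uniaxial fiber stretch 1.1; expected value frozen from an
  # independent arbitrary-precision evaluation of the energy
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  expect_equal(psi_dev(state_of(F), vp), 1.164517546817572e-04,
               tolerance = 1e-12)

  # shear term vanishes when the fiber-sheet coupling invariant is zero
  vp0 <- passive_params(a = 0, a_f = 0, a_s = 0)
  expect_equal(psi_dev(state_of(F), vp0), 0)

  # tension-only convention: compressed fiber and sheet terms contribute 0
  Fc <- diag(c(0.9, 1.05, 1.06))
  vpi <- passive_params(a = 0, a_fs = 0)
  expect_identical(psi_dev(state_of(Fc, f0 = c(1, 0, 0), s0 = c(1, 0, 0)),
                           vpi), 0)
})

test_that("analytic passive stress matches finite differences of the energy", {
  expect_equal(passive_stress(state_of(diag(3)), vp)$S, matrix(0, 3, 3),
               tolerance = 1e-14)
  # the fiber-sheet coupling term contributes nothing when I8fs = 0:
  # stress is then independent of a_fs (shear in the fiber-normal plane)
  Fs <- diag(3); Fs[1, 3] <- 0.2
  st_fn <- state_of(Fs)
  expect_equal(st_fn$I8fs, 0)
  vp_nofs <- passive_params(a_fs = 1e-12)
  expect_equal(passive_stress(st_fn, vp)$S, passive_stress(st_fn, vp_nofs)$S,
               tolerance = 1e-14)

  # first Piola-Kirchhoff stress F S vs central differences of the total
  # energy over random admissible deformation gradients
  h <- 1e-6
  for (F in random_F(100)) {
    P_an <- F %*% passive_stress(state_of(F), vp)$S
    P_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      ep <- psi_dev(state_of(Fp), vp) + psi_vol(state_of(Fp), vp)
      em <- psi_dev(state_of(Fm), vp) + psi_vol(state_of(Fm), vp)
      P_fd[i, j] <- (ep - em) / (2 * h)
    }
    expect_equal(P_an, P_fd, tolerance = 1e-6)
  }
})

test_that("effective sarcomere length follows the strain relation", {
  expect_identical(eff_sarcomere_length(0, ap), ap$l_r)
  expect_equal(eff_sarcomere_length(1.5, ap), 2 * ap$l_r)
  expect_equal(eff_sarcomere_length(-0.18, ap), 0.00148, tolerance = 1e-14)
  expect_error(eff_sarcomere_length(-0.5, ap), "compression")
})

test_that("calcium sensitivity is positive, decreasing, unbounded below l_0", {
  expect_equal(eca50(ap$l_r, ap), 2.694832871124985, tolerance = 1e-12)
  expect_equal(eca50(1.05 * ap$l_r, ap), 2.029299090141070, tolerance = 1e-12)
  expect_gt(eca50(ap$l_r, ap), eca50(1.05 * ap$l_r, ap))
  ls <- seq(ap$l_0 * 1.001, 1.3 * ap$l_r, length.out = 40)
  expect_true(all(diff(eca50(ls, ap)) < 0))
  expect_identical(eca50(ap$l_0, ap), Inf)
  expect_identical(eca50(ap$l_0 * 0.9, ap), Inf)
  ap2 <- active_params(B = 2 * ap$B)
  expect_lt(eca50(ap$l_r, ap2), eca50(ap$l_r, ap))
})

test_that("active stress obeys the elastance time course", {
  tr <- relaxation_duration(ap$l_r, ap)
  expect_equal(tr, 0.2575)
  expect_identical(active_fiber_stress(0, 0, ap), 0)
  expect_identical(active_fiber_stress(ap$t_0 + tr, 0, ap), 0)
  expect_identical(active_fiber_stress(ap$t_0 + tr + 0.2, 0, ap), 0)
  # peak value at t_0, frozen from an independent evaluation
  expect_equal(active_fiber_stress(ap$t_0, 0, ap), 0.14453138493099562,
               tolerance = 1e-12)
  # linear in contractility
  ap2 <- active_params(T_max = 2 * ap$T_max)
  ts <- seq(0, 0.7, by = 0.01)
  expect_equal(active_fiber_stress(ts, 0.05, ap2),
               2 * active_fiber_stress(ts, 0.05, ap), tolerance = 1e-12)
  # continuous at both phase junctions
  eps <- 1e-9
  expect_equal(active_fiber_stress(ap$t_0 - eps, 0, ap),
               active_fiber_stress(ap$t_0 + eps, 0, ap), tolerance = 1e-6)
  expect_lt(active_fiber_stress(ap$t_0 + tr - eps, 0, ap), 1e-6)
  # non-negative everywhere
  grid <- expand.grid(t = ts, E = seq(-0.2, 0.2, by = 0.05))
  expect_true(all(active_fiber_stress(grid$t, grid$E, ap) >= 0))
})

test_that("peak active tension is non-decreasing in fiber strain", {
  E <- seq(-0.15, 0.25, by = 0.02)
  peak <- vapply(E, function(e)
    max(active_fiber_stress(seq(0, 0.6, by = 0.005), e, ap)), 0)
  expect_true(all(diff(peak) >= -1e-12))
})

test_that("single-beat filling curve passes through its anchor", {
  v <- seq(60, 170, by = 5)
  k <- klotz_edpvr(v, p_m = 11.85, v_m = 158.3)
  expect_equal(klotz_edpvr(158.3, 11.85, 158.3)$pressure, 11.85,
               tolerance = 1e-10)
  V0 <- attr(k, "V0")
  expect_identical(klotz_edpvr(V0 - 10, 11.85, 158.3)$pressure, 0)
  above <- k$volume > V0
  expect_true(all(diff(k$pressure[above]) > 0))
  expect_error(klotz_edpvr(v, p_m = -1, v_m = 158.3))
})
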