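# Closed-loop lumped hemodynamics.

cp <- circulation_params()

test_that("valves are one-way and the loop is stationary at equal pressures", {
  st <- init_circulation(cp, v_lv = 100)
  # ventricular pressure below atrial and arterial pressures: aortic valve
  # closed, no outflow
  s1 <- step_circulation(st, lv_pressure = 5, dt = 0.001, cp)
  expect_identical(s1$Q_av, 0)
  expect_gt(s1$Q_mv, 0)
  # equal pressures everywhere: all flows zero, state stationary
  p <- 10
  cp_eq <- cp
  st$V_la <- cp$V0_la + cp$C_la * p
  st$V_art <- cp$V0_art + cp$C_art * p
  st$V_ven <- cp$V0_ven + cp$C_ven * p
  s2 <- step_circulation(st, lv_pressure = p, dt = 0.001, cp_eq)
  expect_equal(c(s2$Q_mv, s2$Q_av), c(0, 0))
  expect_equal(s2$V_la, st$V_la)
  expect_equal(s2$V_art, st$V_art)
})

test_that("blood volume is conserved exactly through arbitrary stepping", {
  st <- init_circulation(cp, v_lv = 120)
  tot0 <- st$V_la + st$V_art + st$V_ven + st$V_lv
  set.seed(11)
  for (i in 1:400)
    st <- step_circulation(st, lv_pressure = runif(1, 6, 16), dt = 0.002, cp)
  expect_equal(st$V_la + st$V_art + st$V_ven + st$V_lv, tot0,
               tolerance = 1e-12)
  # impulse test: perturbing one chamber changes nothing about conservation
  st$V_art <- st$V_art + 10
  tot1 <- st$V_la + st$V_art + st$V_ven + st$V_lv
  for (i in 1:200)
    st <- step_circulation(st, lv_pressure = runif(1, 6, 16), dt = 0.002, cp)
  expect_equal(st$V_la + st$V_art + st$V_ven + st$V_lv, tot1,
               tolerance = 1e-12)
  expect_error(step_circulation(st, 0, dt = -1, cp))
})

test_that("coupled beats reach a counterclockwise limit cycle and conserve volume", {
  ctx <- tiny_context()
  tr <- run_coupled_beat(ctx, cp, dt_mech = 0.02, max_beats = 5)
  expect_s3_class(tr, "beat_trace")
  expect_lt(tr$volume_drift, 1e-9)
  expect_true(all(tr$trace$Q_mv >= 0))
  expect_true(all(tr$trace$Q_av >= 0))
  m <- compute_pv_metrics(tr)
  expect_true(m$counterclockwise)
  expect_gt(m$SV, 0)
  expect_identical(tr$ed_index, which.max(tr$trace$V_lv))
  expect_identical(tr$es_index, which.min(tr$trace$V_lv))
  .cache$tiny_beat <- list(ctx = ctx, tr = tr)
})

test_that("afterload and preload act in the physiological directions", {
  tb <- .cache$tiny_beat
  init <- list(circulation = tb$tr$final_circulation,
               state = tb$tr$final_state)
  m0 <- compute_pv_metrics(tb$tr)
  # afterload: doubling the systemic resistance raises MAP and lowers SV
  cp_hi <- circulation_params(R_sys = 2 * cp$R_sys)
  # a short transient run is enough to read the direction of the effect
  tr_hi <- suppressWarnings(
    run_coupled_beat(tb$ctx, cp_hi, dt_mech = 0.02, max_beats = 3,
                     init = init))
  expect_gt(mean(tr_hi$trace$P_art), m0$MAP)
  expect_lt(max(tr_hi$trace$V_lv) - min(tr_hi$trace$V_lv), m0$SV)
  # preload: adding 10% blood volume raises SV (Frank-Starling)
  init2 <- init
  init2$circulation$V_ven <- init2$circulation$V_ven + 0.1 * cp$V_total
  tr_pre <- suppressWarnings(
    run_coupled_beat(tb$ctx, cp, dt_mech = 0.02, max_beats = 3,
                     init = init2))
  expect_gt(max(tr_pre$trace$V_lv) - min(tr_pre$trace$V_lv), m0$SV)
})
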