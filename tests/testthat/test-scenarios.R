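# Scenario configuration, immutability and comparison assembly.

test_that("scenario definitions are fixed and immutable", {
  a <- scenario_config("A"); b <- scenario_config("B"); c3 <- scenario_config("C")
  expect_equal(a$aortic_stiffness, 0.5)
  expect_equal(a$freed_fraction, 0)
  expect_equal(b$aortic_stiffness, 10)
  expect_equal(b$freed_fraction, 0)
  expect_equal(c3$aortic_stiffness, 10)
  expect_equal(c3$freed_fraction, 0.5)
  expect_equal(a$T_max, 0.2)
  # B and C differ from A only by the aortic stiffness and the freed flag
  strip <- function(x) x[setdiff(names(x), c("scenario", "aortic_stiffness",
                                             "freed_fraction"))]
  expect_identical(strip(a), strip(b))
  expect_identical(strip(a), strip(c3))
})

test_that("configuration round-trips through YAML", {
  cfg <- scenario_config("B", T_max = 0.2, seed = 9,
                         geometry = list(n_theta = 12))
  f <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  cfg2 <- read_scenario_config(f)
  expect_equal(cfg2$scenario, "B")
  expect_equal(cfg2$aortic_stiffness, 10)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$geometry$n_theta, 12)
  unlink(f)
})

fake_result <- function(scale = 1) {
  metrics <- structure(list(EDP = 12 * scale, EDV = 158, ESP = 117, ESV = 66,
                            SV = 92, MAP = 95, SW = 8740), class = "beat_metrics")
  strain <- structure(list(
    summary = data.frame(direction = c("circumferential", "longitudinal",
                                       "radial"),
                         mean = c(-0.2, -0.16, 0.63), sd = c(0.05, 0.01, 0.11)),
    regional = data.frame(sector = c("septal", "anterior", "lateral",
                                     "posterior"),
                          mean = c(-0.17, -0.17, -0.15, -0.15))),
    class = "strain_report")
  stress <- myofiber_stress_summary(rep(0.05, 4))
  list(metrics = metrics, strain = strain, stress = stress)
}

test_that("comparison of identical runs yields zero percent everywhere", {
  r <- fake_result()
  tab <- run_comparison(r, r, r)
  expect_true(all(tab$pv_percent == 0))
  expect_true(all(tab$regional_percent == 0))
  expect_equal(tab$stress$pct_vs_baseline[2:3], c(0, 0))
  expect_error(run_comparison(r, NULL, r), "three")
})

test_that("passive inflation tracks the empirical filling-curve shape", {
  # anchor the empirical curve at the model's own filling point and compare
  # the lower limb shapes
  ctx <- tiny_context(T_max = 0)
  st <- solve_equilibrium(ctx, 12, -1, base_counter_pressure = 12)
  anchor_v <- st$cavity_volume
  vols <- anchor_v * c(0.78, 0.85, 0.92)
  k <- klotz_edpvr(vols, p_m = 12, v_m = anchor_v)
  st2 <- NULL
  for (i in seq_along(vols)) {
    st2 <- pressure_for_volume(vols[i], ctx, -1, state0 = st2,
                               base_counter_pressure = k$pressure[i])
    expect_gt(st2$cavity_pressure, k$pressure[i] / 3)
    expect_lt(st2$cavity_pressure, k$pressure[i] * 3)
  }
})
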