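# PV metrics, percent-change rendering, strain sampling, stress summaries,
# landmark displacements.

test_that("PV metrics reproduce closed-form loops and the SW identity", {
  # rectangular synthetic loop traversed counterclockwise
  V <- c(seq(70, 150, length.out = 20), rep(150, 10),
         seq(150, 70, length.out = 20), rep(70, 10))
  P <- c(rep(10, 20), seq(10, 100, length.out = 10),
         rep(100, 20), seq(100, 10, length.out = 10))
  tr <- data.frame(t = seq_along(V) * 0.01, P_lv = P, V_lv = V, P_art = 90)
  m <- compute_pv_metrics(tr)
  expect_equal(m$loop_area, 80 * 90, tolerance = 1e-10)
  expect_true(m$counterclockwise)
  expect_equal(m$SV, 80)
  expect_equal(m$MAP, 90)
  expect_equal(m$SW, 80 * 90)
  # SW = SV x MAP by construction, so SW/SV always equals the reported MAP
  expect_equal(m$SW / m$SV, m$MAP)
  # non-cyclic trace rejected
  bad <- tr[1:35, ]
  expect_error(compute_pv_metrics(bad), "cyclic")
})

test_that("percent change matches hand arithmetic and table rendering", {
  expect_equal(percent_change(92.20, 82.20), -10.85)
  expect_equal(percent_change(66.10, 77.40), 17.10)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "zero")
  cr <- comparison_rows(c(SV = 92.20, SW = 8747.50),
                        c(SV = 82.20, SW = 7084.50))
  expect_equal(cr["percent", "SV"], -10.85)
  expect_equal(cr["percent", "SW"], -19.01)
})

ctx_pp <- tiny_context()

test_that("strain sampling is exact on affine deformations", {
  ids <- affine_state(diag(3))
  rep0 <- strain_at_locations(ids, ids, ctx_pp)
  expect_equal(max(abs(rep0$samples$strain)), 0, tolerance = 1e-12)
  # uniform axial compression by 0.84: longitudinal strain -0.16 everywhere
  comp <- affine_state(diag(c(1, 1, 0.84)))
  repc <- strain_at_locations(ids, comp, ctx_pp)
  lon <- repc$samples$strain[repc$samples$direction == "longitudinal"]
  expect_equal(lon, rep(-0.16, length(lon)), tolerance = 1e-10)
  # uniform stretch by 1.63: every direction reports strain 0.63
  thick <- affine_state(1.63 * diag(3))
  rept <- strain_at_locations(ids, thick, ctx_pp)
  expect_equal(rept$samples$strain, rep(0.63, nrow(rept$samples)),
               tolerance = 1e-9)
  # arbitrary affine maps: fiducial strain equals |F d| - 1
  set.seed(5)
  for (rep_i in 1:5) {
    A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    st <- affine_state(A)
    r <- strain_at_locations(ids, st, ctx_pp)
    spec <- strain_sampling_spec(ctx_pp$geom)
    # check one site per repetition against the closed form
    i <- sample(nrow(spec), 1)
    ph <- spec$azimuth[i]
    d_rad <- c(cos(ph), sin(ph), 0)
    d_circ <- c(-sin(ph), cos(ph), 0)
    d_long <- c(0, 0, 1)
    expected <- c(sqrt(sum((A %*% d_rad)^2)),
                  sqrt(sum((A %*% d_circ)^2)),
                  sqrt(sum((A %*% d_long)^2))) - 1
    got <- r$samples$strain[r$samples$location == spec$location[i] &
                              r$samples$layer == spec$layer[i] &
                              r$samples$level == spec$level[i]]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("regional longitudinal table renders sector means and changes", {
  idc <- affine_state(diag(3))
  comp <- affine_state(diag(c(1, 1, 0.84)))
  r1 <- strain_at_locations(idc, comp, ctx_pp)
  tab <- regional_longitudinal(r1)
  expect_identical(colnames(tab),
                   c("septal", "anterior", "lateral", "posterior"))
  expect_equal(as.numeric(tab[1, ]), rep(-0.16, 4))
  tab2 <- regional_longitudinal(r1, baseline = r1)
  expect_equal(as.numeric(tab2["percent_change", ]), rep(0, 4))
})

test_that("stress summaries use volume weights and element-wise changes", {
  s <- myofiber_stress_summary(rep(0.05, 10))
  expect_equal(s$mean, 0.05)
  expect_equal(s$sd, 0)
  s2 <- myofiber_stress_summary(c(0.1, 0.2), weights = c(1, 1),
                                reference = c(0.1, 0.1))
  expect_equal(s2$pct_mean, 50)
  expect_equal(s2$pct_sd, 50)     # population SD of {0, 100}
  s3 <- myofiber_stress_summary(c(0.1, 0.2), weights = c(1, 1),
                                reference = c(0.1, 0.2))
  expect_equal(c(s3$pct_mean, s3$pct_sd), c(0, 0))
  # volume-weighted mean of a uniform field is subdivision invariant
  s4 <- myofiber_stress_summary(rep(0.05, 40), weights = runif(40, 1, 3))
  expect_equal(s4$mean, 0.05)
  expect_error(myofiber_stress_summary(c(1, 2), weights = c(1, 1),
                                       reference = c(1, 2, 3)),
               "discretization")
})

test_that("landmark displacements carry the documented sign conventions", {
  mk_trace <- function(root, apex) {
    tr <- data.frame(t = c(0, 0.5), P_lv = c(10, 100), V_lv = c(150, 70),
                     P_art = 90, x_root = root, x_apex = apex)
    structure(list(trace = tr, ed_index = 1L, es_index = 2L),
              class = "beat_trace")
  }
  # rigid axial translation: both landmarks move equally, zero shortening
  tr <- mk_trace(root = c(0, -4), apex = c(0, -4))
  d <- apex_and_root_displacement(tr)
  expect_equal(d$apex, d$root_axial)
  expect_equal(d$root_axial - d$apex, 0)
  # systolic base descent is positive "toward the apex" for the root
  tr2 <- mk_trace(root = c(2, -9), apex = c(0, -1.5))
  d2 <- apex_and_root_displacement(tr2)
  expect_equal(d2$root_toward_apex, 11)
  expect_equal(d2$apex, -1.5)
  expect_error(apex_and_root_displacement(
    structure(list(trace = data.frame(t = 1), ed_index = 1, es_index = 1),
              class = "beat_trace")), "landmark")
})
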