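# shared fixtures: a coarse ventricle for unit tests and a memoized full
# three-scenario study for the acceptance suite

.cache <- new.env(parent = emptyenv())

tiny_lv <- function(...) {
  build_ellipsoid_lv(n_transmural = 2, n_theta = 10, n_phi = 24, ...)
}

tiny_context <- function(geometry = tiny_lv(), T_max = 0.2,
                         aortic_stiffness = 0.5, with_springs = TRUE, ...) {
  micro <- assign_fiber_field(geometry)
  springs <- if (with_springs)
    build_pericardial_springs(geometry, k_apex = 2, k_base = 0.05)
  aortic <- build_aortic_spring(geometry, aortic_stiffness)
  mechanics_context(geometry, micro, passive_params(),
                    active_params(T_max = T_max),
                    springs = springs, aortic_spring = aortic, ...)
}

# full calibrated baseline + three scenarios, computed once per test run
acceptance_study <- function() {
  if (is.null(.cache$study))
    .cache$study <- run_study(scenario_config("A", seed = 1))
  .cache$study
}

# random admissible deformation gradients for property tests
random_F <- function(n, magnitude = 0.15, seed = 7) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    F <- diag(3) + matrix(stats::rnorm(9, 0, magnitude), 3, 3)
    if (det(F) > 0.3) {
      i <- i + 1
      out[[i]] <- F
    }
  }
  out
}
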