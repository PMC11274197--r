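# Scenario configuration, baseline calibration and the three-simulation
# comparison (A: elastic ascending aorta; B: stiff ascending aorta;
# C: stiff ascending aorta with freed apex).

.scenario_table <- list(
  A = list(aortic_stiffness = 0.5, freed_fraction = 0),
  B = list(aortic_stiffness = 10, freed_fraction = 0),
  C = list(aortic_stiffness = 10, freed_fraction = 0.5))

#' Scenario configuration
#'
#' Bundles every knob of one simulation. The scenario id fixes the aortic
#' spring stiffness and the freed apical fraction (A: 0.5 N/mm, nothing
#' freed; B: 10 N/mm, nothing freed; C: 10 N/mm, distal half freed); B and C
#' differ from A in nothing else.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param T_max contractility (MPa).
#' @param geometry,fibers,pericardial,circulation,mechanics,run optional
#'   lists overriding the defaults of the corresponding sub-configurations.
#' @param seed RNG seed (epicardial clustering).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("A", "B", "C"), T_max = 0.2,
                            geometry = list(), fibers = list(),
                            pericardial = list(), circulation = list(),
                            mechanics = list(), run = list(), seed = 1) {
  scenario <- match.arg(scenario)
  sc <- .scenario_table[[scenario]]
  structure(list(
    scenario = scenario,
    aortic_stiffness = sc$aortic_stiffness,
    freed_fraction = sc$freed_fraction,
    T_max = T_max,
    geometry = utils::modifyList(list(a_endo = 22, c_endo = 52,
                                      wall_thickness = 10, z_base = 20,
                                      scale = 1, root_offset = 26,
                                      n_transmural = 3, n_theta = 24,
                                      n_phi = 64), geometry),
    fibers = utils::modifyList(list(endo_angle = 60, epi_angle = -60),
                               fibers),
    pericardial = utils::modifyList(list(k_apex = 2, k_base = 0.05,
                                         n_clusters = 49,
                                         septal_tie_k = 8), pericardial),
    circulation = circulation,
    mechanics = mechanics,
    run = utils::modifyList(list(dt_mech = 0.01, dt_circ = 0.001,
                                 max_beats = 8, sv_tol = 0.01), run),
    seed = seed), class = "scenario_config")
}

#' Read / write a scenario configuration as YAML
#'
#' @param path file path.
#' @param config a [scenario_config()].
#' @return `read_scenario_config` returns a `scenario_config`;
#'   `write_scenario_config` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_config, y)
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  y <- unclass(config)
  y$aortic_stiffness <- NULL; y$freed_fraction <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}

# assemble geometry, microstructure, springs and mechanics context for a
# scenario under a calibrated parameter set
.scenario_context <- function(config, calibration = NULL) {
  geo_args <- config$geometry
  peri <- config$pericardial
  circ_args <- config$circulation
  if (!is.null(calibration)) {
    geo_args$scale <- calibration$scale
    peri$k_apex <- calibration$k_apex
    peri$k_base <- calibration$k_base
    circ_args <- utils::modifyList(calibration$circulation_args, circ_args)
  }
  geometry <- do.call(build_ellipsoid_lv, geo_args)
  micro <- assign_fiber_field(geometry, config$fibers$endo_angle,
                              config$fibers$epi_angle)
  springs <- build_pericardial_springs(geometry, peri$k_apex, peri$k_base,
                                       peri$n_clusters, seed = config$seed)
  if (config$freed_fraction > 0)
    springs <- free_apex(springs, config$freed_fraction)
  aortic <- build_aortic_spring(geometry, config$aortic_stiffness)
  ctx <- mechanics_context(geometry, micro,
                           passive_params(),
                           active_params(T_max = config$T_max),
                           springs = springs, aortic_spring = aortic,
                           septal_tie = list(k = peri$septal_tie_k,
                                             u = 0.5, zhat = 0.85),
                           settings = config$mechanics)
  circ <- do.call(circulation_params, circ_args)
  list(context = ctx, geometry = geometry, microstructure = micro,
       springs = springs, aortic = aortic, circulation = circ)
}

#' Calibrate the baseline (elastic aorta) model
#'
#' Tunes the parameters the published model leaves unprinted so that the
#' converged baseline beat reproduces its operating point: (1) the geometry
#' scale, so that passive inflation at the end-diastolic pressure gives the
#' target end-diastolic volume; (2) the systemic resistance and total blood
#' volume, so that mean arterial pressure and end-diastolic pressure land on
#' target; (3) the apical pericardial stiffness, so that the systolic
#' aortic-root excursion matches the target. The calibrated set is saved and
#' reused verbatim for the stiff-aorta and freed-apex scenarios.
#'
#' @param config a scenario-A [scenario_config()].
#' @param targets list with `root_disp` (mm, toward apex), `edv` (mL),
#'   `edp` (mmHg), `map` (mmHg).
#' @param max_iter maximum coupled-run calibration iterations.
#' @param progress print per-iteration summaries.
#' @return object of class `lv_calibration`: `scale`, `k_apex`, `k_base`,
#'   `circulation_args`, achieved metrics and the convergence flag.
#' @export
calibrate_baseline <- function(config = scenario_config("A"),
                               targets = list(root_disp = 11.0, edv = 158.3,
                                              edp = 11.85, map = 94.87),
                               max_iter = 12, progress = FALSE) {
  if (config$scenario != "A")
    stop("calibration is defined on the baseline (scenario A) configuration")
  circ_args <- utils::modifyList(
    list(R_sys = targets$map / (0.92 * targets$edv * 0.58), V_total = 3000),
    config$circulation)

  # step 1: geometry scale from passive inflation at the target EDP
  passive_edv <- function(scale) {
    cfg <- config; cfg$geometry$scale <- scale
    sc <- .scenario_context(cfg, NULL)
    # during filling the atrial pressure above the valve plane matches the
    # cavity pressure, so the basal cap carries no net load
    solve_equilibrium(sc$context, targets$edp, -1,
                      base_counter_pressure = targets$edp)$cavity_volume
  }
  s_lo <- 0.9; s_hi <- 1.45
  v_lo <- passive_edv(s_lo); v_hi <- passive_edv(s_hi)
  if (!(v_lo < targets$edv && v_hi > targets$edv))
    stop(sprintf(paste0("geometry scale bounds do not bracket the EDV ",
                        "target (%.1f mL): achieved [%.1f, %.1f] mL"),
                 targets$edv, v_lo, v_hi))
  scale <- stats::uniroot(function(s) passive_edv(s) - targets$edv,
                          c(s_lo, s_hi), tol = 1e-3)$root

  # steps 2-3: coupled fixed point on R_sys, V_total and k_apex
  k_apex <- config$pericardial$k_apex
  k_base <- config$pericardial$k_base
  init <- NULL
  achieved <- NULL
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    cal <- list(scale = scale, k_apex = k_apex, k_base = k_base,
                circulation_args = circ_args)
    sc <- .scenario_context(config, cal)
    if (!is.null(init)) {
      # inject the blood-volume change of this iteration into the venous
      # compartment of the carried state (the loop conserves volume)
      tot <- init$circulation$V_la + init$circulation$V_art +
        init$circulation$V_ven + init$circulation$V_lv
      init$circulation$V_ven <- init$circulation$V_ven +
        (circ_args$V_total - tot)
    }
    beats <- if (is.null(init)) config$run$max_beats else 3
    tr <- run_coupled_beat(sc$context, sc$circulation,
                           dt_mech = config$run$dt_mech,
                           dt_circ = config$run$dt_circ,
                           max_beats = beats, sv_tol = config$run$sv_tol,
                           init = init, progress = FALSE)
    init <- list(circulation = tr$final_circulation, state = tr$final_state)
    m <- compute_pv_metrics(tr)
    disp <- apex_and_root_displacement(tr)
    achieved <- list(root_disp = disp$root_toward_apex, apex = disp$apex,
                     edv = m$EDV, edp = m$EDP, map = m$MAP, sv = m$SV,
                     sw = m$SW)
    if (progress)
      message(sprintf(
        "cal %d: root %.1f mm apex %.1f mm EDV %.1f EDP %.2f MAP %.1f SV %.1f (k_apex %.2f R_sys %.2f V_tot %.0f)",
        it, achieved$root_disp, achieved$apex, m$EDV, m$EDP, m$MAP, m$SV,
        k_apex, circ_args$R_sys, circ_args$V_total))
    ok <- abs(achieved$root_disp - targets$root_disp) < 0.75 &&
      abs(m$EDV - targets$edv) < 5 && abs(m$MAP - targets$map) < 3
    if (ok) break
    circ_args$R_sys <- min(max(circ_args$R_sys *
                                 (targets$map / m$MAP)^0.7, 0.3), 4)
    circ_args$V_total <- min(max(circ_args$V_total +
                                   12 * (targets$edv - m$EDV), 2200), 5000)
    if (achieved$root_disp > 0.2)
      k_apex <- min(max(k_apex * (targets$root_disp /
                                    achieved$root_disp)^0.7, 0.2), 15)
    else k_apex <- min(k_apex * 2, 15)
    k_apex <- max(k_apex, k_base)
  }
  if (!ok)
    warning(sprintf(paste0(
      "calibration targets not met within %d iterations; closest: root ",
      "%.1f mm, EDV %.1f mL, EDP %.2f mmHg, MAP %.1f mmHg"), max_iter,
      achieved$root_disp, achieved$edv, achieved$edp, achieved$map))
  structure(list(scale = scale, k_apex = k_apex, k_base = k_base,
                 circulation_args = circ_args, targets = targets,
                 achieved = achieved, converged = ok,
                 init = init), class = "lv_calibration")
}

#' Run one scenario to its limit cycle and post-process it
#'
#' End-diastole and end-systole are detected from the extrema of the volume
#' trace of the converged beat; strain, stress and displacement reports are
#' computed between those two states.
#'
#' @param config a [scenario_config()].
#' @param calibration a [calibrate_baseline()] result.
#' @param init optional warm-start (as in [run_coupled_beat()]).
#' @return object of class `scenario_result` with elements `trace`
#'   (`beat_trace`), `metrics` (`beat_metrics`), `strain`
#'   (`strain_report`), `stress` (`stress_report`), `displacement`,
#'   `wall_volumes` (ED/ES material volume, mL), `config`, `context`.
#' @export
run_scenario <- function(config, calibration, init = NULL) {
  sc <- .scenario_context(config, calibration)
  tr <- run_coupled_beat(sc$context, sc$circulation,
                         dt_mech = config$run$dt_mech,
                         dt_circ = config$run$dt_circ,
                         max_beats = config$run$max_beats,
                         sv_tol = config$run$sv_tol, init = init)
  metrics <- compute_pv_metrics(tr)
  ied <- tr$ed_index; ies <- tr$es_index
  mk_state <- function(i) structure(
    list(q = tr$Q[i, ], activation_time = tr$trace$t[i],
         cavity_pressure = tr$trace$P_lv[i]),
    class = "mechanical_state")
  ed <- mk_state(ied); es <- mk_state(ies)
  strain <- strain_at_locations(ed, es, sc$context)
  stress <- myofiber_stress_summary(es, context = sc$context)
  disp <- apex_and_root_displacement(tr)
  wall <- c(ED = wall_volume(ed, sc$context), ES = wall_volume(es, sc$context))
  structure(list(scenario = config$scenario, trace = tr, metrics = metrics,
                 strain = strain, stress = stress, displacement = disp,
                 wall_volumes = wall, ed_state = ed, es_state = es,
                 config = config, context = sc$context),
            class = "scenario_result")
}

#' Compare the three scenarios in the published table layout
#'
#' Builds the absolute and percent-change tables: pressure/volume metrics,
#' average strain by direction, regional longitudinal strain and myofiber
#' stress, with percent change defined as
#' `100 * (variant - baseline) / baseline`.
#'
#' @param result_a,result_b,result_c [run_scenario()] results for the
#'   elastic-aorta baseline, the stiff aorta and the stiff aorta with freed
#'   apex.
#' @return list of data.frames `pv`, `strain`, `regional`, `stress`.
#' @export
run_comparison <- function(result_a, result_b, result_c) {
  res <- list(result_a, result_b, result_c)
  if (any(vapply(res, is.null, TRUE)))
    stop("all three scenario results (A, B, C) are required")
  labs <- c("baseline", "stiff_AA", "stiff_AA_free_apex")
  pv_row <- function(r) with(r$metrics, c(EDP = EDP, EDV = EDV, ESP = ESP,
                                          ESV = ESV, SV = SV, SW = SW))
  pv <- do.call(rbind, lapply(res, pv_row))
  rownames(pv) <- labs
  pv_pct <- rbind(
    baseline_vs_stiff = percent_change(pv[1, ], pv[2, ]),
    baseline_vs_free_apex = percent_change(pv[1, ], pv[3, ]))

  dir_means <- function(r) {
    s <- r$strain$summary
    stats::setNames(s$mean, s$direction)[c("radial", "circumferential",
                                           "longitudinal")]
  }
  st <- do.call(rbind, lapply(res, dir_means))
  rownames(st) <- labs
  st_pct <- rbind(baseline_vs_stiff = percent_change(st[1, ], st[2, ]),
                  baseline_vs_free_apex = percent_change(st[1, ], st[3, ]))

  reg_means <- function(r) stats::setNames(r$strain$regional$mean,
                                           r$strain$regional$sector)
  reg <- round(do.call(rbind, lapply(res, reg_means)), 2)
  rownames(reg) <- labs
  reg_pct <- rbind(baseline_vs_stiff = percent_change(reg[1, ], reg[2, ]),
                   baseline_vs_free_apex = percent_change(reg[1, ], reg[3, ]))

  stress_b <- myofiber_stress_summary(res[[2]]$stress$field,
                                      res[[2]]$stress$weights,
                                      reference = res[[1]]$stress)
  stress_c <- myofiber_stress_summary(res[[3]]$stress$field,
                                      res[[3]]$stress$weights,
                                      reference = res[[1]]$stress)
  stress <- data.frame(
    mean_MPa = vapply(res, function(r) r$stress$mean, 0),
    sd_MPa = vapply(res, function(r) r$stress$sd, 0),
    pct_vs_baseline = c(NA, stress_b$pct_mean, stress_c$pct_mean),
    pct_sd = c(NA, stress_b$pct_sd, stress_c$pct_sd),
    row.names = labs)

  list(pv = as.data.frame(pv), pv_percent = as.data.frame(pv_pct),
       strain = as.data.frame(st), strain_percent = as.data.frame(st_pct),
       regional = as.data.frame(reg),
       regional_percent = as.data.frame(reg_pct),
       stress = stress)
}

#' Run the full three-scenario study
#'
#' Calibrates the baseline, runs scenarios A, B and C under the identical
#' calibrated parameter set (only the aortic stiffness and the freed-apex
#' flag differ) and assembles the comparison tables.
#'
#' @param base_config a scenario-A [scenario_config()] used as the template.
#' @param calibration optional pre-computed [calibrate_baseline()] result.
#' @param progress print progress messages.
#' @return list with `calibration`, `results` (named list A/B/C) and
#'   `tables` ([run_comparison()] output).
#' @export
run_study <- function(base_config = scenario_config("A"), calibration = NULL,
                      progress = FALSE) {
  if (is.null(calibration))
    calibration <- calibrate_baseline(base_config, progress = progress)
  cfg_of <- function(id) {
    cfg <- base_config
    cfg$scenario <- id
    cfg$aortic_stiffness <- .scenario_table[[id]]$aortic_stiffness
    cfg$freed_fraction <- .scenario_table[[id]]$freed_fraction
    cfg
  }
  results <- list()
  for (id in c("A", "B", "C")) {
    if (progress) message("running scenario ", id)
    init <- if (id == "A") calibration$init else NULL
    results[[id]] <- run_scenario(cfg_of(id), calibration, init = init)
  }
  list(calibration = calibration, results = results,
       tables = run_comparison(results$A, results$B, results$C))
}
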