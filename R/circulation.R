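# Closed-loop lumped-parameter hemodynamics: left atrium, diode-resistor
# mitral and aortic valves, two-element Windkessel arterial load, and a
# lumped venous/pulmonary return compartment. Volumes in mL, pressures in
# mmHg, resistances in mmHg s/mL, compliances in mL/mmHg.

#' Circulation parameters
#'
#' @param R_mv,R_av mitral and aortic valve resistances (mmHg s/mL).
#' @param C_art arterial compliance (mL/mmHg).
#' @param R_sys systemic resistance (mmHg s/mL).
#' @param C_ven venous (pulmonary return) compliance (mL/mmHg).
#' @param R_ven venous return resistance into the atrium (mmHg s/mL).
#' @param C_la left-atrial passive compliance (mL/mmHg).
#' @param booster_amplitude optional atrial booster pump amplitude (mmHg);
#'   0 disables the booster (default).
#' @param booster_onset,booster_duration timing of the booster pressure bump
#'   relative to ventricular activation onset (s); the default places it
#'   just before activation.
#' @param V0_la,V0_art,V0_ven unstressed compartment volumes (mL).
#' @param V_total total blood volume of the closed loop (mL), including the
#'   ventricular cavity.
#' @param cycle_length cardiac cycle duration (s).
#' @return object of class `circulation_params`.
#' @export
circulation_params <- function(R_mv = 0.02, R_av = 0.015, C_art = 1.8,
                               R_sys = 1.03, C_ven = 40, R_ven = 0.05,
                               C_la = 8, booster_amplitude = 0,
                               booster_onset = -0.1, booster_duration = 0.1,
                               V0_la = 40, V0_art = 300, V0_ven = 2000,
                               V_total = 3000, cycle_length = 1.0) {
  stopifnot(R_mv > 0, R_av > 0, C_art > 0, R_sys > 0, C_ven > 0, R_ven > 0,
            C_la > 0, V_total > 0, cycle_length > 0)
  structure(as.list(environment()), class = "circulation_params")
}

.p_la <- function(V_la, t_beat, params) {
  p <- (V_la - params$V0_la) / params$C_la
  if (params$booster_amplitude > 0) {
    tb <- t_beat - params$booster_onset
    if (tb > 0 && tb < params$booster_duration)
      p <- p + params$booster_amplitude * sin(pi * tb / params$booster_duration)
  }
  p
}

#' Initialize the circulation state
#'
#' Distributes the total blood volume over the compartments at plausible
#' starting pressures; the remainder (after the ventricular cavity) fills
#' the venous compartment.
#'
#' @param params a [circulation_params()].
#' @param v_lv initial ventricular cavity volume (mL).
#' @param p_art,p_la starting arterial and atrial pressures (mmHg).
#' @return object of class `circulation_state` with compartment volumes,
#'   pressures, valve flags and flows.
#' @export
init_circulation <- function(params, v_lv, p_art = 90, p_la = 10) {
  V_la <- params$V0_la + params$C_la * p_la
  V_art <- params$V0_art + params$C_art * p_art
  V_ven <- params$V_total - v_lv - V_la - V_art
  if (V_ven <= params$V0_ven * 0.1)
    stop("total blood volume too small for the requested initial pressures")
  structure(list(V_la = V_la, V_art = V_art, V_ven = V_ven, V_lv = v_lv,
                 t_beat = 0,
                 P_la = p_la, P_art = p_art,
                 P_ven = (V_ven - params$V0_ven) / params$C_ven,
                 mv_open = FALSE, av_open = FALSE,
                 Q_mv = 0, Q_av = 0),
            class = "circulation_state")
}

#' Advance the circulation by one explicit step
#'
#' Diode-resistor valve flows `Q = max(0, dP) / R`, conservative explicit
#' volume updates and compliance pressure relations. The sum of all
#' compartment volumes (including the ventricle) is conserved exactly.
#'
#' @param state a `circulation_state`.
#' @param lv_pressure current ventricular pressure (mmHg).
#' @param dt time step (s), positive.
#' @param params a [circulation_params()].
#' @return updated `circulation_state`; elements `Q_mv` and `Q_av` carry the
#'   mitral (LV inflow) and aortic (LV outflow) flows in mL/s.
#' @export
step_circulation <- function(state, lv_pressure, dt, params) {
  stopifnot(dt > 0)
  P_la <- .p_la(state$V_la, state$t_beat, params)
  P_art <- (state$V_art - params$V0_art) / params$C_art
  P_ven <- (state$V_ven - params$V0_ven) / params$C_ven
  Q_mv <- max(0, P_la - lv_pressure) / params$R_mv
  Q_av <- max(0, lv_pressure - P_art) / params$R_av
  Q_sys <- (P_art - P_ven) / params$R_sys
  Q_ven <- (P_ven - P_la) / params$R_ven
  state$V_la <- state$V_la + dt * (Q_ven - Q_mv)
  state$V_art <- state$V_art + dt * (Q_av - Q_sys)
  state$V_ven <- state$V_ven + dt * (Q_sys - Q_ven)
  state$V_lv <- state$V_lv + dt * (Q_mv - Q_av)
  if (min(state$V_la, state$V_art, state$V_ven, state$V_lv) < 0)
    stop("negative compartment volume: circulation time step too large")
  state$t_beat <- state$t_beat + dt
  state$P_la <- .p_la(state$V_la, state$t_beat, params)
  state$P_art <- (state$V_art - params$V0_art) / params$C_art
  state$P_ven <- (state$V_ven - params$V0_ven) / params$C_ven
  state$mv_open <- Q_mv > 0
  state$av_open <- Q_av > 0
  state$Q_mv <- Q_mv
  state$Q_av <- Q_av
  state
}

.total_volume <- function(state) state$V_la + state$V_art + state$V_ven + state$V_lv

#' Run the coupled heart-circulation model to a limit cycle
#'
#' Volume-driven staggered coupling: at each mechanical step the equilibrium
#' cavity pressure for the current ventricular volume is solved at the
#' current activation time, then the circulation is advanced with explicit
#' sub-steps using a local-elastance pressure predictor. Beats repeat until
#' the stroke volume changes by less than `sv_tol` between successive beats
#' (limit cycle) or `max_beats` is reached; the last beat's trace is
#' returned.
#'
#' @param context a [mechanics_context()].
#' @param params a [circulation_params()].
#' @param dt_mech mechanical step (s).
#' @param dt_circ maximum circulation sub-step (s).
#' @param max_beats maximum number of beats.
#' @param sv_tol relative stroke-volume drift defining the limit cycle.
#' @param init optional list with elements `circulation`
#'   (a `circulation_state`) and `state` (a `mechanical_state`) to resume
#'   from a previous run.
#' @param progress logical; print per-beat summaries.
#' @return object of class `beat_trace`: data.frame `trace` with per-step
#'   time, ventricular/arterial/atrial/venous pressures (mmHg), ventricular
#'   volume (mL), valve flows (mL/s), axial root and apex displacement (mm,
#'   positive toward the base); the per-step mode matrix `Q`; end-diastolic
#'   and end-systolic step indices; convergence information and the final
#'   circulation and mechanical states.
#' @export
run_coupled_beat <- function(context, params, dt_mech = 0.01,
                             dt_circ = 0.001, max_beats = 10, sv_tol = 0.01,
                             init = NULL, progress = FALSE) {
  n_steps <- round(params$cycle_length / dt_mech)
  stopifnot(n_steps >= 20)
  rho_root <- context$geom$root_offset
  stj_ratio <- if (!is.null(context$aortic)) context$aortic$stj_ratio else 1
  # initial diastolic state: passive ventricle at a venous filling pressure
  if (is.null(init)) {
    mstate <- solve_equilibrium(context, 10, -1)
    cstate <- init_circulation(params, mstate$cavity_volume)
  } else {
    mstate <- init$state
    cstate <- init$circulation
    cstate$t_beat <- 0
  }
  sv_prev <- NA; sv_hist <- numeric(0)
  converged <- FALSE
  trace <- NULL; Qmat <- NULL
  vol_drift <- 0
  for (beat in seq_len(max_beats)) {
    cstate$t_beat <- 0
    v_tot0 <- .total_volume(cstate)
    rows <- vector("list", n_steps)
    Qmat <- matrix(0, n_steps, context$n_modes)
    p_prev <- mstate$cavity_pressure; v_prev <- mstate$cavity_volume
    E_est <- 1
    for (i in seq_len(n_steps)) {
      t <- (i - 1) * dt_mech
      # the atrial pressure above the valve plane counteracts the cavity
      # pressure acting on the basal cap
      mstate <- pressure_for_volume(cstate$V_lv, context,
                                    activation_time = t, state0 = mstate,
                                    base_counter_pressure = cstate$P_la)
      p_lv <- mstate$cavity_pressure
      # local chamber elastance from the constrained mechanical solve
      E_est <- if (is.finite(mstate$elastance))
        min(max(mstate$elastance, 0.02), 30) else E_est
      p_prev <- p_lv; v_prev <- mstate$cavity_volume
      rows[[i]] <- data.frame(
        t = t, P_lv = p_lv, V_lv = cstate$V_lv, P_art = cstate$P_art,
        P_la = cstate$P_la, P_ven = cstate$P_ven,
        Q_mv = cstate$Q_mv, Q_av = cstate$Q_av,
        x_root = (mstate$q[6] - mstate$q[8] * rho_root) * stj_ratio,
        x_apex = mstate$q[5] - mstate$q[9])
      Qmat[i, ] <- mstate$q
      n_sub <- ceiling(dt_mech / dt_circ)
      dt_s <- dt_mech / n_sub
      for (s in seq_len(n_sub)) {
        p_sub <- p_lv + E_est * (cstate$V_lv - v_prev)
        cstate <- step_circulation(cstate, p_sub, dt_s, params)
      }
    }
    trace <- do.call(rbind, rows)
    vol_drift <- abs(.total_volume(cstate) - v_tot0)
    sv <- max(trace$V_lv) - min(trace$V_lv)
    sv_hist <- c(sv_hist, sv)
    if (progress)
      message(sprintf("beat %d: EDV %.1f ESV %.1f SV %.1f MAP %.1f EDP %.2f",
                      beat, max(trace$V_lv), min(trace$V_lv), sv,
                      mean(trace$P_art), trace$P_lv[which.max(trace$V_lv)]))
    if (!is.na(sv_prev) && abs(sv - sv_prev) < sv_tol * max(sv, 1e-9)) {
      converged <- TRUE
      break
    }
    sv_prev <- sv
  }
  if (!converged)
    warning("no limit cycle within max_beats; returning the last beat")
  structure(list(trace = trace, Q = Qmat,
                 ed_index = which.max(trace$V_lv),
                 es_index = which.min(trace$V_lv),
                 dt_mech = dt_mech, converged = converged,
                 beats = length(sv_hist), sv_history = sv_hist,
                 volume_drift = vol_drift,
                 final_circulation = cstate, final_state = mstate),
            class = "beat_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beat_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "beat_trace: %d steps, %d beat(s)%s\n", nrow(tr), x$beats,
    if (x$converged) ", limit cycle" else " (not converged)"))
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL, SV %.1f mL, MAP %.1f mmHg\n",
              max(tr$V_lv), min(tr$V_lv), max(tr$V_lv) - min(tr$V_lv),
              mean(tr$P_art)))
  invisible(x)
}
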