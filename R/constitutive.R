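# Passive (Holzapfel-Ogden) and active (time-varying elastance) myocardium.
# Unit system: mm, s, N, MPa (= N/mm^2), mM.  1 mmHg = 1.33322e-4 MPa.

#' Unit conversion between mmHg and MPa
#'
#' Pressures are handled in mmHg at the interfaces of the package and in MPa
#' (N/mm^2) inside the mechanics kernel.
#'
#' @param p pressure value(s).
#' @return converted pressure value(s).
#' @export
mmHg_to_MPa <- function(p) p * 1.33322e-4

#' @rdname mmHg_to_MPa
#' @export
MPa_to_mmHg <- function(p) p / 1.33322e-4

#' Passive myocardial material parameters
#'
#' Parameter set of the orthotropic Holzapfel-Ogden strain-energy function
#' with an added quadratic volumetric penalty enforcing near-incompressibility.
#' Defaults are the calibrated human-ventricle values (stress-like moduli in
#' MPa, exponents dimensionless).
#'
#' @param a,b isotropic modulus (MPa) and exponent.
#' @param a_f,b_f fiber modulus (MPa) and exponent.
#' @param a_s,b_s sheet modulus (MPa) and exponent.
#' @param a_fs,b_fs fiber-sheet shear modulus (MPa) and exponent.
#' @param kappa volumetric penalty modulus (MPa). Must exceed
#'   `10 * max(a, a_f)`; the default keeps the myocardial volume change
#'   between end-diastole and end-systole below 2%.
#' @return object of class `passive_params`.
#' @export
passive_params <- function(a = 3.9e-4, b = 3.7,
                           a_f = 1.9e-3, b_f = 14.0,
                           a_s = 1.1e-3, b_s = 11.0,
                           a_fs = 3.6e-7, b_fs = 7e-4,
                           kappa = 5) {
  stopifnot(a >= 0, a_f >= 0, a_s >= 0, a_fs >= 0,
            b > 0, b_f > 0, b_s > 0, b_fs > 0)
  if (kappa < 10 * max(a, a_f))
    stop("kappa must be at least 10x the largest stress-like modulus ",
         "(near-incompressibility)")
  structure(list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
                 a_fs = a_fs, b_fs = b_fs, kappa = kappa),
            class = "passive_params")
}

#' Atrial passive parameter set
#'
#' Passive moduli used for the (lumped) left atrium; retained for reference
#' and for the atrial compliance estimate of the circulation module.
#'
#' @inheritParams passive_params
#' @return object of class `passive_params`.
#' @export
passive_params_atrium <- function(kappa = 5) {
  passive_params(a = 1.0e-3, b = 3.1, a_f = 4.7e-3, b_f = 12.0,
                 a_s = 2.7e-3, b_s = 9.1, a_fs = 9.0e-7, b_fs = 6.7e-4,
                 kappa = kappa)
}

#' Active contraction parameters (time-varying elastance)
#'
#' Length-dependent active fiber stress parameters. Sarcomere lengths are
#' carried in mm (`l_0 = 0.00158` mm is 1.58 um). `b_relax` is the intercept
#' of the linear relaxation-duration law `tr(l) = m * l + b_relax`; it is
#' named `b_relax` to avoid a collision with the passive exponent `b`.
#'
#' @param T_max maximum isometric tension at the longest sarcomere length
#'   (MPa); the contractility scalar.
#' @param Ca_0 peak intracellular calcium concentration (mM).
#' @param Ca_0max maximum peak intracellular calcium concentration (mM).
#' @param B shape coefficient of the tension/sarcomere-length relation (1/mm).
#' @param l_0 sarcomere length below which no active force develops (mm).
#' @param l_r initial (resting) sarcomere length (mm).
#' @param t_0 time to peak tension (s).
#' @param m,b_relax slope (s/mm) and intercept (s) of the relaxation-duration
#'   law.
#' @param sheet_fraction fraction of the active fiber stress also applied in
#'   the sheet direction (dimensionless, default 0: fiber only).
#' @return object of class `active_params`.
#' @export
active_params <- function(T_max = 0.2, Ca_0 = 4.35, Ca_0max = 4.35,
                          B = 4750, l_0 = 0.00158, l_r = 0.00185,
                          t_0 = 0.35, m = 950, b_relax = -1.5,
                          sheet_fraction = 0) {
  stopifnot(T_max >= 0, l_0 > 0, l_r > l_0, t_0 > 0,
            sheet_fraction >= 0, sheet_fraction <= 1)
  if (m * l_r + b_relax <= 0)
    stop("relaxation duration tr(l_r) = m*l_r + b_relax must be positive")
  structure(list(T_max = T_max, Ca_0 = Ca_0, Ca_0max = Ca_0max, B = B,
                 l_0 = l_0, l_r = l_r, t_0 = t_0, m = m, b_relax = b_relax,
                 sheet_fraction = sheet_fraction),
            class = "active_params")
}

#' Kinematic state at a material point
#'
#' Wraps a deformation gradient together with the local fiber/sheet frame and
#' computes the deformation invariants used by the constitutive laws.
#'
#' @param F deformation gradient, 3x3 matrix with positive determinant.
#' @param f0 reference unit fiber direction (length-3).
#' @param s0 reference unit sheet direction (length-3), orthogonal to `f0`.
#' @return object of class `kinematics_state` with elements `F`, `J`, `C`,
#'   `I1`, `I4f`, `I4s`, `I8fs`, `E_ff`, `f0`, `s0`.
#' @export
kinematics_state <- function(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("deformation gradient must have det(F) > 0")
  C <- crossprod(F)           # F^T F
  I1 <- sum(diag(C))
  I4f <- drop(f0 %*% C %*% f0)
  I4s <- drop(s0 %*% C %*% s0)
  I8fs <- drop(f0 %*% C %*% s0)
  structure(list(F = F, J = J, C = C, I1 = I1, I4f = I4f, I4s = I4s,
                 I8fs = I8fs, E_ff = (I4f - 1) / 2, f0 = f0, s0 = s0),
            class = "kinematics_state")
}

#' Deviatoric strain-energy density of passive myocardium
#'
#' Holzapfel-Ogden orthotropic energy
#' `a/(2b) exp(b (I1bar - 3)) + sum_i a_i/(2 b_i) (exp(b_i (I4i - 1)^2) - 1)
#'  + a_fs/(2 b_fs) (exp(b_fs I8fs^2) - 1)`
#' with the standard tension-only convention (the fiber and sheet terms
#' contribute only when the corresponding squared stretch exceeds one) and
#' the isotropic term acting on the isochoric invariant
#' `I1bar = J^(-2/3) I1`, so that the reference state is exactly
#' stress-free; volumetric response lives entirely in the penalty term.
#'
#' @param state a [kinematics_state()].
#' @param p a [passive_params()] set.
#' @return strain-energy density (MPa).
#' @export
psi_dev <- function(state, p) {
  with(state, {
    if (!all(is.finite(c(I1, I4f, I4s, I8fs)))) stop("non-finite invariants")
    e4f <- max(I4f - 1, 0)
    e4s <- max(I4s - 1, 0)
    I1bar <- J^(-2 / 3) * I1
    p$a / (2 * p$b) * exp(p$b * (I1bar - 3)) +
      p$a_f / (2 * p$b_f) * (exp(p$b_f * e4f^2) - 1) +
      p$a_s / (2 * p$b_s) * (exp(p$b_s * e4s^2) - 1) +
      p$a_fs / (2 * p$b_fs) * (exp(p$b_fs * I8fs^2) - 1)
  })
}

#' Volumetric penalty energy
#'
#' Quadratic penalty `kappa/2 (J - 1)^2` enforcing near-incompressibility.
#'
#' @inheritParams psi_dev
#' @return energy density (MPa).
#' @export
psi_vol <- function(state, p) p$kappa / 2 * (state$J - 1)^2

#' Passive stress tensors
#'
#' Analytic differentiation of the deviatoric energy plus the volumetric
#' penalty. Returns the second Piola-Kirchhoff stress and the corresponding
#' Cauchy stress.
#'
#' @inheritParams psi_dev
#' @return list with symmetric 3x3 matrices `S` (second Piola-Kirchhoff, MPa)
#'   and `sigma` (Cauchy, MPa).
#' @export
passive_stress <- function(state, p) {
  F <- state$F
  J <- state$J
  if (J <= 0) stop("inverted state: det(F) <= 0")
  f0 <- state$f0; s0 <- state$s0
  I <- diag(3)
  Cinv <- solve(state$C)
  I1bar <- J^(-2 / 3) * state$I1
  S <- p$a * exp(p$b * (I1bar - 3)) * J^(-2 / 3) *
    (I - state$I1 / 3 * Cinv)
  e4f <- state$I4f - 1
  if (e4f > 0)
    S <- S + 2 * p$a_f * e4f * exp(p$b_f * e4f^2) * tcrossprod(f0)
  e4s <- state$I4s - 1
  if (e4s > 0)
    S <- S + 2 * p$a_s * e4s * exp(p$b_s * e4s^2) * tcrossprod(s0)
  i8 <- state$I8fs
  S <- S + p$a_fs * i8 * exp(p$b_fs * i8^2) *
    (tcrossprod(f0, s0) + tcrossprod(s0, f0))
  # volumetric: d(kappa/2 (J-1)^2)/dE = kappa (J-1) J C^{-1}
  S <- S + p$kappa * (J - 1) * J * Cinv
  S <- (S + t(S)) / 2
  sigma <- F %*% S %*% t(F) / J
  list(S = S, sigma = (sigma + t(sigma)) / 2)
}

#' Effective sarcomere length
#'
#' `l_eff = l_r * sqrt(2 E_ff + 1)` where `E_ff` is the Lagrangian strain
#' along the local fiber direction.
#'
#' @param E_ff fiber Lagrangian strain (dimensionless).
#' @param p an [active_params()] set.
#' @return effective sarcomere length (mm).
#' @export
eff_sarcomere_length <- function(E_ff, p) {
  if (any(2 * E_ff + 1 <= 0))
    stop("non-physical fiber compression: 2*E_ff + 1 must be positive")
  p$l_r * sqrt(2 * E_ff + 1)
}

#' Length-dependent calcium sensitivity
#'
#' `ECa50 = Ca_0max / sqrt(exp(B (l_eff - l_0)) - 1)`. For `l_eff <= l_0`
#' the sensitivity is unbounded (`Inf`), which downstream yields zero active
#' force: `l_0` is the sarcomere length below which no force develops.
#'
#' @param l_eff effective sarcomere length (mm); may be a vector.
#' @inheritParams eff_sarcomere_length
#' @return calcium sensitivity (mM), `Inf` where `l_eff <= l_0`.
#' @export
eca50 <- function(l_eff, p) {
  den2 <- exp(p$B * (l_eff - p$l_0)) - 1
  out <- rep(Inf, length(l_eff))
  pos <- den2 > 0
  out[pos] <- p$Ca_0max / sqrt(den2[pos])
  out
}

#' Relaxation duration of the active twitch
#'
#' Linear law `tr(l) = m * l + b_relax` in the effective sarcomere length.
#'
#' @inheritParams eca50
#' @return relaxation duration (s).
#' @export
relaxation_duration <- function(l_eff, p) p$m * l_eff + p$b_relax

#' Active fiber stress
#'
#' Time-varying-elastance active stress
#' `sigma_a = T_max/2 * Ca_0^2 / (Ca_0^2 + ECa50^2) * (1 - cos(omega))`
#' with the phase `omega = pi t / t_0` during contraction
#' (`0 <= t <= t_0`), `omega = pi (t - t_0 + tr) / tr` during relaxation
#' (`t_0 <= t <= t_0 + tr`) and zero afterwards, where `tr` is the
#' length-dependent relaxation duration. Vectorized over `t` and `E_ff`.
#'
#' @param t time since activation onset (s), `t >= 0`.
#' @param E_ff fiber Lagrangian strain (dimensionless).
#' @inheritParams eff_sarcomere_length
#' @return active fiber stress (MPa), always non-negative.
#' @export
active_fiber_stress <- function(t, E_ff, p) {
  stopifnot(all(t >= 0))
  n <- max(length(t), length(E_ff))
  t <- rep_len(t, n); E_ff <- rep_len(E_ff, n)
  l_eff <- eff_sarcomere_length(E_ff, p)
  tr <- relaxation_duration(l_eff, p)
  e50 <- eca50(l_eff, p)
  amp <- p$T_max / 2 * p$Ca_0^2 / (p$Ca_0^2 + e50^2)
  # below l_0 no active force develops (ECa50 unbounded); the relaxation
  # duration only matters where force exists
  amp[!is.finite(e50) | l_eff <= p$l_0] <- 0
  if (any(tr <= 0 & amp > 0))
    stop("relaxation duration tr(l_eff) must be positive where force develops")
  omega <- numeric(n)
  contr <- t <= p$t_0
  omega[contr] <- pi * t[contr] / p$t_0
  relax <- !contr & t <= p$t_0 + tr & amp > 0
  omega[relax] <- pi * (t[relax] - p$t_0 + tr[relax]) / tr[relax]
  amp * (1 - cos(omega))
}

#' Single-beat empirical end-diastolic pressure-volume relationship
#'
#' Rescales the empirical normalized EDPVR `P = An * Vn^Bn` through one
#' measured pressure-volume pair `(p_m, v_m)`. The zero-pressure volume is
#' estimated as `V0 = v_m (0.6 - 0.006 p_m)` and the 30 mmHg volume from the
#' measured pair, so the predicted curve passes through the anchor exactly.
#' Used as a calibration check that passive inflation of the synthetic
#' ventricle tracks the empirical diastolic filling shape.
#'
#' @param volume_samples volumes at which to evaluate the curve (mL).
#' @param p_m,v_m measured end-diastolic pressure (mmHg) and volume (mL).
#' @param An,Bn empirical curve constants (configuration, not hard-coded
#'   physiology).
#' @return data.frame with columns `volume` (mL) and `pressure` (mmHg);
#'   attributes `V0` and `V30` carry the estimated zero-pressure and
#'   30 mmHg volumes.
#' @export
klotz_edpvr <- function(volume_samples, p_m, v_m, An = 28.2, Bn = 2.79) {
  stopifnot(p_m > 0, v_m > 0)
  V0 <- v_m * (0.6 - 0.006 * p_m)
  V30 <- V0 + (v_m - V0) / (p_m / An)^(1 / Bn)
  Vn <- pmax((volume_samples - V0) / (V30 - V0), 0)
  structure(data.frame(volume = volume_samples, pressure = An * Vn^Bn),
            V0 = V0, V30 = V30)
}
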