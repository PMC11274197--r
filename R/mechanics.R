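# Quasi-static wall mechanics: reduced-kinematics continuum model.
#
# The deformed configuration of the truncated-ellipsoid wall is described by
# a small set of smooth deformation modes. Equilibrium is the minimizer of
# the total potential energy
#   Pi(q) = int(Psi_dev + Psi_vol + sigma_a * E_ff) dV
#           - p * V_cavity(q) + sum springs 1/2 k ext^2
# evaluated by Gauss quadrature over the wall; the active stress is lagged
# (updated once per Newton iteration) to handle the length dependence of the
# elastance model. Volume-driven solves treat (q, p) as a saddle system with
# the cavity-volume constraint.
#
# Mode vector q (lv family). The radial kinematics follow the exact
# volume-conserving thick-wall rule: within each material slab at reference
# height z0, the deformed squared radius is
#   rho'^2 = Pi2(z0) (1 + W(zhat)) + (rho^2 - Pi2(z0)) / lambda_z(zhat)
# where Pi2 is the squared endocardial radius of the slab, W the endocardial
# inflation profile and lambda_z the axial stretch of the slab, so the
# axisymmetric part of the map has det(F) = 1 identically and the volumetric
# penalty only acts on the small dedicated compressibility mode.
#   q[1] A0    uniform endocardial inflation (rho_i'^2 = rho_i^2 (1 + W))
#   q[2] A1    apical taper of the inflation, ~ (1 - zhat)
#   q[3] A2    mid-wall bulge of the inflation, ~ sin(pi * zhat)
#   q[4] B1    transmural compressibility mode (penalized, J ~ 1 + B1 (u - 1/2))
#   q[5] u_apex  axial translation of the apex (mm)
#   q[6] u_base  axial translation of the basal plane center (mm)
#   q[7] c4    axial bulge ~ sin(pi * zhat) (mm)
#   q[8] beta  tilt of the basal plane about the in-plane axis normal to the
#              septal direction (rad, linearized); the basal ring remains
#              planar and circular, twist about the long axis is suppressed
#   q[9] A_cap axial thickening of the apical cap (mm): the epicardial apex
#              moves away from the base relative to the interior wall
#
# Sphere family (verification configuration): q = (alpha, e1, e2) with
# r^3 = R^3 + alpha (incompressible inflation) times a small transmural
# correction (1 + e1 u + e2 u^2).

.lv_scales <- c(0.3, 0.3, 0.3, 0.02, 5, 5, 2, 0.2, 2)
.sphere_scales <- c(1e4, 0.05, 0.05)

# precomputed reference-geometry arrays for a fixed set of material points
.precompute_points <- function(geom, family, u, th, ph) {
  r <- .geom_r(geom, u); cc <- .geom_c(geom, u)
  rho0 <- r * sin(th); z0 <- cc * cos(th)
  pre <- list(n = length(u), u = u,
              cosph = cos(ph), sinph = sin(ph),
              rho0 = rho0, z0 = z0)
  if (family == "sphere") {
    R <- sqrt(rho0^2 + z0^2)
    pre$R3 <- R^3
    pre$u2 <- u^2
    pre$X1 <- rho0 * pre$cosph; pre$X2 <- rho0 * pre$sinph; pre$X3 <- z0
  } else {
    H <- geom$z_base + geom$c_epi
    zh <- (z0 + geom$c_epi) / H
    pre$invH <- 1 / H
    pre$zh <- zh
    pre$omz <- 1 - zh
    pre$sinpz <- sin(pi * zh)
    pre$picos <- pi * cos(pi * zh) / H
    pre$Pi2 <- geom$a_endo^2 * pmax(1 - z0^2 / geom$c_endo^2, 0)
    pre$rz <- rho0^2 - pre$Pi2
    pre$um05 <- u - 0.5
    cosd <- cos(ph - geom$septal_azimuth)
    pre$tiltz <- rho0 * cosd * zh
    # partial axial derivative of the tilt field at fixed (rho, phi)
    pre$tiltl <- cosd * rho0 / H
    # apical-cap thickening shape (gaussian in zhat) and its axial derivative
    pre$capz <- exp(-(zh / 0.1)^2)
    pre$capl <- (2 * zh / 0.01) * pre$capz / H
  }
  pre
}

# deformed positions at precomputed points; q1..qd are per-point vectors
.map_pre <- function(pre, family, qr) {
  if (family == "sphere") {
    s <- (pmax(pre$R3 + qr[[1]], 1e-9) / pre$R3)^(1 / 3) *
      (1 + qr[[2]] * pre$u + qr[[3]] * pre$u2)
    return(list(x = pre$X1 * s, y = pre$X2 * s, z = pre$X3 * s))
  }
  lz <- 1 + (qr[[6]] - qr[[5]]) * pre$invH + qr[[7]] * pre$picos -
    qr[[8]] * pre$tiltl + qr[[9]] * pre$capl
  W <- qr[[1]] + qr[[2]] * pre$omz + qr[[3]] * pre$sinpz
  rho2 <- pre$Pi2 * (1 + W) + pre$rz / lz * (1 + qr[[4]] * pre$um05)
  rho2[rho2 <= 0 | lz <= 0] <- NaN
  rho <- sqrt(rho2)
  z <- pre$z0 + qr[[5]] * pre$omz + qr[[6]] * pre$zh + qr[[7]] * pre$sinpz -
    qr[[8]] * pre$tiltz - qr[[9]] * pre$capz
  list(x = rho * pre$cosph, y = rho * pre$sinph, z = z)
}

# generic (non-precomputed) deformed-point evaluation, batched mode columns
.map_points <- function(ctx, u, th, ph, qp) {
  pre <- .precompute_points(ctx$geom, ctx$family, u, th, ph)
  qr <- lapply(seq_len(ctx$n_modes), function(r) qp[r, ])
  if (ctx$family == "sphere") qr <- qr[1:3]
  m <- .map_pre(pre, ctx$family, qr)
  cbind(m$x, m$y, m$z)
}

# 3x3 determinant / inverse on row-wise component matrices (L x 9, columns
# m11, m12, m13, m21, ..., m33)
.det3 <- function(M) {
  M[, 1] * (M[, 5] * M[, 9] - M[, 6] * M[, 8]) -
    M[, 2] * (M[, 4] * M[, 9] - M[, 6] * M[, 7]) +
    M[, 3] * (M[, 4] * M[, 8] - M[, 5] * M[, 7])
}

.inv3 <- function(M) {
  d <- .det3(M)
  cbind((M[, 5] * M[, 9] - M[, 6] * M[, 8]) / d,
        (M[, 3] * M[, 8] - M[, 2] * M[, 9]) / d,
        (M[, 2] * M[, 6] - M[, 3] * M[, 5]) / d,
        (M[, 6] * M[, 7] - M[, 4] * M[, 9]) / d,
        (M[, 1] * M[, 9] - M[, 3] * M[, 7]) / d,
        (M[, 3] * M[, 4] - M[, 1] * M[, 6]) / d,
        (M[, 4] * M[, 8] - M[, 5] * M[, 7]) / d,
        (M[, 2] * M[, 7] - M[, 1] * M[, 8]) / d,
        (M[, 1] * M[, 5] - M[, 2] * M[, 4]) / d)
}

# parametric Jacobian d(x)/d(u, th, ph) by central differences (setup only)
.param_jacobian <- function(ctx, u, th, ph, qp, delta = 1e-5) {
  J <- matrix(0, length(u), 9)
  for (k in 1:3) {
    du <- dth <- dph <- 0
    if (k == 1) du <- delta else if (k == 2) dth <- delta else dph <- delta
    xp <- .map_points(ctx, u + du, th + dth, ph + dph, qp)
    xm <- .map_points(ctx, u - du, th - dth, ph - dph, qp)
    J[, c(k, k + 3, k + 6)] <- (xp - xm) / (2 * delta)
  }
  J
}

# right Cauchy-Green components and invariants from F rows
.invariants <- function(F, f0, s0) {
  C11 <- F[, 1]^2 + F[, 4]^2 + F[, 7]^2
  C22 <- F[, 2]^2 + F[, 5]^2 + F[, 8]^2
  C33 <- F[, 3]^2 + F[, 6]^2 + F[, 9]^2
  C12 <- F[, 1] * F[, 2] + F[, 4] * F[, 5] + F[, 7] * F[, 8]
  C13 <- F[, 1] * F[, 3] + F[, 4] * F[, 6] + F[, 7] * F[, 9]
  C23 <- F[, 2] * F[, 3] + F[, 5] * F[, 6] + F[, 8] * F[, 9]
  qf <- function(a, b) {
    a[, 1] * b[, 1] * C11 + a[, 2] * b[, 2] * C22 + a[, 3] * b[, 3] * C33 +
      (a[, 1] * b[, 2] + a[, 2] * b[, 1]) * C12 +
      (a[, 1] * b[, 3] + a[, 3] * b[, 1]) * C13 +
      (a[, 2] * b[, 3] + a[, 3] * b[, 2]) * C23
  }
  list(I1 = C11 + C22 + C33, I4f = qf(f0, f0), I4s = qf(s0, s0),
       I8fs = qf(f0, s0), J = .det3(F))
}

.psi_values <- function(inv, pp, act, idx, sheet_fraction = 0) {
  # smoothed tension-only gate (width ~1e-3 in I4): keeps the energy smooth
  # for the Newton solver; indistinguishable from the hard gate at physical
  # strains
  sgate <- function(x) 0.5 * (x + sqrt(x^2 + 1e-6))
  e4f <- sgate(inv$I4f - 1)
  e4s <- sgate(inv$I4s - 1)
  I1bar <- inv$J^(-2 / 3) * inv$I1
  psi <- pp$a / (2 * pp$b) * exp(pp$b * (I1bar - 3)) +
    pp$a_f / (2 * pp$b_f) * (exp(pp$b_f * e4f^2) - 1) +
    pp$a_s / (2 * pp$b_s) * (exp(pp$b_s * e4s^2) - 1) +
    pp$a_fs / (2 * pp$b_fs) * (exp(pp$b_fs * inv$I8fs^2) - 1) +
    pp$kappa / 2 * (inv$J - 1)^2
  # active fiber work, linearized about the current strain E0 so the Newton
  # model carries the length-dependence (Frank-Starling) tangent stiffness
  E_ff <- (inv$I4f - 1) / 2
  psi <- psi + act$sig[idx] * E_ff +
    0.5 * act$dsig[idx] * (E_ff - act$E0[idx])^2
  if (sheet_fraction > 0)
    psi <- psi + sheet_fraction * act$sig[idx] * ((inv$I4s - 1) / 2)
  psi
}

# expanded per-point mode rows for a batch: row r of Q indexed per point
.q_rows <- function(ctx, Q, n_pts) {
  m <- ncol(Q)
  key <- paste0("cid", n_pts, "_", m)
  cid <- ctx$cache[[key]]
  if (is.null(cid)) {
    cid <- rep(seq_len(m), each = n_pts)
    ctx$cache[[key]] <- cid
  }
  lapply(seq_len(ctx$n_modes), function(r) Q[r, ][cid])
}

# repeat precomputed point arrays for a batch of m columns (cached)
.pre_rep <- function(ctx, pre, tag, m) {
  if (m == 1) return(pre)
  key <- paste0(tag, "_m", m)
  out <- ctx$cache[[key]]
  if (is.null(out)) {
    idx <- rep(seq_len(pre$n), m)
    out <- lapply(pre, function(a) if (length(a) == pre$n) a[idx] else a)
    out$n <- pre$n * m
    ctx$cache[[key]] <- out
  }
  out
}

# deformation gradient rows (L x 9) at the wall Gauss points for a batch
.wall_F <- function(ctx, Q) {
  N <- ctx$gp$N
  m <- ncol(Q)
  qr <- .q_rows(ctx, Q, N)
  delta <- ctx$settings$delta_xi
  D <- vector("list", 6)
  for (k in 1:6) {
    pre <- .pre_rep(ctx, ctx$sten$wall[[k]], paste0("w", k), m)
    D[[k]] <- .map_pre(pre, ctx$family, qr)
  }
  Jd <- matrix(0, N * m, 9)
  for (k in 1:3) {
    Jd[, k] <- (D[[2 * k - 1]]$x - D[[2 * k]]$x) / (2 * delta)
    Jd[, 3 + k] <- (D[[2 * k - 1]]$y - D[[2 * k]]$y) / (2 * delta)
    Jd[, 6 + k] <- (D[[2 * k - 1]]$z - D[[2 * k]]$z) / (2 * delta)
  }
  Ji <- ctx$gp$Jinv
  idx <- rep(seq_len(N), m)
  F <- matrix(0, N * m, 9)
  for (i in 1:3) for (j in 1:3)
    F[, 3 * (i - 1) + j] <-
      Jd[, 3 * (i - 1) + 1] * Ji[idx, j] +
      Jd[, 3 * (i - 1) + 2] * Ji[idx, 3 + j] +
      Jd[, 3 * (i - 1) + 3] * Ji[idx, 6 + j]
  F
}

# cavity volumes (mm^3) for a batch of mode columns
.cavity_volume_batch <- function(ctx, Q) {
  m <- ncol(Q)
  if (ctx$family == "sphere")
    return((1 + Q[1, ] / ctx$geom$a_endo^3) * ctx$cavity_ref_mm3)
  s <- ctx$surf
  Ns <- s$N
  qr <- .q_rows(ctx, Q, Ns)
  d <- 1e-5
  P <- lapply(1:5, function(k)
    .map_pre(.pre_rep(ctx, ctx$sten$surf[[k]], paste0("s", k), m),
             ctx$family, qr))
  xt <- list(x = (P[[2]]$x - P[[3]]$x) / (2 * d),
             y = (P[[2]]$y - P[[3]]$y) / (2 * d),
             z = (P[[2]]$z - P[[3]]$z) / (2 * d))
  xp <- list(x = (P[[4]]$x - P[[5]]$x) / (2 * d),
             y = (P[[4]]$y - P[[5]]$y) / (2 * d),
             z = (P[[4]]$z - P[[5]]$z) / (2 * d))
  integrand <- P[[1]]$x * (xt$y * xp$z - xt$z * xp$y) +
    P[[1]]$y * (xt$z * xp$x - xt$x * xp$z) +
    P[[1]]$z * (xt$x * xp$y - xt$y * xp$x)
  v_lat <- colSums(matrix(s$w * integrand, Ns, m)) / 3
  # flat basal cap: plane center on the axis, ring circular (radius from the
  # deformed ring point); tilt enters the cap term at second order only
  ring <- .map_pre(.pre_rep(ctx, ctx$sten$ring, "ring", m), ctx$family,
                   lapply(seq_len(ctx$n_modes), function(r) Q[r, ]))
  r_ring2 <- ring$x^2 + ring$y^2
  z_cap <- ctx$geom$z_base + Q[6, ]
  v_lat + z_cap * pi * r_ring2 / 3
}

# spring energies (N mm) for a batch of mode columns
.spring_energy_batch <- function(ctx, Q) {
  m <- ncol(Q)
  out <- numeric(m)
  sp <- ctx$springs
  if (!is.null(sp) && any(sp$active)) {
    K <- length(sp$k)
    qr <- .q_rows(ctx, Q, K)
    x <- .map_pre(.pre_rep(ctx, ctx$sten$spring, "spr", m), ctx$family, qr)
    ext <- (x$x - rep(sp$X[, 1], m)) * rep(sp$n[, 1], m) +
           (x$y - rep(sp$X[, 2], m)) * rep(sp$n[, 2], m) +
           (x$z - rep(sp$X[, 3], m)) * rep(sp$n[, 3], m)
    kact <- sp$k * sp$active
    out <- out + colSums(matrix(0.5 * rep(kact, m) * ext^2, K, m))
  }
  ao <- ctx$aortic
  if (!is.null(ao)) {
    ext_a <- Q[6, ] - Q[8, ] * ao$rho_root
    out <- out + 0.5 * ao$k * ext_a^2
  }
  tie <- ctx$septal_tie
  if (!is.null(tie)) {
    # aorto-septal fibrous continuity: axial tie between the upper septal
    # wall and the aortic-root attachment
    qr <- lapply(seq_len(ctx$n_modes), function(r) Q[r, ])
    xw <- .map_pre(.pre_rep(ctx, ctx$sten$tie, "tie", m), ctx$family, qr)
    dz_wall <- xw$z - ctx$sten$tie$z0
    dz_root <- Q[6, ] - Q[8, ] * ctx$aortic$rho_root
    out <- out + 0.5 * tie$k * (dz_wall - dz_root)^2
  }
  out
}

# total potential energy and cavity volume for a batch of mode columns
.act_none <- function(ctx) {
  z <- numeric(ctx$gp$N)
  list(sig = z, dsig = z, E0 = z)
}

.eval_batch <- function(ctx, Q, act, p_mpa, p_ext_mpa = 0,
                        need_vol = TRUE) {
  m <- ncol(Q)
  N <- ctx$gp$N
  F <- .wall_F(ctx, Q)
  idx <- rep(seq_len(N), m)
  inv <- .invariants(F, ctx$gp$f0[idx, , drop = FALSE],
                     ctx$gp$s0[idx, , drop = FALSE])
  psi <- .psi_values(inv, ctx$pp, act, idx, ctx$ap$sheet_fraction)
  bad <- !is.finite(psi)
  psi[bad] <- 0
  E <- colSums(matrix(ctx$gp$w[idx] * psi, N, m))
  E[colSums(matrix(bad, N, m)) > 0] <- Inf
  V <- NULL
  if (need_vol || p_mpa != 0) V <- .cavity_volume_batch(ctx, Q)
  if (p_mpa != 0) E <- E - p_mpa * V
  # counter-pressure of the structures above the valve plane acting on the
  # basal cap (the cavity pressure itself loads the cap through -p V)
  if (p_ext_mpa != 0 && ctx$family == "lv")
    E <- E + p_ext_mpa * ctx$ring_area * Q[6, ]
  E <- E + .spring_energy_batch(ctx, Q)
  list(E = E, V = V)
}

.energy_many <- function(ctx, Q, act, p_mpa, p_ext_mpa = 0)
  .eval_batch(ctx, Q, act, p_mpa, p_ext_mpa, need_vol = FALSE)$E

#' Assemble a mechanics context
#'
#' Precomputes the Gauss-point data (reference Jacobians, quadrature weights,
#' fiber triads), the endocardial surface quadrature for the cavity volume,
#' and the spring attachments, for repeated equilibrium solves.
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param microstructure an [assign_fiber_field()] microstructure (its helix
#'   angles are re-evaluated at the Gauss points).
#' @param passive,active material parameter sets ([passive_params()],
#'   [active_params()]).
#' @param springs pericardial spring list, or `NULL`.
#' @param aortic_spring an aortic `spring_bc`, or `NULL`.
#' @param septal_tie aorto-septal fibrous continuity: an axial spring tying
#'   the upper septal wall (parametric location `u`, `zhat`) to the
#'   aortic-root attachment, with stiffness `k` (N/mm); `NULL` disables it.
#' @param family `"lv"` for the ventricular mode set, `"sphere"` for the
#'   incompressible radial verification family (which integrates the
#'   complete spherical shell).
#' @param settings optional list overriding quadrature resolution and solver
#'   controls: `n_gp_u`, `n_gp_theta`, `n_gp_phi`, `n_surf_theta`,
#'   `n_surf_phi`, `newton_tol`, `max_iter`, `delta_xi`.
#' @return object of class `mech_context`.
#' @export
mechanics_context <- function(geometry, microstructure, passive, active,
                              springs = NULL, aortic_spring = NULL,
                              septal_tie = list(k = 8, u = 0.5, zhat = 0.85),
                              family = c("lv", "sphere"), settings = list()) {
  family <- match.arg(family)
  st <- utils::modifyList(list(n_gp_u = 3, n_gp_theta = 6, n_gp_phi = 8,
                               n_surf_theta = 8, n_surf_phi = 8,
                               newton_tol = 1e-6, max_iter = 50,
                               delta_xi = 1e-5), settings)
  ctx <- list(geom = geometry, pp = passive, ap = active, family = family,
              settings = st,
              scales = if (family == "lv") .lv_scales else .sphere_scales)
  ctx$n_modes <- length(ctx$scales)

  glu <- pracma::gaussLegendre(st$n_gp_u, 0, 1)
  glph <- 2 * pi * (seq_len(st$n_gp_phi) - 1) / st$n_gp_phi
  u <- th <- ph <- w0 <- numeric(0)
  for (i in seq_len(st$n_gp_u)) {
    # the sphere verification family integrates the complete spherical
    # shell; the ventricular family stops at the basal truncation plane
    tb <- if (family == "sphere") 0 else .geom_theta_base(geometry, glu$x[i])
    glt <- pracma::gaussLegendre(st$n_gp_theta, tb, pi)
    for (j in seq_len(st$n_gp_theta)) {
      u <- c(u, rep(glu$x[i], st$n_gp_phi))
      th <- c(th, rep(glt$x[j], st$n_gp_phi))
      ph <- c(ph, glph)
      w0 <- c(w0, rep(glu$w[i] * glt$w[j] * 2 * pi / st$n_gp_phi,
                      st$n_gp_phi))
    }
  }
  tri <- .fiber_triad(geometry, u, th, ph,
                      microstructure$endo_angle, microstructure$epi_angle)
  q0 <- matrix(0, ctx$n_modes, length(u))
  Jref <- .param_jacobian(ctx, u, th, ph, q0, st$delta_xi)
  detJ <- abs(.det3(Jref))
  ctx$gp <- list(N = length(u), u = u, th = th, ph = ph, w = w0 * detJ,
                 Jinv = .inv3(Jref), f0 = tri$f0, s0 = tri$s0,
                 helix_deg = tri$helix_deg)
  ctx$wall_volume_ref <- sum(ctx$gp$w)

  # finite-difference stencils in the parametric coordinates, precomputed
  dx <- st$delta_xi
  mkpre <- function(uu, tt, pp2) .precompute_points(geometry, family, uu, tt, pp2)
  ctx$sten <- list(wall = list(
    mkpre(u + dx, th, ph), mkpre(u - dx, th, ph),
    mkpre(u, th + dx, ph), mkpre(u, th - dx, ph),
    mkpre(u, th, ph + dx), mkpre(u, th, ph - dx)))

  tb0 <- if (family == "sphere") 0 else .geom_theta_base(geometry, 0)
  gls <- pracma::gaussLegendre(st$n_surf_theta, tb0, pi)
  sph <- 2 * pi * (seq_len(st$n_surf_phi) - 1) / st$n_surf_phi
  sth <- rep(gls$x, each = st$n_surf_phi)
  sphv <- rep(sph, st$n_surf_theta)
  su <- rep(0, length(sth))
  ds <- 1e-5
  ctx$surf <- list(N = length(sth),
                   w = rep(gls$w * 2 * pi / st$n_surf_phi,
                           each = st$n_surf_phi))
  ctx$sten$surf <- list(mkpre(su, sth, sphv),
                        mkpre(su, sth + ds, sphv), mkpre(su, sth - ds, sphv),
                        mkpre(su, sth, sphv + ds), mkpre(su, sth, sphv - ds))
  ctx$sten$ring <- mkpre(0, tb0, 0)
  ctx$cavity_ref_mm3 <- if (family == "sphere")
    4 / 3 * pi * geometry$a_endo^3 else 1000 * geometry$cavity_volume
  # reference basal-orifice area for the valve-plane counter-pressure
  ctx$ring_area <- if (family == "lv")
    pi * (geometry$a_endo * sin(tb0))^2 else 0

  if (!is.null(springs)) {
    K <- length(springs)
    thc <- phc <- k <- ax <- numeric(K); act <- logical(K)
    nmat <- matrix(0, K, 3)
    for (j in seq_len(K)) {
      s <- springs[[j]]
      prm <- geometry$node_param[s$nodes, , drop = FALSE]
      thc[j] <- mean(prm[, 2])
      phc[j] <- atan2(mean(sin(prm[, 3])), mean(cos(prm[, 3])))
      k[j] <- s$stiffness; act[j] <- s$active; ax[j] <- s$axial_position
      nmat[j, ] <- s$normal
    }
    X <- .map_points(ctx, rep(1, K), thc, phc, matrix(0, ctx$n_modes, K))
    ctx$springs <- list(th = thc, ph = phc, n = nmat, k = k, active = act,
                        axial = ax, X = X, ids = seq_len(K))
    ctx$sten$spring <- mkpre(rep(1, K), thc, phc)
  }
  if (!is.null(aortic_spring)) {
    kt <- aortic_spring$tissue_stiffness %||% Inf
    k_eff <- 1 / (1 / aortic_spring$stiffness + 1 / kt)
    ctx$aortic <- list(k = k_eff, k_aa = aortic_spring$stiffness,
                       stj_ratio = k_eff / aortic_spring$stiffness,
                       rho_root = geometry$root_offset)
    if (!is.null(septal_tie) && septal_tie$k > 0) {
      zt <- -geometry$c_epi + septal_tie$zhat * (geometry$z_base +
                                                   geometry$c_epi)
      tht <- acos(zt / .geom_c(geometry, septal_tie$u))
      ctx$sten$tie <- mkpre(septal_tie$u, tht, geometry$septal_azimuth)
      ctx$septal_tie <- septal_tie
    }
  }
  ctx$cache <- new.env(parent = emptyenv())
  structure(ctx, class = "mech_context")
}

# finite-difference Hessian of the total energy (batched)
.hessian_fd <- function(ctx, q, E0, h, act, p_mpa, p_ext_mpa = 0) {
  d <- ctx$n_modes
  pairs <- utils::combn(d, 2)
  np <- ncol(pairs)
  Q <- matrix(q, d, 2 * d + 4 * np)
  for (i in seq_len(d)) {
    Q[i, 2 * i - 1] <- q[i] + h[i]
    Q[i, 2 * i] <- q[i] - h[i]
  }
  for (cix in seq_len(np)) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    base <- 2 * d + 4 * (cix - 1)
    Q[i, base + 1] <- q[i] + h[i]; Q[j, base + 1] <- q[j] + h[j]
    Q[i, base + 2] <- q[i] + h[i]; Q[j, base + 2] <- q[j] - h[j]
    Q[i, base + 3] <- q[i] - h[i]; Q[j, base + 3] <- q[j] + h[j]
    Q[i, base + 4] <- q[i] - h[i]; Q[j, base + 4] <- q[j] - h[j]
  }
  E <- .energy_many(ctx, Q, act, p_mpa, p_ext_mpa)
  H <- matrix(0, d, d)
  diag(H) <- (E[seq(1, 2 * d, 2)] - 2 * E0 + E[seq(2, 2 * d, 2)]) / h^2
  for (cix in seq_len(np)) {
    i <- pairs[1, cix]; j <- pairs[2, cix]
    base <- 2 * d + 4 * (cix - 1)
    H[i, j] <- H[j, i] <-
      (E[base + 1] - E[base + 2] - E[base + 3] + E[base + 4]) /
      (4 * h[i] * h[j])
  }
  H
}

# Levenberg-regularized Newton at fixed cavity pressure (frozen sigma_a)
.newton_solve <- function(ctx, q0, act, p_mpa, p_ext_mpa = 0) {
  d <- ctx$n_modes
  tol <- ctx$settings$newton_tol
  h <- 5e-4 * ctx$scales
  q <- q0
  H <- ctx$cache$H
  lambda <- 1e-6
  E0 <- .energy_many(ctx, matrix(q, d, 1), act, p_mpa, p_ext_mpa)
  if (!is.finite(E0)) stop("element inversion at the initial state")
  grad_at <- function(q) {
    Q <- matrix(q, d, 2 * d)
    for (i in seq_len(d)) {
      Q[i, 2 * i - 1] <- q[i] + h[i]
      Q[i, 2 * i] <- q[i] - h[i]
    }
    E <- .energy_many(ctx, Q, act, p_mpa, p_ext_mpa)
    (E[seq(1, 2 * d, 2)] - E[seq(2, 2 * d, 2)]) / (2 * h)
  }
  res <- Inf
  it <- 0
  for (it in seq_len(ctx$settings$max_iter)) {
    g <- grad_at(q)
    if (is.null(H) || it %% 6 == 0) H <- .hessian_fd(ctx, q, E0, h, act,
                                                     p_mpa, p_ext_mpa)
    # convergence measured on the undamped Newton step relative to the
    # characteristic mode amplitudes (robust to the round-off floor of the
    # finite-difference gradient)
    s_N <- tryCatch(solve(H, -g), error = function(e) NULL)
    res <- if (!is.null(s_N)) max(abs(s_N) / ctx$scales)
           else max(abs(g) * ctx$scales) / max(abs(E0), 1)
    if (res < tol) break
    accepted <- FALSE
    for (try in 1:10) {
      Hreg <- H + diag(lambda * pmax(abs(diag(H)), 1e-8 / ctx$scales^2), d)
      step <- tryCatch(solve(Hreg, -g), error = function(e) NULL)
      if (!is.null(step)) {
        Et <- .energy_many(ctx, matrix(q + step, d, 1), act, p_mpa,
                           p_ext_mpa)
        if (is.finite(Et) && Et <= E0 + 1e-9 * (abs(E0) + 1)) {
          q <- q + step; E0 <- Et
          lambda <- max(lambda / 5, 1e-9)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (try == 4) H <- .hessian_fd(ctx, q, E0, h, act, p_mpa, p_ext_mpa)
    }
    if (!accepted) break
  }
  ctx$cache$H <- H
  list(q = q, residual = res, iterations = it, energy = E0,
       converged = res < tol)
}

# per-point active stress, its strain slope and linearization point for the
# current state
.sigma_a_field <- function(ctx, q, activation_time) {
  if (ctx$ap$T_max == 0 || activation_time < 0) return(.act_none(ctx))
  F <- .wall_F(ctx, matrix(q, ctx$n_modes, 1))
  inv <- .invariants(F, ctx$gp$f0, ctx$gp$s0)
  E_ff <- pmax((inv$I4f - 1) / 2, -0.4999)
  de <- 1e-4
  sig <- active_fiber_stress(activation_time, E_ff, ctx$ap)
  dsig <- (active_fiber_stress(activation_time, E_ff + de, ctx$ap) -
           active_fiber_stress(activation_time, pmax(E_ff - de, -0.4999),
                               ctx$ap)) / (2 * de)
  list(sig = sig, dsig = pmax(dsig, 0), E0 = E_ff)
}

#' Solve quasi-static mechanical equilibrium
#'
#' Minimizes the total potential energy (passive strain energy, volumetric
#' penalty, frozen active work term, spring energies, minus the pressure
#' work on the cavity) over the deformation modes, with an outer fixed-point
#' loop updating the length-dependent active stress. On failure from a cold
#' start the load is ramped in increments.
#'
#' @param context a [mechanics_context()].
#' @param cavity_pressure cavity pressure (mmHg).
#' @param activation_time time since activation onset (s); negative or large
#'   values give a passive solve.
#' @param state0 optional previous `mechanical_state` (warm start).
#' @param ramp logical; ramp the load when the direct solve fails.
#' @return object of class `mechanical_state`: mode vector `q`, cavity
#'   volume (mL), pressure (mmHg), activation time, residual, convergence
#'   flag and iteration count.
#' @export
solve_equilibrium <- function(context, cavity_pressure, activation_time = -1,
                              state0 = NULL, ramp = TRUE,
                              base_counter_pressure = 0) {
  stopifnot(cavity_pressure >= 0)
  q <- if (is.null(state0)) rep(0, context$n_modes) else state0$q
  p_mpa <- mmHg_to_MPa(cavity_pressure)
  pe_mpa <- mmHg_to_MPa(base_counter_pressure)
  sol <- NULL
  act <- .sigma_a_field(context, q, activation_time)
  for (fp in 1:8) {
    sol <- .newton_solve(context, q, act, p_mpa, pe_mpa)
    if (!sol$converged && ramp) {
      # restart with load stepping from the unloaded state
      qr <- rep(0, context$n_modes)
      for (frac in c(0.25, 0.5, 0.75, 1)) {
        sa <- .sigma_a_field(context, qr, activation_time)
        sa$sig <- sa$sig * frac; sa$dsig <- sa$dsig * frac
        solr <- .newton_solve(context, qr, sa, p_mpa * frac, pe_mpa * frac)
        qr <- solr$q
      }
      sol <- .newton_solve(context, qr, act, p_mpa, pe_mpa)
    }
    if (!sol$converged)
      stop(sprintf("equilibrium solve did not converge (residual %.3e)",
                   sol$residual))
    q_new <- sol$q
    act_new <- .sigma_a_field(context, q_new, activation_time)
    dsig <- max(abs(act_new$sig - act$sig))
    q <- q_new
    act <- act_new
    if (dsig < 1e-7 * max(context$ap$T_max, 1e-6)) break
  }
  vol <- .cavity_volume_batch(context, matrix(q, context$n_modes, 1)) / 1000
  structure(list(q = q, cavity_volume = as.numeric(vol),
                 cavity_pressure = cavity_pressure,
                 activation_time = activation_time,
                 sigma_a = act$sig,
                 residual = sol$residual, converged = sol$converged,
                 iterations = sol$iterations, energy = sol$energy),
            class = "mechanical_state")
}

# coupled Newton on the volume-constrained saddle system: find (q, p) with
# grad_q [Pi_wall+springs(q) - p V(q)] = 0 and V(q) = V_target; the active
# stress is lagged (updated each iteration from the current state)
.newton_solve_volume <- function(ctx, q0, p0_mpa, vt_mm3, activation_time,
                                 p_ext_mpa = 0) {
  d <- ctx$n_modes
  tol <- ctx$settings$newton_tol
  h <- 5e-4 * ctx$scales
  q <- q0; p <- p0_mpa
  H <- ctx$cache$Hv
  lambda <- 1e-6
  res <- Inf
  act <- .sigma_a_field(ctx, q, activation_time)
  dq <- rep(0, d); cv <- Inf
  it <- 0
  for (it in seq_len(ctx$settings$max_iter)) {
    Q <- matrix(q, d, 2 * d + 1)
    for (i in seq_len(d)) {
      Q[i, 2 * i] <- q[i] + h[i]
      Q[i, 2 * i + 1] <- q[i] - h[i]
    }
    ev <- .eval_batch(ctx, Q, act, p, p_ext_mpa, need_vol = TRUE)
    E <- ev$E; V <- ev$V
    if (!is.finite(E[1])) stop("element inversion at the current state")
    ip <- 2 * seq_len(d); im <- ip + 1
    g <- (E[ip] - E[im]) / (2 * h)
    Vq <- (V[ip] - V[im]) / (2 * h)
    cv <- V[1] - vt_mm3
    if (is.null(H) || it %% 5 == 0)
      H <- .hessian_fd(ctx, q, E[1], h, act, p, p_ext_mpa)
    ok <- FALSE
    for (try in 1:10) {
      Hreg <- H + diag(lambda * pmax(abs(diag(H)), 1e-8 / ctx$scales^2), d)
      K <- rbind(cbind(Hreg, -Vq), c(Vq, 0))
      sol <- tryCatch(solve(K, c(-g, -cv)), error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        dq <- sol[seq_len(d)]; dp <- sol[d + 1]
        # trust region on the step
        sc <- max(abs(dq) / (20 * ctx$scales), abs(dp) / 4e-3)
        if (sc > 1) { dq <- dq / sc; dp <- dp / sc }
        Et <- .energy_many(ctx, matrix(q + dq, d, 1), act, p + dp,
                           p_ext_mpa)
        if (is.finite(Et)) {
          q <- q + dq; p <- p + dp
          lambda <- max(lambda / 5, 1e-9)
          ok <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!ok) break
    act <- .sigma_a_field(ctx, q, activation_time)
    res <- max(abs(dq) / ctx$scales)
    # 1e-4 of a mode scale is ~0.5 um of displacement; the lagged active
    # stress keeps increments from falling much further during activation
    if (res < max(tol, 5e-5) && abs(cv) < 25) break
  }
  ctx$cache$Hv <- H
  vfin <- .cavity_volume_batch(ctx, matrix(q, d, 1))[1]
  # local chamber elastance dP/dV from the constrained system (MPa/mm^3)
  el <- tryCatch({
    s <- solve(H, Vq)
    1 / sum(Vq * s)
  }, error = function(e) NA_real_)
  list(q = q, p_mpa = p, v_mm3 = vfin, sigma_a = act$sig,
       residual = res, iterations = it, elastance_mpa_mm3 = el,
       converged = res < 1e-3 && abs(vfin - vt_mm3) < 50)
}

#' Find the cavity pressure producing a target volume
#'
#' Volume-constrained equilibrium: solves simultaneously for the deformation
#' modes and the cavity pressure such that the wall is in equilibrium and
#' the cavity volume equals the target (saddle-point Newton with the volume
#' constraint and a lagged active-stress update).
#'
#' @param target_volume target cavity volume (mL).
#' @param context a [mechanics_context()].
#' @param activation_time activation time passed to the solves (s).
#' @param state0 optional warm-start state.
#' @param p_init initial pressure guess (mmHg).
#' @param tol volume tolerance (mL).
#' @return the converged `mechanical_state` at the matched volume.
#' @export
pressure_for_volume <- function(target_volume, context, activation_time = -1,
                                state0 = NULL, p_init = NULL, tol = 0.05,
                                base_counter_pressure = 0) {
  q <- if (is.null(state0)) rep(0, context$n_modes) else state0$q
  p <- mmHg_to_MPa(if (!is.null(p_init)) p_init
                   else if (!is.null(state0)) state0$cavity_pressure else 5)
  pe <- mmHg_to_MPa(base_counter_pressure)
  vt <- target_volume * 1000
  sol <- .newton_solve_volume(context, q, p, vt, activation_time, pe)
  if (!sol$converged) {
    # ramp the volume from the currently achievable state
    v0 <- .cavity_volume_batch(context, matrix(q, context$n_modes, 1))[1]
    qr <- q; pr <- p
    for (frac in c(0.25, 0.5, 0.75, 1)) {
      sol <- .newton_solve_volume(context, qr, pr, v0 + frac * (vt - v0),
                                  activation_time, pe)
      qr <- sol$q; pr <- sol$p_mpa
    }
  }
  if (!sol$converged || abs(sol$v_mm3 - vt) > tol * 1000)
    stop(sprintf(paste0("volume-constrained solve failed: target %.2f mL, ",
                        "achieved %.2f mL (residual %.2e)"),
                 target_volume, sol$v_mm3 / 1000, sol$residual))
  structure(list(q = sol$q, cavity_volume = sol$v_mm3 / 1000,
                 cavity_pressure = MPa_to_mmHg(sol$p_mpa),
                 activation_time = activation_time, sigma_a = sol$sigma_a,
                 elastance = sol$elastance_mpa_mm3 * 1000 / 1.33322e-4,
                 residual = sol$residual, converged = sol$converged,
                 iterations = sol$iterations),
            class = "mechanical_state")
}

#' Cavity volume of a mechanical state
#'
#' Divergence-theorem volume of the deformed endocardial surface closed at
#' the basal plane, by smooth surface quadrature.
#'
#' @param state a `mechanical_state`.
#' @param context the [mechanics_context()] the state was solved on.
#' @return cavity volume (mL).
#' @export
cavity_volume <- function(state, context) {
  as.numeric(.cavity_volume_batch(context,
                                  matrix(state$q, context$n_modes, 1))) / 1000
}

#' Deformed wall material volume
#'
#' @inheritParams cavity_volume
#' @return wall volume (mL) of the deformed configuration (quadrature of the
#'   pointwise Jacobian).
#' @export
wall_volume <- function(state, context) {
  F <- .wall_F(context, matrix(state$q, context$n_modes, 1))
  sum(context$gp$w * .det3(F)) / 1000
}

#' Spring reaction forces at a mechanical state
#'
#' Reports, per pericardial cluster and for the aortic spring, the extension
#' along the spring's action direction and the reaction force vector
#' `-k * extension * direction`.
#'
#' @inheritParams cavity_volume
#' @return data.frame with columns `id`, `type`, `stiffness`, `active`,
#'   `extension` (mm), `force` (N, signed magnitude opposing extension)
#'   and force components `fx`, `fy`, `fz`.
#' @export
axial_reaction <- function(state, context) {
  rows <- list()
  sp <- context$springs
  if (!is.null(sp)) {
    K <- length(sp$k)
    x <- .map_points(context, rep(1, K), sp$th, sp$ph,
                     matrix(state$q, context$n_modes, K))
    ext <- rowSums((x - sp$X) * sp$n)
    for (j in seq_len(K)) {
      f <- -sp$k[j] * sp$active[j] * ext[j] * sp$n[j, ]
      rows[[j]] <- data.frame(id = as.character(sp$ids[j]),
                              type = "pericardial", stiffness = sp$k[j],
                              active = sp$active[j], extension = ext[j],
                              force = -sp$k[j] * sp$active[j] * ext[j],
                              fx = f[1], fy = f[2], fz = f[3])
    }
  }
  ao <- context$aortic
  if (!is.null(ao)) {
    # extension of the ascending-aorta spring itself (at the sino-tubular
    # junction, downstream of the series root-tissue compliance)
    ext <- (state$q[6] - state$q[8] * ao$rho_root) * ao$stj_ratio
    rows[[length(rows) + 1]] <-
      data.frame(id = "aortic", type = "aortic", stiffness = ao$k_aa,
                 active = TRUE, extension = ext, force = -ao$k_aa * ext,
                 fx = 0, fy = 0, fz = -ao$k_aa * ext)
  }
  do.call(rbind, rows)
}

#' Deformed positions of material points
#'
#' Maps parametric material points `(u, theta, phi)` through the deformation
#' of a mechanical state (or a raw mode vector).
#'
#' @param context a [mechanics_context()].
#' @param state a `mechanical_state` or a numeric mode vector.
#' @param u,theta,phi parametric coordinates (vectors of equal length).
#' @return matrix of deformed coordinates (mm).
#' @export
map_material_points <- function(context, state, u, theta, phi) {
  q <- if (inherits(state, "mechanical_state")) state$q else state
  .map_points(context, u, theta, phi, matrix(q, context$n_modes, length(u)))
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf(
    "mechanical_state: p = %.2f mmHg, V = %.2f mL, t_act = %.3f s\n",
    x$cavity_pressure, x$cavity_volume, x$activation_time))
  cat(sprintf("  residual %.2e (%s, %d iterations)\n", x$residual,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
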