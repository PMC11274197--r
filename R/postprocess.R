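# Reported metrics: PV-loop quantities and stroke work, strain decomposition
# at 12 sampling locations (x endo/epi), regional longitudinal strain,
# volumetric-averaged myofiber stress, apex/root displacement, and the
# comparison-table renderer.

#' Pressure-volume loop metrics of one beat
#'
#' End-diastole is the volume maximum of the trace, end-systole the volume
#' minimum. `MAP` is the time average of the arterial (Windkessel) pressure
#' over the cycle, `SW = SV * MAP`, and the loop area is the shoelace
#' integral of the (V, P) polygon, reported alongside.
#'
#' @param trace a `beat_trace` or its per-step data.frame (columns `t`,
#'   `P_lv`, `V_lv`, `P_art`).
#' @param cyclic_tol maximum allowed start/end volume mismatch, as a
#'   fraction of the stroke volume, before the trace is rejected as
#'   non-cyclic.
#' @return object of class `beat_metrics`: `EDP`, `EDV`, `ESP`, `ESV`,
#'   `SV`, `MAP`, `SW` (mmHg mL), `SW_J` (joule), `loop_area` (mmHg mL) and
#'   `counterclockwise` (orientation of the loop in the (V, P) plane).
#' @export
compute_pv_metrics <- function(trace, cyclic_tol = 0.01) {
  tr <- if (inherits(trace, "beat_trace")) trace$trace else trace
  stopifnot(all(c("P_lv", "V_lv", "P_art") %in% names(tr)))
  sv_range <- max(tr$V_lv) - min(tr$V_lv)
  if (abs(tr$V_lv[1] - tr$V_lv[nrow(tr)]) > cyclic_tol * max(sv_range, 1))
    stop("trace is not cyclic: start/end volume mismatch exceeds tolerance")
  ied <- which.max(tr$V_lv); ies <- which.min(tr$V_lv)
  V <- tr$V_lv; P <- tr$P_lv
  n <- length(V); nx <- c(2:n, 1)
  area2 <- sum(V * P[nx] - V[nx] * P)      # shoelace, CCW positive
  sv <- V[ied] - V[ies]
  map <- mean(tr$P_art)
  sw <- sv * map
  structure(list(EDP = P[ied], EDV = V[ied], ESP = P[ies], ESV = V[ies],
                 SV = sv, MAP = map, SW = sw,
                 SW_J = sw * 1.33322e-4,   # mmHg mL -> J
                 loop_area = abs(area2) / 2,
                 counterclockwise = area2 > 0,
                 ed_index = ied, es_index = ies),
            class = "beat_metrics")
}

#' Percent change relative to a baseline
#'
#' `100 * (variant - baseline) / baseline`, rounded to two decimals for
#' table rendering.
#'
#' @param baseline,variant numeric scalars or vectors (baseline non-zero).
#' @param digits decimals for rounding (default 2, the table convention).
#' @return percent change(s).
#' @export
percent_change <- function(baseline, variant, digits = 2) {
  if (any(baseline == 0)) stop("percent change undefined for zero baseline")
  round(100 * (variant - baseline) / baseline, digits)
}

# deformed positions of reference points for a state: mechanical states map
# through the mode kinematics, affine states through x = A X + b
.deform_xi <- function(state, context, u, theta, phi) {
  if (inherits(state, "affine_state")) {
    X <- .map_points(context, u, theta, phi,
                     matrix(0, context$n_modes, length(u)))
    return(X %*% t(state$A) + matrix(state$b, length(u), 3, byrow = TRUE))
  }
  map_material_points(context, state, u, theta, phi)
}

#' Affine deformation state
#'
#' Convenience state for verification: every material point moves as
#' `x = A X + b`. Accepted by the strain sampler in place of a mechanical
#' state.
#'
#' @param A 3x3 matrix; `b` length-3 translation.
#' @return object of class `affine_state`.
#' @export
affine_state <- function(A = diag(3), b = c(0, 0, 0)) {
  structure(list(A = matrix(A, 3, 3), b = b), class = "affine_state")
}

#' Default strain sampling locations
#'
#' Three axial levels by four azimuthal sectors (septal, anterior, lateral,
#' posterior), at an endocardial and an epicardial transmural depth.
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param zhat_levels normalized axial positions of the three levels.
#' @param u_layers transmural coordinates of the endo/epi sampling layers.
#' @return data.frame of sampling sites (location id, sector, layer, u,
#'   zhat, azimuth).
#' @export
strain_sampling_spec <- function(geometry,
                                 zhat_levels = c(0.25, 0.5, 0.75),
                                 u_layers = c(endocardium = 0.2,
                                              epicardium = 0.8)) {
  sectors <- c(septal = 0, anterior = 90, lateral = 180, posterior = 270)
  grid <- expand.grid(level = seq_along(zhat_levels),
                      sector = names(sectors),
                      layer = names(u_layers),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$zhat <- zhat_levels[grid$level]
  grid$u <- u_layers[grid$layer]
  grid$azimuth <- geometry$septal_azimuth + sectors[grid$sector] * pi / 180
  grid$location <- paste0(grid$sector, "-L", grid$level)
  grid
}

# parametric coordinates (u, theta, phi) of a sampling site
.site_xi <- function(geometry, u, zhat, azimuth) {
  z0 <- -geometry$c_epi + zhat * (geometry$z_base + geometry$c_epi)
  cth <- z0 / .geom_c(geometry, u)
  if (any(abs(cth) >= 1))
    stop("sampling site outside the wall (axial level too apical)")
  list(u = u, theta = acos(cth), phi = azimuth)
}

# invert (rho, z) -> (u, theta) on the ellipsoid shell family (Newton)
.invert_param <- function(geometry, rho, z, u0 = 0.5, th0 = 2) {
  dr <- geometry$a_epi - geometry$a_endo
  dc <- geometry$c_epi - geometry$c_endo
  u <- u0; th <- th0
  for (it in 1:50) {
    r <- .geom_r(geometry, u); cc <- .geom_c(geometry, u)
    f1 <- r * sin(th) - rho
    f2 <- cc * cos(th) - z
    if (abs(f1) < 1e-11 && abs(f2) < 1e-11) break
    J <- matrix(c(dr * sin(th), r * cos(th),
                  dc * cos(th), -cc * sin(th)), 2, 2, byrow = TRUE)
    step <- solve(J, -c(f1, f2))
    u <- u + step[1]; th <- th + step[2]
    th <- min(max(th, 1e-3), pi - 1e-3)
  }
  if (u < -1e-9 || u > 1 + 1e-9)
    stop("fiducial segment leaves the wall")
  list(u = min(max(u, 0), 1), theta = th)
}

#' Strain decomposition between two states
#'
#' Measures radial, circumferential and longitudinal strain at the sampling
#' sites as the relative length change of short material fiducial segments
#' oriented along the local radial/circumferential/longitudinal directions
#' of the reference configuration: `(L_es - L_ed) / L_ed`. Radial strain is
#' positive for wall thickening; circumferential and longitudinal strains
#' are negative for shortening.
#'
#' @param state_ed,state_es mechanical (or [affine_state()]) states of the
#'   same converged beat, at end-diastole and end-systole.
#' @param context the [mechanics_context()].
#' @param spec sampling specification from [strain_sampling_spec()].
#' @param fiducial_fraction fiducial segment half-length as a fraction of
#'   the local wall thickness.
#' @return object of class `strain_report`: data.frame `samples` (strain per
#'   site and direction), `summary` (mean and population SD per direction),
#'   and `regional` (mean longitudinal strain per azimuthal sector).
#' @export
strain_at_locations <- function(state_ed, state_es, context, spec = NULL,
                                fiducial_fraction = 0.1) {
  geom <- context$geom
  if (is.null(spec)) spec <- strain_sampling_spec(geom)
  h <- fiducial_fraction * geom$wall_thickness
  dirs <- c("radial", "circumferential", "longitudinal")
  out <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    xi <- .site_xi(geom, spec$u[i], spec$zhat[i], spec$azimuth[i])
    rho <- .geom_r(geom, xi$u) * sin(xi$theta)
    z0 <- .geom_c(geom, xi$u) * cos(xi$theta)
    phi <- xi$phi
    # exact fiducial endpoints: radial (transmural, cylindrical rho),
    # circumferential (arc at fixed rho, z) and longitudinal (apex-base
    # axis); radial/longitudinal endpoints are re-parameterized by Newton
    # inversion of the shell family
    strains <- numeric(3)
    for (k in 1:3) {
      if (k == 1) {          # radial
        e1 <- .invert_param(geom, rho + h, z0, xi$u, xi$theta)
        e2 <- .invert_param(geom, rho - h, z0, xi$u, xi$theta)
        up <- c(e1$u, e2$u); tp <- c(e1$theta, e2$theta); pp <- c(phi, phi)
      } else if (k == 2) {   # circumferential (chord directed along e_phi)
        dphi <- h / rho
        up <- rep(xi$u, 2); tp <- rep(xi$theta, 2)
        pp <- phi + c(dphi, -dphi)
      } else {               # longitudinal
        e1 <- .invert_param(geom, rho, z0 + h, xi$u, xi$theta)
        e2 <- .invert_param(geom, rho, z0 - h, xi$u, xi$theta)
        up <- c(e1$u, e2$u); tp <- c(e1$theta, e2$theta); pp <- c(phi, phi)
      }
      xe <- .deform_xi(state_ed, context, up, tp, pp)
      xs <- .deform_xi(state_es, context, up, tp, pp)
      L_ed <- sqrt(sum((xe[1, ] - xe[2, ])^2))
      L_es <- sqrt(sum((xs[1, ] - xs[2, ])^2))
      strains[k] <- (L_es - L_ed) / L_ed
    }
    out[[i]] <- data.frame(location = spec$location[i],
                           sector = spec$sector[i], layer = spec$layer[i],
                           level = spec$level[i],
                           direction = dirs, strain = strains)
  }
  samples <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(split(samples, samples$direction),
    function(d) data.frame(direction = d$direction[1],
                           mean = mean(d$strain),
                           sd = stats::sd(d$strain))))
  lon <- samples[samples$direction == "longitudinal", ]
  reg <- do.call(rbind, lapply(split(lon, lon$sector),
    function(d) data.frame(sector = d$sector[1], mean = mean(d$strain))))
  reg <- reg[match(c("septal", "anterior", "lateral", "posterior"),
                   reg$sector), ]
  structure(list(samples = samples, summary = summ, regional = reg),
            class = "strain_report")
}

#' Regional longitudinal strain table
#'
#' Per-sector mean longitudinal strain (septal, anterior, lateral,
#' posterior) rendered at two decimals, with optional percent-change rows
#' against a baseline report.
#'
#' @param report a [strain_at_locations()] report.
#' @param baseline optional baseline `strain_report`.
#' @return data.frame with one column per sector.
#' @export
regional_longitudinal <- function(report, baseline = NULL) {
  stopifnot(inherits(report, "strain_report"))
  v <- round(report$regional$mean, 2)
  names(v) <- report$regional$sector
  out <- as.data.frame(as.list(v))
  rownames(out) <- "longitudinal"
  if (!is.null(baseline)) {
    b <- round(baseline$regional$mean, 2)
    out <- rbind(out, percent_change(b, v))
    rownames(out) <- c("longitudinal", "percent_change")
  }
  out
}

# Cauchy fiber stress per Gauss point at a state (MPa)
.fiber_stress_field <- function(context, state, activation_time = NULL) {
  q <- state$q
  t_act <- if (is.null(activation_time)) state$activation_time else activation_time
  gp <- context$gp
  N <- gp$N
  F <- .wall_F(context, matrix(q, context$n_modes, 1))
  inv <- .invariants(F, gp$f0, gp$s0)
  sig_a <- if (t_act >= 0)
    active_fiber_stress(t_act, pmax((inv$I4f - 1) / 2, -0.4999), context$ap)
  else numeric(N)
  pp <- context$pp
  sff <- numeric(N)
  for (i in seq_len(N)) {
    Fm <- matrix(F[i, ], 3, 3, byrow = TRUE)
    st <- kinematics_state(Fm, gp$f0[i, ], gp$s0[i, ])
    S <- passive_stress(st, pp)$S + sig_a[i] * tcrossprod(gp$f0[i, ])
    if (context$ap$sheet_fraction > 0)
      S <- S + context$ap$sheet_fraction * sig_a[i] * tcrossprod(gp$s0[i, ])
    f <- Fm %*% gp$f0[i, ]   # deformed fiber direction (unnormalized)
    sff[i] <- drop(t(f) %*% (Fm %*% S %*% t(Fm)) %*% f) / (st$J * sum(f * f))
  }
  list(sigma_ff = sff, weights = gp$w * inv$J)
}

#' Volumetric-averaged myofiber stress summary
#'
#' Cauchy stress contracted twice with the deformed (unit) fiber direction,
#' averaged over the wall with deformed element volumes as weights. With a
#' reference field, element-wise percent changes are summarized as mean and
#' population SD (the comparison convention of the stress table).
#'
#' @param field numeric vector of fiber stresses (MPa), or a
#'   `mechanical_state` (evaluated on the context's Gauss points).
#' @param weights volume weights (same length as `field`); defaults to the
#'   deformed Gauss-point volumes when `field` is a state.
#' @param context required when `field` is a `mechanical_state`.
#' @param reference optional reference field (same discretization) for the
#'   percent-change summary.
#' @param activation_time optional activation time override for the active
#'   stress contribution.
#' @return object of class `stress_report`: `mean`, `sd` (MPa, volume
#'   weighted), and when a reference is given `pct_mean`, `pct_sd`
#'   (element-wise percent change, volume weighted).
#' @export
myofiber_stress_summary <- function(field, weights = NULL, context = NULL,
                                    reference = NULL,
                                    activation_time = NULL) {
  if (inherits(field, "mechanical_state")) {
    stopifnot(!is.null(context))
    fs <- .fiber_stress_field(context, field, activation_time)
    field <- fs$sigma_ff
    if (is.null(weights)) weights <- fs$weights
  }
  if (is.null(weights)) weights <- rep(1, length(field))
  stopifnot(length(weights) == length(field))
  wm <- function(x) sum(weights * x) / sum(weights)
  mu <- wm(field)
  sdv <- sqrt(wm((field - mu)^2))
  out <- list(mean = mu, sd = sdv, field = field, weights = weights)
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "stress_report")) reference$field else reference
    if (length(ref) != length(field))
      stop("reference field has a different discretization")
    pct <- 100 * (field - ref) / ref
    pm <- wm(pct)
    out$pct_mean <- pm
    out$pct_sd <- sqrt(wm((pct - pm)^2))
  }
  structure(out, class = "stress_report")
}

#' Apex and aortic-root displacement of a beat
#'
#' ED-to-ES motion of the epicardial apex and of the aortic-root attachment,
#' projected on the apex-base axis of the end-diastolic configuration.
#' Apex displacement is positive toward the base. The root displacement is
#' reported positive when the root moves toward the apex (the phrasing used
#' for systolic atrioventricular-plane descent); its raw signed axial value
#' is returned alongside.
#'
#' @param trace a `beat_trace`.
#' @return list with `apex` (mm, + toward base), `root_toward_apex` (mm, +
#'   toward apex), `root_axial` (mm, + toward base) and the ED/ES indices.
#' @export
apex_and_root_displacement <- function(trace) {
  stopifnot(inherits(trace, "beat_trace"))
  tr <- trace$trace
  if (!all(c("x_root", "x_apex") %in% names(tr)))
    stop("trace is missing landmark trajectories")
  ied <- trace$ed_index; ies <- trace$es_index
  apex <- tr$x_apex[ies] - tr$x_apex[ied]
  root <- tr$x_root[ies] - tr$x_root[ied]
  list(apex = apex, root_toward_apex = -root, root_axial = root,
       ed_index = ied, es_index = ies)
}

#' Render a comparison table row pair
#'
#' Given baseline and variant rows of named absolute values, returns the
#' absolute-difference row and the percent-change row rounded to two
#' decimals (the layout of the published comparison tables).
#'
#' @param baseline,variant named numeric vectors with identical names.
#' @return data.frame with rows `baseline`, `variant`, `difference`,
#'   `percent`.
#' @export
comparison_rows <- function(baseline, variant) {
  stopifnot(identical(names(baseline), names(variant)))
  out <- rbind(baseline = baseline, variant = variant,
               difference = round(variant - baseline, 2),
               percent = percent_change(baseline, variant))
  as.data.frame(out)
}

#' @export
print.beat_metrics <- function(x, ...) {
  cat(sprintf(paste0("EDP %.2f mmHg  EDV %.2f mL  ESP %.2f mmHg  ESV %.2f mL\n",
                     "SV %.2f mL  MAP %.2f mmHg  SW %.1f mmHg mL (%.2f J)\n"),
              x$EDP, x$EDV, x$ESP, x$ESV, x$SV, x$MAP, x$SW, x$SW_J))
  invisible(x)
}

#' @export
print.strain_report <- function(x, ...) {
  cat("Average strain (mean +/- SD over sampling sites):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-15s %+0.3f +/- %0.3f\n", x$summary$direction[i],
                x$summary$mean[i], x$summary$sd[i]))
  cat("Regional longitudinal strain:\n")
  for (i in seq_len(nrow(x$regional)))
    cat(sprintf("  %-10s %+0.3f\n", x$regional$sector[i], x$regional$mean[i]))
  invisible(x)
}

#' @export
print.stress_report <- function(x, ...) {
  cat(sprintf("Myofiber stress at ES: %.4f +/- %.4f MPa\n", x$mean, x$sd))
  if (!is.null(x$pct_mean))
    cat(sprintf("  vs reference: %+.2f +/- %.2f %%\n", x$pct_mean, x$pct_sd))
  invisible(x)
}
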