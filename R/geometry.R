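# Synthetic idealized LV: truncated prolate ellipsoid, rule-based fibers,
# pericardial spring clusters and the aortic spring.
# Coordinates in mm; long axis along z, epicardial apex at z = -c_epi,
# basal truncation plane at z = z_base; apex-base unit axis = +z.

# semi-axis / truncation helpers for the shell family u in [0, 1]
.geom_r <- function(g, u) g$a_endo + u * (g$a_epi - g$a_endo)
.geom_c <- function(g, u) g$c_endo + u * (g$c_epi - g$c_endo)
.geom_theta_base <- function(g, u) acos(g$z_base / .geom_c(g, u))

# normalized axial coordinate: 0 at the epicardial apex, 1 at the base plane
.geom_zhat <- function(g, z) {
  pmin(pmax((z - (-g$c_epi)) / (g$z_base + g$c_epi), 0), 1)
}

#' Build the idealized truncated-ellipsoid left ventricle
#'
#' Generates a structured hexahedral shell mesh of a truncated prolate
#' ellipsoid: cavity semi-axes `a_endo` (equatorial) and `c_endo` (long),
#' uniform wall thickness, truncated by the basal plane `z = z_base`.
#' Landmarks are placed at the epicardial apex, the centroid of the basal
#' endocardial ring (mitral annulus plane center) and at a configurable
#' septal offset from the annulus center (aortic root attachment). The
#' unloaded cavity volume is computed from the triangulated endocardial
#' surface closed by the basal plane.
#'
#' @param a_endo,c_endo cavity semi-axes (mm).
#' @param wall_thickness uniform wall thickness (mm); must be smaller than
#'   the inner semi-axes.
#' @param z_base height of the basal truncation plane (mm), `0 < z_base <
#'   c_endo`.
#' @param scale global length scale factor applied to every dimension
#'   (calibration handle for the unloaded volume).
#' @param root_offset in-plane offset of the aortic-root attachment from the
#'   annulus center (mm), directed toward the septal azimuth.
#' @param septal_azimuth azimuth (radians) of the septal sector; the aortic
#'   root sits on this side.
#' @param n_transmural,n_theta,n_phi mesh resolution: element counts through
#'   the wall, along the meridian and around the circumference.
#' @param target_edv,reference_pressure informational operating point (mL,
#'   mmHg) recorded for the calibration routines.
#' @return object of class `lv_geometry`: nodes, hexahedral elements,
#'   surface node sets (`endocardium`, `epicardium`, `base`), landmarks,
#'   apex-base unit axis, per-node parametric coordinates and the unloaded
#'   cavity volume in mL.
#' @export
build_ellipsoid_lv <- function(a_endo = 22, c_endo = 52, wall_thickness = 10,
                               z_base = 20, scale = 1,
                               root_offset = 26, septal_azimuth = 0,
                               n_transmural = 3, n_theta = 24, n_phi = 64,
                               target_edv = 158.3, reference_pressure = 11.85) {
  stopifnot(a_endo > 0, c_endo > 0, z_base > 0, scale > 0,
            n_transmural >= 1, n_theta >= 4, n_phi >= 8)
  if (wall_thickness <= 0 || wall_thickness >= min(a_endo, c_endo))
    stop("degenerate geometry: wall thickness must be positive and smaller ",
         "than the inner semi-axes")
  if (z_base >= c_endo)
    stop("basal truncation plane must intersect the cavity (z_base < c_endo)")
  g <- list(a_endo = a_endo * scale, c_endo = c_endo * scale,
            a_epi = (a_endo + wall_thickness) * scale,
            c_epi = (c_endo + wall_thickness) * scale,
            z_base = z_base * scale,
            wall_thickness = wall_thickness * scale,
            root_offset = root_offset * scale,
            septal_azimuth = septal_azimuth,
            n_transmural = n_transmural, n_theta = n_theta, n_phi = n_phi,
            target_edv = target_edv, reference_pressure = reference_pressure,
            scale = scale)

  n_u <- n_transmural; n_th <- n_theta
  per_shell <- n_th * n_phi + 1          # n_th regular rows + pole node
  idx <- function(l, j, k) {             # l shell, j theta row, k phi column
    n <- max(length(l), length(j), length(k))
    l <- rep_len(l, n); j <- rep_len(j, n); k <- rep_len(k, n)
    l * per_shell + ifelse(j == n_th, n_th * n_phi + 1,
                           j * n_phi + (k %% n_phi) + 1)
  }
  us <- seq(0, 1, length.out = n_u + 1)
  nodes <- matrix(0, (n_u + 1) * per_shell, 3)
  param <- matrix(0, (n_u + 1) * per_shell, 3)
  phis <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  for (l in seq_len(n_u + 1) - 1) {
    u <- us[l + 1]
    th_b <- .geom_theta_base(g, u)
    ths <- seq(th_b, pi, length.out = n_th + 1)
    for (j in seq_len(n_th) - 1) {
      ii <- idx(l, j, seq_len(n_phi) - 1)
      nodes[ii, ] <- cbind(.geom_r(g, u) * sin(ths[j + 1]) * cos(phis),
                           .geom_r(g, u) * sin(ths[j + 1]) * sin(phis),
                           .geom_c(g, u) * cos(ths[j + 1]))
      param[ii, ] <- cbind(u, ths[j + 1], phis)
    }
    ip <- idx(l, n_th, 0)
    nodes[ip, ] <- c(0, 0, -.geom_c(g, u))
    param[ip, ] <- c(u, pi, 0)
  }

  elem <- vector("list", n_u * n_th * n_phi)
  e <- 0L
  for (l in seq_len(n_u) - 1) for (j in seq_len(n_th) - 1)
    for (k in seq_len(n_phi) - 1) {
      e <- e + 1L
      elem[[e]] <- c(idx(l, j, k), idx(l, j, k + 1),
                     idx(l, j + 1, k + 1), idx(l, j + 1, k),
                     idx(l + 1, j, k), idx(l + 1, j, k + 1),
                     idx(l + 1, j + 1, k + 1), idx(l + 1, j + 1, k))
    }
  elements <- do.call(rbind, elem)

  surf <- list(
    endocardium = sort(unique(as.integer(idx(0, rep(0:n_th, each = n_phi),
                                             rep(0:(n_phi - 1), n_th + 1))))),
    epicardium = sort(unique(as.integer(idx(n_u, rep(0:n_th, each = n_phi),
                                            rep(0:(n_phi - 1), n_th + 1))))),
    base = sort(as.integer(idx(rep(0:n_u, each = n_phi), 0,
                               rep(0:(n_phi - 1), n_u + 1))))
  )

  landmarks <- list(
    apex_epi = c(0, 0, -g$c_epi),
    annulus_center = c(0, 0, g$z_base),
    aortic_root = c(g$root_offset * cos(septal_azimuth),
                    g$root_offset * sin(septal_azimuth), g$z_base)
  )
  axis <- landmarks$annulus_center - landmarks$apex_epi
  axis <- axis / sqrt(sum(axis^2))

  geom <- structure(
    c(g, list(nodes = nodes, elements = elements, surfaces = surf,
              node_param = param, landmarks = landmarks, axis = axis)),
    class = "lv_geometry")
  geom$endo_faces <- .endo_surface_triangles(geom)
  geom$cavity_volume <- .mesh_cavity_volume(geom)
  geom
}

# triangulation of the endocardial surface closed by a basal cap; oriented
# outward from the enclosed cavity (lateral normals point into the wall,
# cap normal points along +z)
.endo_surface_triangles <- function(geom) {
  n_th <- geom$n_theta; n_phi <- geom$n_phi
  idx <- function(j, k) ifelse(j == n_th, n_th * n_phi + 1,
                               j * n_phi + (k %% n_phi) + 1)
  tris <- list()
  for (j in seq_len(n_th - 1) - 1) for (k in seq_len(n_phi) - 1) {
    a <- idx(j, k); b <- idx(j, k + 1); cc <- idx(j + 1, k + 1); d <- idx(j + 1, k)
    tris[[length(tris) + 1]] <- c(a, cc, b)
    tris[[length(tris) + 1]] <- c(a, d, cc)
  }
  for (k in seq_len(n_phi) - 1)      # apex fan
    tris[[length(tris) + 1]] <- c(idx(n_th - 1, k), idx(n_th, 0),
                                  idx(n_th - 1, k + 1))
  # basal cap: fan to a virtual center vertex appended after the mesh nodes
  nc <- nrow(geom$nodes) + 1L
  for (k in seq_len(n_phi) - 1)
    tris[[length(tris) + 1]] <- c(idx(0, k), idx(0, k + 1), nc)
  do.call(rbind, tris)
}

.mesh_cavity_volume <- function(geom, nodes = geom$nodes) {
  verts <- rbind(nodes, geom$landmarks$annulus_center)
  v <- surface_volume(verts, geom$endo_faces)
  if (v <= 0) stop("endocardial surface is not positively oriented")
  v / 1000                             # mm^3 -> mL
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem (signed tetrahedron) volume of a closed, consistently
#' oriented triangle mesh. Positive for outward orientation.
#'
#' @param vertices V x 3 matrix of vertex coordinates.
#' @param faces F x 3 matrix of 1-based vertex indices.
#' @return signed enclosed volume, in the cube of the coordinate unit.
#' @export
surface_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# orthonormal local frame (circumferential, longitudinal, transmural) and
# fiber triad at parametric points; vectorized over u, theta, phi
.local_frame <- function(geom, u, theta, phi) {
  r <- .geom_r(geom, u); cc <- .geom_c(geom, u)
  ec <- cbind(-sin(phi), cos(phi), rep(0, length(phi)))
  dth <- cbind(r * cos(theta) * cos(phi), r * cos(theta) * sin(phi),
               -cc * sin(theta))
  nl <- sqrt(rowSums(dth^2))
  if (any(nl < 1e-12))
    stop("degenerate meridional tangent (pole) at requested points")
  el <- -dth / nl                      # points toward the base
  et <- cbind(ec[, 2] * el[, 3] - ec[, 3] * el[, 2],
              ec[, 3] * el[, 1] - ec[, 1] * el[, 3],
              ec[, 1] * el[, 2] - ec[, 2] * el[, 1])
  list(e_c = ec, e_l = el, e_t = et)
}

.fiber_triad <- function(geom, u, theta, phi, endo_angle, epi_angle) {
  fr <- .local_frame(geom, u, theta, phi)
  alpha <- (endo_angle * (1 - u) + epi_angle * u) * pi / 180
  f0 <- cos(alpha) * fr$e_c + sin(alpha) * fr$e_l
  # sheet axis in the wall tangent plane orthogonal to the fiber; the sheet
  # normal is transmural (with the tabulated moduli a transmural sheet axis
  # would make physiological systolic wall thickening energetically
  # impossible)
  s0 <- -sin(alpha) * fr$e_c + cos(alpha) * fr$e_l
  n0 <- fr$e_t
  list(f0 = f0, s0 = s0, n0 = n0, helix_deg = alpha * 180 / pi)
}

#' Assign a rule-based fiber architecture
#'
#' Per-element orthonormal fiber/sheet/normal frames with the fiber helix
#' angle interpolating linearly across the wall from `endo_angle` at the
#' endocardium to `epi_angle` at the epicardium. The fiber lies in the local
#' wall-tangent plane; the sheet direction is transmural.
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param endo_angle,epi_angle helix angles (degrees) at the endo- and
#'   epicardial surfaces, each in (-90, 90).
#' @return object of class `lv_microstructure` with per-element matrices
#'   `f0`, `s0`, `n0`, the transmural coordinate and helix angle per element,
#'   and the angle pair used.
#' @export
assign_fiber_field <- function(geometry, endo_angle = 60, epi_angle = -60) {
  stopifnot(abs(endo_angle) < 90, abs(epi_angle) < 90)
  pr <- geometry$node_param[t(geometry$elements), , drop = FALSE]
  grp <- rep(seq_len(nrow(geometry$elements)), each = 8)
  u <- as.numeric(tapply(pr[, 1], grp, mean))
  th <- as.numeric(tapply(pr[, 2], grp, mean))
  ph <- as.numeric(atan2(tapply(sin(pr[, 3]), grp, mean),
                         tapply(cos(pr[, 3]), grp, mean)))
  tri <- .fiber_triad(geometry, u, th, ph, endo_angle, epi_angle)
  structure(list(f0 = tri$f0, s0 = tri$s0, n0 = tri$n0,
                 transmural = as.numeric(u), helix_deg = tri$helix_deg,
                 endo_angle = endo_angle, epi_angle = epi_angle,
                 element_param = cbind(u = as.numeric(u), theta = as.numeric(th),
                                       phi = as.numeric(ph))),
            class = "lv_microstructure")
}

# outward epicardial surface normal of the ellipsoid family
.epi_normal <- function(geom, xyz) {
  n <- cbind(xyz[, 1] / geom$a_epi^2, xyz[, 2] / geom$a_epi^2,
             xyz[, 3] / geom$c_epi^2)
  n / sqrt(rowSums(n^2))
}

#' Build the pericardial spring clusters
#'
#' Partitions the epicardial node set into `n_clusters` clusters (k-means on
#' the node coordinates, fixed seed) and attaches one spring per cluster.
#' Each spring acts along the reference outward epicardial normal of its
#' cluster (the pericardial sac resists normal motion while permitting
#' tangential sliding) and is anchored at the unloaded cluster centroid.
#' Stiffness interpolates linearly from `k_apex` at normalized axial
#' position 0 (apex) to `k_base` at 1 (base).
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param k_apex,k_base spring stiffness (N/mm) at apex and base;
#'   `k_apex >= k_base >= 0`.
#' @param n_clusters number of clusters (default 49).
#' @param seed RNG seed for the k-means seeding (determinism).
#' @return list of `spring_bc` objects (class `pericardial_springs`), ordered
#'   from apex to base. Each spring carries the member node indices, anchor
#'   point (mm), action normal, stiffness (N/mm), normalized axial position
#'   and an `active` flag.
#' @export
build_pericardial_springs <- function(geometry, k_apex = 2, k_base = 0.05,
                                      n_clusters = 49, seed = 1) {
  if (!(k_apex >= k_base && k_base >= 0))
    stop("require k_apex >= k_base >= 0")
  epi <- geometry$surfaces$epicardium
  if (length(epi) < n_clusters)
    stop("fewer epicardial nodes (", length(epi), ") than clusters (",
         n_clusters, ")")
  xyz <- geometry$nodes[epi, , drop = FALSE]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(xyz, centers = n_clusters,
                                       nstart = 5, iter.max = 300))
  normals <- .epi_normal(geometry, xyz)
  zmin <- -geometry$c_epi; zspan <- geometry$z_base - zmin
  springs <- lapply(seq_len(n_clusters), function(j) {
    sel <- km$cluster == j
    anchor <- colMeans(xyz[sel, , drop = FALSE])
    nrm <- colMeans(normals[sel, , drop = FALSE])
    nrm <- nrm / sqrt(sum(nrm^2))
    axial <- min(max((anchor[3] - zmin) / zspan, 0), 1)
    structure(list(id = j, nodes = epi[sel], anchor = anchor, normal = nrm,
                   stiffness = k_apex + (k_base - k_apex) * axial,
                   axial_position = axial, active = TRUE,
                   type = "pericardial"),
              class = "spring_bc")
  })
  ord <- order(vapply(springs, `[[`, 0, "axial_position"),
               vapply(springs, function(s) atan2(s$anchor[2], s$anchor[1]), 0))
  springs <- springs[ord]
  for (j in seq_along(springs)) springs[[j]]$id <- j
  structure(springs, class = c("pericardial_springs", "list"))
}

#' Release the apical pericardial constraint
#'
#' Flags inactive every pericardial cluster whose normalized axial position
#' lies below `freed_fraction` (the distal part of the pericardial sack).
#' The input list is not modified.
#'
#' @param springs a [build_pericardial_springs()] list.
#' @param freed_fraction normalized axial extent freed, in `[0, 1]`;
#'   0.5 frees the distal (apical) half.
#' @return a new spring list with apical clusters deactivated.
#' @export
free_apex <- function(springs, freed_fraction = 0.5) {
  if (length(springs) == 0) stop("empty spring list")
  if (freed_fraction < 0 || freed_fraction > 1)
    stop("freed_fraction must lie in [0, 1]")
  out <- lapply(springs, function(s) {
    if (s$axial_position < freed_fraction ||
        (freed_fraction == 1 && s$axial_position <= 1)) s$active <- FALSE
    s
  })
  structure(out, class = class(springs))
}

#' Build the ascending-aorta spring
#'
#' One spring attached at the aortic-root landmark, acting along the
#' apex-base axis and anchored at the unloaded landmark position: the root
#' is restrained axially (the longitudinal elasticity of the ascending
#' aorta) while rotation about the long axis is suppressed by the basal
#' kinematics.
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param stiffness spring stiffness (N/mm), positive. 0.5 models the
#'   elastic ascending aorta, 10 the stiff one.
#' @param tissue_stiffness axial stiffness (N/mm) of the aortic-root tissue
#'   between the ventricular attachment and the sino-tubular junction where
#'   the ascending-aorta spring acts (the root is constrained from rotation
#'   but allowed to stretch); acts in series with `stiffness`.
#' @return a `spring_bc` object of type `aortic`.
#' @export
build_aortic_spring <- function(geometry, stiffness = 0.5,
                                tissue_stiffness = 2) {
  stopifnot(stiffness > 0, tissue_stiffness > 0)
  structure(list(id = "aortic", nodes = integer(0),
                 anchor = geometry$landmarks$aortic_root,
                 normal = geometry$axis, stiffness = stiffness,
                 tissue_stiffness = tissue_stiffness,
                 axial_position = 1, active = TRUE, type = "aortic"),
            class = "spring_bc")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat("Idealized truncated-ellipsoid LV\n")
  cat(sprintf("  cavity semi-axes: %.1f x %.1f mm, wall %.1f mm, base at z = %.1f mm\n",
              x$a_endo, x$c_endo, x$wall_thickness, x$z_base))
  cat(sprintf("  mesh: %d nodes, %d hexahedral elements\n",
              nrow(x$nodes), nrow(x$elements)))
  cat(sprintf("  unloaded cavity volume: %.1f mL\n", x$cavity_volume))
  invisible(x)
}

#' Export the mesh as a legacy ASCII VTK unstructured grid
#'
#' @param geometry an [build_ellipsoid_lv()] geometry.
#' @param path output file path.
#' @param displacements optional N x 3 nodal displacement field written as
#'   point data.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(geometry, path, displacements = NULL) {
  n <- nrow(geometry$nodes); m <- nrow(geometry$elements)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "apexfree LV mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(format(geometry$nodes, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8, geometry$elements - 1), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("CELL_TYPES %d", m),
               paste(rep(12, m), collapse = "\n")), con)
  if (!is.null(displacements)) {
    writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS displacement double"),
               con)
    utils::write.table(format(displacements, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
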