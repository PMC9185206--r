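## Exact meridional ray tracing through a four-surface pseudophakic eye.
##
## Geometry lives in a meridional (y, z) plane: z runs from the anterior
## corneal vertex (z = 0) toward the retina (z = axial length), y is height
## above the axis. A surface is a conic of revolution
##   y^2 = 2 R zeta - (1 + q) zeta^2,   zeta = z - z_vertex,
## with signed vertex radius R (positive = centre of curvature toward the
## retina) and conic constant q. Rays are lines y(z) = y0 + u (z - z0) with
## slope u = tan(angle); refraction applies exact vector Snell's law, so
## spherical aberration and pupil dependence are fully represented.

#' Ray-tracing configuration
#'
#' @param pupil_mm pupil diameter at the iris plane, mm (default 2.5)
#' @param n_cornea,n_aqueous,n_vitreous refractive indices (Gullstrand-style
#'   defaults 1.376 / 1.336 / 1.336)
#' @param posterior_anterior_ratio posterior/anterior corneal radius ratio
#'   (default 0.883, the Gullstrand 6.8/7.7 ratio)
#' @param q_cornea conic constant applied to both corneal surfaces (default 0:
#'   keratometry supplies curvature only)
#' @param vertex_mm spectacle vertex distance, mm
#' @param focus_ray_fraction pupil-plane height of the best-focus reference
#'   ray as a fraction of the pupil radius; the default `1/sqrt(2)` is the
#'   zonal ray that halves the pupil area (ISO 11979-2 reading)
#' @param sc_beta Stiles-Crawford apodization coefficient, mm^-2 (used by the
#'   multi-ray RMS mode only)
#' @param mode `"iso_single_ray"` (default) or `"rms_multiray"`
#' @param n_rings number of pupil zones sampled in multi-ray mode
#' @return list of class `raytrace_config`
#' @export
raytrace_config <- function(pupil_mm = 2.5, n_cornea = 1.376,
                            n_aqueous = 1.336, n_vitreous = 1.336,
                            posterior_anterior_ratio = 0.883, q_cornea = 0,
                            vertex_mm = 12, focus_ray_fraction = 1 / sqrt(2),
                            sc_beta = 0.116,
                            mode = c("iso_single_ray", "rms_multiray"),
                            n_rings = 6) {
  mode <- match.arg(mode)
  stopifnot(pupil_mm > 0.1, pupil_mm < 8,
            posterior_anterior_ratio > 0.7, posterior_anterior_ratio < 1,
            focus_ray_fraction > 0, focus_ray_fraction <= 1, sc_beta >= 0)
  structure(list(pupil_mm = pupil_mm, n_cornea = n_cornea,
                 n_aqueous = n_aqueous, n_vitreous = n_vitreous,
                 posterior_anterior_ratio = posterior_anterior_ratio,
                 q_cornea = q_cornea, vertex_mm = vertex_mm,
                 focus_ray_fraction = focus_ray_fraction, sc_beta = sc_beta,
                 mode = mode, n_rings = n_rings),
            class = "raytrace_config")
}

#' Construct a refracting surface
#'
#' @param z_vertex axial vertex position, mm
#' @param radius signed vertex radius, mm (|radius| > 0.5)
#' @param q conic constant
#' @param half_aperture semi-aperture, mm
#' @param n_before,n_after refractive indices on either side
#' @return list of class `rt_surface`
#' @export
make_surface <- function(z_vertex, radius, q = 0, half_aperture = 6,
                         n_before, n_after) {
  stopifnot(abs(radius) > 0.5, n_before > 1 || n_before == 1,
            n_after > 1 || n_after == 1, half_aperture > 0)
  structure(list(z_vertex = z_vertex, radius = radius, q = q,
                 half_aperture = half_aperture,
                 n_before = n_before, n_after = n_after),
            class = "rt_surface")
}

#' Construct a ray
#' @param y height above the axis, mm
#' @param z axial position, mm
#' @param u meridional slope (tangent of the angle with the axis, |u| < 1.5)
#' @return list of class `rt_ray`
#' @export
make_ray <- function(y, z, u) {
  stopifnot(is.finite(y), is.finite(z), is.finite(u), abs(u) < 1.5)
  structure(list(y = y, z = z, u = u), class = "rt_ray")
}

#' Exact ray/conic intersection
#'
#' Solves the quadratic obtained by substituting the ray line into the conic
#' implicit form and returns the intersection on the vertex branch together
#' with the unit surface normal (oriented against the incoming ray).
#'
#' @param ray an [make_ray()] propagating toward the surface
#' @param surface an [make_surface()]
#' @return list with `y`, `z`, `normal` (length-2 vector, (y, z) components)
#' @export
intersect_conic <- function(ray, surface) {
  R <- surface$radius; q <- surface$q
  zeta0 <- ray$z - surface$z_vertex
  y0 <- ray$y; u <- ray$u
  A <- u^2 + (1 + q)
  B <- 2 * (y0 * u - R + (1 + q) * zeta0)
  C <- y0^2 - 2 * R * zeta0 + (1 + q) * zeta0^2
  sag_of <- function(y) {
    inner <- 1 - (1 + q) * y^2 / R^2
    if (inner < 0) return(NA_real_)
    y^2 / (R * (1 + sqrt(inner)))
  }
  roots <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else {
      sq <- sqrt(disc)
      # numerically stable pair
      r1 <- if (B >= 0) (-B - sq) / (2 * A) else (2 * C) / (-B + sq)
      r2 <- if (B >= 0) (2 * C) / (-B - sq) else (-B + sq) / (2 * A)
      c(r1, r2)
    }
  }
  roots <- roots[is.finite(roots) & roots > 1e-9]
  hit <- NULL
  for (t in sort(roots)) {
    yt <- y0 + u * t; zt <- zeta0 + t
    s <- sag_of(yt)
    if (!is.na(s) && abs(s - zt) < 1e-6 * (1 + abs(zt))) { hit <- c(yt, zt); break }
  }
  if (is.null(hit)) {
    iolray_stop("iolray_ray_escape", "ray does not intersect the surface")
  }
  y <- hit[1]; zeta <- hit[2]
  if (abs(y) > surface$half_aperture) {
    iolray_stop("iolray_ray_escape", "ray exceeds the surface aperture")
  }
  # gradient of F(y, zeta) = y^2 - 2 R zeta + (1+q) zeta^2
  n <- c(y, (1 + q) * zeta - R)
  n <- n / sqrt(sum(n^2))
  list(y = y, z = surface$z_vertex + zeta, normal = n)
}

#' Exact Snell refraction
#'
#' Vector form of Snell's law in the meridional plane; conserves
#' `n sin(theta)` to machine precision. Total internal reflection raises a
#' ray-escape error.
#'
#' @param ray an [make_ray()] (its slope `u` defines the incident direction)
#' @param normal unit surface normal, (y, z) components
#' @param n1,n2 refractive indices before/after the interface
#' @return the refracted [make_ray()] at the same point
#' @export
refract_snell <- function(ray, normal, n1, n2) {
  d <- c(ray$u, 1) / sqrt(1 + ray$u^2)
  n <- normal
  ci <- -sum(d * n)
  if (ci < 0) { n <- -n; ci <- -ci }
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  if (k < 0) {
    iolray_stop("iolray_ray_escape", "total internal reflection")
  }
  t <- eta * d + (eta * ci - sqrt(k)) * n
  if (t[2] <= 1e-12) {
    iolray_stop("iolray_ray_escape", "refracted ray no longer advances toward the retina")
  }
  make_ray(ray$y, ray$z, t[1] / t[2])
}

#' Build the four-surface pseudophakic eye model
#'
#' Surfaces: anterior cornea at z = 0 with radius `337.5 / K` (keratometric
#' back-conversion, per principal meridian), posterior cornea at the corneal
#' thickness with the fixed posterior/anterior ratio, and the IOL with its
#' front vertex at `cct + elp_front_vertex` (posterior-cornea/endothelium
#' reference). The retina sits at the axial length. One model is built per
#' principal meridian (from `k1` and `k2`).
#'
#' @param record one cohort row (needs `al`, `k1`, `k2`, `cct`)
#' @param geometry an [iol_geometry()]
#' @param elp an `elp_prediction` (or a number taken as the centre position)
#' @param config a [raytrace_config()]
#' @return list of class `pseudophakic_eye` with per-meridian surface lists
#' @export
build_pseudophakic_eye <- function(record, geometry, elp,
                                   config = raytrace_config()) {
  if (is.numeric(elp)) elp <- elp_prediction(elp, geometry$thickness, "given")
  cct_mm <- if (!is.null(record$cct) && !is.na(record$cct)) record$cct / 1000 else 0.54
  z_front <- cct_mm + elp$elp_front_vertex
  z_back <- z_front + geometry$thickness
  if (!(z_front > cct_mm && z_back < record$al)) {
    iolray_stop("iolray_geometry_error",
                sprintf("surface ordering violated: IOL [%.2f, %.2f] mm must lie between cornea (%.2f) and retina (%.2f)",
                        z_front, z_back, cct_mm, record$al))
  }
  pupil_z <- max(z_front - 0.2, (cct_mm + z_front) / 2)
  meridian <- function(k) {
    r_ant <- 337.5 / k
    r_post <- config$posterior_anterior_ratio * r_ant
    list(
      make_surface(0, r_ant, config$q_cornea, 6, 1.0, config$n_cornea),
      make_surface(cct_mm, r_post, config$q_cornea, 6, config$n_cornea, config$n_aqueous),
      make_surface(z_front, geometry$r_front, geometry$q_front, 3.25,
                   config$n_aqueous, geometry$n_iol),
      make_surface(z_back, geometry$r_back, geometry$q_back, 3.25,
                   geometry$n_iol, config$n_vitreous))
  }
  structure(list(meridians = list(meridian(record$k1), meridian(record$k2)),
                 k = c(record$k1, record$k2),
                 pupil_z = pupil_z, pupil_diameter = config$pupil_mm,
                 retina_z = record$al, config = config),
            class = "pseudophakic_eye")
}

# trace through an ordered surface list; returns ray states and Snell checks
trace_surfaces <- function(surfaces, ray, pupil_z = NULL, pupil_radius = Inf) {
  path <- vector("list", length(surfaces))
  for (i in seq_along(surfaces)) {
    s <- surfaces[[i]]
    if (!is.null(pupil_z) && ray$z <= pupil_z && s$z_vertex >= pupil_z) {
      y_pupil <- ray$y + ray$u * (pupil_z - ray$z)
      if (abs(y_pupil) > pupil_radius) {
        iolray_stop("iolray_pupil_clip",
                    sprintf("ray clipped at the pupil (|y| = %.3f mm > %.3f mm)",
                            abs(y_pupil), pupil_radius))
      }
    }
    hit <- intersect_conic(ray, s)
    incident <- make_ray(hit$y, hit$z, ray$u)
    refracted <- refract_snell(incident, hit$normal, s$n_before, s$n_after)
    d_in <- c(incident$u, 1) / sqrt(1 + incident$u^2)
    d_out <- c(refracted$u, 1) / sqrt(1 + refracted$u^2)
    sin_in <- d_in[1] * hit$normal[2] - d_in[2] * hit$normal[1]
    sin_out <- d_out[1] * hit$normal[2] - d_out[2] * hit$normal[1]
    path[[i]] <- list(y = hit$y, z = hit$z, u = refracted$u,
                      n_sin_incident = s$n_before * sin_in,
                      n_sin_refracted = s$n_after * sin_out)
    ray <- refracted
  }
  list(ray = ray, path = path)
}

#' Trace a ray to the retina
#'
#' Sequentially intersects and refracts the ray through the eye's four
#' surfaces (one principal meridian), clips it at the pupil plane, then
#' propagates it in a straight line to the retina. Escapes and pupil clips
#' raise classed errors (`iolray_ray_escape`, `iolray_pupil_clip`), never
#' silent results.
#'
#' @param eye a `pseudophakic_eye`
#' @param ray entry [make_ray()] starting before the first surface
#' @param meridian which principal meridian to trace (1 = `k1`, 2 = `k2`)
#' @return list with `y_retina` (mm) and `path` (per-surface ray states with
#'   the `n sin(theta)` bookkeeping)
#' @export
trace_to_retina <- function(eye, ray, meridian = 1) {
  res <- trace_surfaces(eye$meridians[[meridian]], ray,
                        pupil_z = eye$pupil_z,
                        pupil_radius = eye$pupil_diameter / 2)
  final <- res$ray
  y_ret <- final$y + final$u * (eye$retina_z - final$z)
  list(y_retina = y_ret, path = res$path, exit_ray = final)
}

#' Stiles-Crawford pupil apodization weight
#'
#' Photometric convention `w = 10^(-beta y^2)`: rays entering near the pupil
#' margin contribute less to the perceived image.
#'
#' @param y_pupil ray height in the pupil, mm
#' @param beta apodization coefficient, mm^-2 (default 0.116)
#' @return weight in (0, 1\]
#' @export
stiles_crawford_weight <- function(y_pupil, beta = 0.116) {
  stopifnot(beta >= 0)
  10^(-beta * y_pupil^2)
}

# mirror an eye meridian so a retina-to-cornea trace can reuse the forward
# machinery: z' = retina - z, radii flip sign, indices swap sides
mirror_meridian <- function(surfaces, retina_z) {
  rev(lapply(surfaces, function(s) {
    make_surface(retina_z - s$z_vertex, -s$radius, s$q, s$half_aperture,
                 n_before = s$n_after, n_after = s$n_before)
  }))
}

# reverse-trace the ISO reference ray for one meridian and return the
# spectacle-plane power that makes the emerging ray parallel (the eye's
# refraction). The reference ray leaves the retinal intersection of the
# fixation axis and crosses the pupil plane at h_p = pupil_radius * fraction;
# reversibility of refraction makes this exactly the corrected ray path, so
# no iteration over spectacle power is needed.
meridian_refraction_iso <- function(surfaces, retina_z, pupil_z, h_pupil,
                                    vertex_mm) {
  msurf <- mirror_meridian(surfaces, retina_z)
  pupil_zp <- retina_z - pupil_z
  # indices of mirrored surfaces before the pupil plane (IOL back, IOL front)
  pre <- Filter(function(i) msurf[[i]]$z_vertex < pupil_zp, seq_along(msurf))
  pupil_height <- function(u0) {
    r <- make_ray(0, 0, u0)
    res <- trace_surfaces(msurf[pre], r)
    res$ray$y + res$ray$u * (pupil_zp - res$ray$z)
  }
  # secant solve for the launch slope hitting the ISO pupil height
  u0 <- h_pupil / pupil_zp
  f0 <- pupil_height(u0) - h_pupil
  u1 <- u0 * 1.05 + 1e-6
  f1 <- pupil_height(u1) - h_pupil
  for (it in 1:60) {
    if (abs(f1) < 1e-12) break
    if (abs(f1 - f0) < 1e-18) {
      iolray_stop("iolray_numeric_error", "ISO reference-ray solve stalled")
    }
    u2 <- u1 - f1 * (u1 - u0) / (f1 - f0)
    u0 <- u1; f0 <- f1
    u1 <- u2; f1 <- pupil_height(u1) - h_pupil
  }
  if (abs(f1) > 1e-8) {
    iolray_stop("iolray_numeric_error", "ISO reference ray did not converge")
  }
  full <- trace_surfaces(msurf, make_ray(0, 0, u1))
  out <- full$ray
  # mirrored spectacle plane: vertex_mm beyond the (mirrored) cornea
  z_spec <- retina_z + vertex_mm
  h <- out$y + out$u * (z_spec - out$z)
  m <- out$u
  s <- 1000 * m / h
  if (!is.finite(s) || abs(s) > 30) {
    iolray_stop("iolray_domain_error",
                sprintf("best-focus refraction %.1f D outside [-30, 30]: non-physiologic eye", s))
  }
  s
}

# multi-ray RMS-spot refraction for one meridian: spectacle power minimizing
# the Stiles-Crawford weighted RMS retinal spot of a parallel zonal fan
meridian_refraction_rms <- function(surfaces, retina_z, pupil_z, pupil_radius,
                                    config) {
  fracs <- seq(-1, 1, length.out = 2 * config$n_rings + 1)
  fracs <- fracs[fracs != 0] * 0.95
  z_spec <- -config$vertex_mm
  spot <- function(s) {
    num <- 0; den <- 0
    for (f in fracs) {
      # parallel fan generously covering the pupil; the spectacle lens of
      # power s deflects each ray before it reaches the cornea
      y_s <- f * pupil_radius * 1.3
      u <- -y_s * s / 1000
      entry <- make_ray(y_s + u * (-0.5 - z_spec), -0.5, u)  # 0.5 mm before the cornea
      res <- tryCatch({
        tr <- trace_surfaces(surfaces, entry, pupil_z = pupil_z,
                             pupil_radius = pupil_radius)
        yr <- tr$ray$y + tr$ray$u * (retina_z - tr$ray$z)
        # apodization weight from the ray's height at the pupil plane
        st <- tr$path[[2]]
        y_pup <- st$y + st$u * (pupil_z - st$z)
        list(yr = yr, w = stiles_crawford_weight(y_pup, config$sc_beta))
      }, iolray_ray_escape = function(e) NULL, iolray_pupil_clip = function(e) NULL)
      if (!is.null(res)) { num <- num + res$w * res$yr^2; den <- den + res$w }
    }
    if (den == 0) return(1e6)
    sqrt(num / den)
  }
  optimize(spot, c(-30, 30), tol = 1e-4)$minimum
}

#' Best-focus refraction of a pseudophakic eye
#'
#' In the default single-ray mode the ISO 11979-2 style criterion is used:
#' for each principal meridian the reference ray through the pupil plane at
#' `pupil_radius * focus_ray_fraction` must cross the optical axis exactly at
#' the retina; the spectacle-plane power (12 mm vertex) achieving that is the
#' meridian's refraction, and the spherical equivalent is the mean of the two
#' meridians. The optional `"rms_multiray"` mode instead minimizes the
#' Stiles-Crawford weighted RMS retinal spot of a ray fan.
#'
#' @param eye a [build_pseudophakic_eye()] result
#' @param config a [raytrace_config()]; defaults to the eye's own
#' @return spherical-equivalent refraction at the spectacle plane, D
#' @export
best_focus_refraction <- function(eye, config = NULL) {
  if (is.null(config)) config <- eye$config
  pupil_radius <- config$pupil_mm / 2
  h_p <- pupil_radius * config$focus_ray_fraction
  per_meridian <- vapply(eye$meridians, function(surf) {
    if (config$mode == "iso_single_ray") {
      meridian_refraction_iso(surf, eye$retina_z, eye$pupil_z, h_p,
                              config$vertex_mm)
    } else {
      meridian_refraction_rms(surf, eye$retina_z, eye$pupil_z, pupil_radius,
                              config)
    }
  }, numeric(1))
  mean(per_meridian)
}

#' Predicted refraction by ray tracing at a given implanted power
#'
#' Looks up/interpolates the lens geometry, predicts the IOL position with
#' the ACD/lens-thickness algorithm ([predict_iol_position()]), builds the
#' eye and evaluates [best_focus_refraction()].
#'
#' @param record one cohort row
#' @param iol an [iol_model()] with geometry
#' @param power implanted IOL power, D
#' @param config a [raytrace_config()]
#' @param elp_mode ELP mode forwarded to [predict_iol_position()]
#' @return predicted spherical equivalent, D
#' @export
raytrace_predicted_se <- function(record, iol, power,
                                  config = raytrace_config(),
                                  elp_mode = "auto") {
  geometry <- iol_geometry_at(iol, power)
  dm <- tryCatch(iol_geometry_at(iol, 21)$thickness, error = function(e) geometry$thickness)
  elp <- predict_iol_position(record, geometry, mode = elp_mode,
                              am_mm = iol$am_mm, dm_mm = dm)
  eye <- build_pseudophakic_eye(record, geometry, elp, config)
  best_focus_refraction(eye, config)
}

#' Solve the IOL power by ray tracing
#'
#' Finds the labeled power (0.5 D grid inside the model's geometry table)
#' whose ray-traced predicted refraction is closest to the target; midpoint
#' ties resolve to the higher power, as in the thin-lens module.
#'
#' @inheritParams raytrace_predicted_se
#' @param target_d target spectacle refraction, D
#' @param step power grid step, D
#' @return a `formula_result` with `formula_id = "raytrace"`
#' @export
solve_iol_power_raytrace <- function(record, iol, target_d = 0,
                                     config = raytrace_config(),
                                     elp_mode = "auto", step = 0.5) {
  if (!has_raytrace_geometry(iol)) {
    iolray_stop("iolray_capability_error",
                sprintf("model %s has no geometry table", iol$model_id))
  }
  rng <- range(iol$geometry$power)
  se_at <- function(p) raytrace_predicted_se(record, iol, p, config, elp_mode)
  f <- function(p) se_at(p) - target_d
  f_lo <- f(rng[1]); f_hi <- f(rng[2])
  # refraction decreases with power: f_lo > 0 > f_hi for a solvable eye
  if (f_lo * f_hi > 0) {
    p_star <- if (abs(f_lo) < abs(f_hi)) rng[1] else rng[2]
  } else {
    p_star <- uniroot(f, rng, f.lower = f_lo, f.upper = f_hi, tol = 1e-4)$root
  }
  cand <- unique(pmin(pmax(c(floor(p_star / step) * step,
                             ceiling(p_star / step) * step), rng[1]), rng[2]))
  se <- vapply(cand, se_at, numeric(1))
  d <- abs(se - target_d)
  i <- which(d < min(d) + 1e-9)
  i <- i[length(i)]   # tie -> higher power (grid is ascending)
  geometry <- iol_geometry_at(iol, cand[i])
  dm <- tryCatch(iol_geometry_at(iol, 21)$thickness, error = function(e) geometry$thickness)
  elp <- predict_iol_position(record, geometry, mode = elp_mode,
                              am_mm = iol$am_mm, dm_mm = dm)
  formula_result("raytrace", p_star, cand[i], se[i], elp$elp_center,
                 list(model_id = iol$model_id, elp_method = elp$method),
                 target_d)
}
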