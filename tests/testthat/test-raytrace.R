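# helper: a custom one-refraction "eye" for textbook checks
single_surface_eye <- function(radius = 7.7, n2 = 1.336,
                               retina_z = 1.336 * 7.7 / 0.336) {
  flat <- function(z) make_surface(z, 1e9, 0, 50, n2, n2)
  structure(list(
    meridians = list(list(make_surface(0, radius, 0, 50, 1, n2),
                          flat(1), flat(2), flat(3))),
    k = c(NA, NA), pupil_z = 2.5, pupil_diameter = 50, retina_z = retina_z,
    config = raytrace_config()), class = "pseudophakic_eye")
}

default_eye <- function(al = 23.5, k = 43, cct = 540, power = 21,
                        config = raytrace_config(), q_iol = 0) {
  rec <- make_record(al = al, k = k, cct = cct)
  iol <- synthetic_iol_database()[[if (q_iol == 0) "SYN-SPH" else "SYN-ASPH"]]
  g <- iol_geometry_at(iol, power)
  elp <- predict_iol_position(rec, g, am_mm = iol$am_mm)
  build_pseudophakic_eye(rec, g, elp, config)
}

test_that("conic intersection matches the exact sag", {
  s <- make_surface(0, 7.7, 0, 6, 1, 1.336)
  hit <- intersect_conic(make_ray(1, -5, 0), s)
  expect_equal(hit$z, 7.7 - sqrt(7.7^2 - 1), tolerance = 1e-12)  # 0.0652118
  expect_equal(hit$y, 1)
  # axial ray hits the vertex, normal along the axis
  hit0 <- intersect_conic(make_ray(0, -5, 0), s)
  expect_equal(hit0$z, 0, tolerance = 1e-12)
  expect_equal(abs(hit0$normal[2]), 1, tolerance = 1e-12)
  # parabola: sag is exactly y^2 / 2R
  sp <- make_surface(0, 10, -1, 6, 1, 1.336)
  for (y in c(0.5, 1.5, 2.5)) {
    expect_equal(intersect_conic(make_ray(y, -5, 0), sp)$z, y^2 / 20,
                 tolerance = 1e-12)
  }
  # aperture and miss handling
  expect_error(intersect_conic(make_ray(5.9, -5, 0), make_surface(0, 7.7, 0, 3, 1, 1.336)),
               class = "iolray_ray_escape")
})

test_that("Snell refraction is exact", {
  # flat interface, 30 degrees, 1.0 -> 1.5: sin(theta2) = 1/3
  ray <- make_ray(0, 0, tan(pi / 6))
  out <- refract_snell(ray, c(0, -1), 1.0, 1.5)
  expect_equal(atan(out$u), asin(1 / 3), tolerance = 1e-14)
  # index identity and normal incidence leave the ray unchanged
  expect_equal(refract_snell(ray, c(0, -1), 1.4, 1.4)$u, ray$u, tolerance = 1e-15)
  expect_equal(refract_snell(make_ray(1, 0, 0), c(0, -1), 1, 1.5)$u, 0)
  # total internal reflection is flagged (critical angle 41.8 deg here)
  expect_error(refract_snell(make_ray(0, 0, tan(50 * pi / 180)), c(0, -1), 1.5, 1.0),
               class = "iolray_ray_escape")
})

test_that("n sin(theta) is conserved at every interface on random rays", {
  set.seed(421)
  eye <- default_eye()
  worst <- 0
  for (i in 1:200) {
    ray <- make_ray(runif(1, -1, 1), -2, runif(1, -0.05, 0.05))
    tr <- tryCatch(trace_to_retina(eye, ray), iolray_error = function(e) NULL)
    if (is.null(tr)) next
    for (st in tr$path) {
      worst <- max(worst, abs(st$n_sin_incident - st$n_sin_refracted))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("tracing is reversible and meridionally symmetric", {
  eye <- default_eye()
  set.seed(77)
  for (i in 1:50) {
    y0 <- runif(1, -1, 1); u0 <- runif(1, -0.04, 0.04)
    tr <- trace_to_retina(eye, make_ray(y0, -2, u0))
    # mirror the meridian and send the exit ray back
    msurf <- iolray:::mirror_meridian(eye$meridians[[1]], eye$retina_z)
    exit <- tr$exit_ray
    back0 <- make_ray(exit$y + exit$u * (eye$retina_z - exit$z), 0, -exit$u)
    bk <- iolray:::trace_surfaces(msurf, back0)
    y_at_start <- bk$ray$y + bk$ray$u * ((eye$retina_z + 2) - bk$ray$z)
    expect_equal(y_at_start, y0, tolerance = 1e-9)
    # flipping the entry height flips the retinal height exactly
    tr_m <- trace_to_retina(eye, make_ray(-y0, -2, -u0))
    expect_equal(tr_m$y_retina, -tr$y_retina, tolerance = 1e-12)
  }
})

test_that("a single refracting surface focuses at the textbook distance", {
  # paraxial ray through one spherical surface: f = n2 R / (n2 - n1)
  eye <- single_surface_eye(7.7, 1.336)
  tr <- trace_to_retina(eye, make_ray(1e-4, -5, 0))
  z_cross <- tr$exit_ray$z - tr$exit_ray$y / tr$exit_ray$u
  expect_equal(z_cross, 1.336 * 7.7 / 0.336, tolerance = 1e-3)  # 30.615 mm
  # axial ray stays on axis
  expect_equal(trace_to_retina(eye, make_ray(0, -5, 0))$y_retina, 0)
})

test_that("rays beyond the pupil radius are clipped, not silently traced", {
  cfg <- raytrace_config(pupil_mm = 2.5)
  eye <- default_eye(config = cfg)
  expect_error(trace_to_retina(eye, make_ray(1.6, -2, 0)),
               class = "iolray_pupil_clip")
  # inside the pupil the same ray geometry traces fine
  expect_silent(trace_to_retina(eye, make_ray(0.9, -2, 0)))
})

test_that("eye assembly places the surfaces at the documented positions", {
  rec <- make_record(al = 23.5, k = 43, cct = 540)
  g <- iol_geometry(11.8, -11.8, 0.9, 1.46)
  eye <- build_pseudophakic_eye(rec, g, 4.9)
  zs <- vapply(eye$meridians[[1]], function(s) s$z_vertex, numeric(1))
  expect_equal(zs, c(0, 0.54, 0.54 + 4.9 - 0.45, 0.54 + 4.9 - 0.45 + 0.9),
               tolerance = 1e-12)
  expect_identical(eye$retina_z, 23.5)
  expect_gt(eye$pupil_z, zs[2])
  expect_lt(eye$pupil_z, zs[3])
  # an ELP at the retina violates surface ordering
  expect_error(build_pseudophakic_eye(rec, g, 23.5),
               class = "iolray_geometry_error")
  # default pupil is the study setting
  expect_identical(raytrace_config()$pupil_mm, 2.5)
})

test_that("best focus is zero when the ISO ray already crosses at the retina", {
  eye <- default_eye(al = 23.5)
  cfg <- eye$config
  h_p <- cfg$pupil_mm / 2 * cfg$focus_ray_fraction
  # independent forward construction: find the parallel entry ray whose
  # pupil-plane height is h_p, follow it, and put the retina where it
  # crosses the axis
  pupil_h <- function(y0) {
    tr <- trace_to_retina(eye, make_ray(y0, -2, 0))
    st <- tr$path[[2]]
    st$y + st$u * (eye$pupil_z - st$z)
  }
  y0 <- uniroot(function(y) pupil_h(y) - h_p, c(0.01, 1.2), tol = 1e-12)$root
  tr <- trace_to_retina(eye, make_ray(y0, -2, 0))
  z_cross <- tr$exit_ray$z - tr$exit_ray$y / tr$exit_ray$u
  eye2 <- eye
  eye2$retina_z <- z_cross
  expect_equal(best_focus_refraction(eye2), 0, tolerance = 1e-6)
})

test_that("at a tiny pupil the ray trace matches the paraxial oracle", {
  cfg <- raytrace_config(pupil_mm = 0.2)
  for (al in c(21.5, 23.5, 26)) {
    for (k in c(41, 43, 46)) {
      eye <- default_eye(al = al, k = k, config = cfg)
      expect_equal(best_focus_refraction(eye, cfg), paraxial_se(eye),
                   tolerance = 0.05, label = sprintf("al=%g k=%g", al, k))
    }
  }
})

test_that("a spherical biconvex IOL shows positive spherical aberration", {
  eye <- default_eye(power = 22)
  cross_of <- function(y0) {
    tr <- trace_to_retina(eye, make_ray(y0, -2, 0))
    tr$exit_ray$z - tr$exit_ray$y / tr$exit_ray$u
  }
  # marginal focus anterior to paraxial focus
  expect_lt(cross_of(1.1), cross_of(0.1))
})

test_that("Stiles-Crawford weighting follows the photometric convention", {
  expect_identical(stiles_crawford_weight(0), 1)
  expect_equal(stiles_crawford_weight(2, 0.116), 10^(-0.464), tolerance = 1e-12)
  ys <- seq(0, 3, by = 0.25)
  expect_true(all(diff(stiles_crawford_weight(ys)) < 0))
  expect_identical(stiles_crawford_weight(2, 0), 1)
})

test_that("the multi-ray RMS mode agrees broadly with the single-ray mode", {
  cfg_rms <- raytrace_config(mode = "rms_multiray")
  eye <- default_eye(config = cfg_rms)
  se_rms <- best_focus_refraction(eye, cfg_rms)
  se_iso <- best_focus_refraction(eye, raytrace_config())
  expect_lt(abs(se_rms - se_iso), 0.4)
})

test_that("ray-traced power solving respects the target and monotonicity", {
  iol <- synthetic_iol_database()[["SYN-SPH"]]
  chosen <- vapply(c(22, 24, 26), function(al) {
    solve_iol_power_raytrace(make_record(al = al, k = 43), iol)$chosen_power
  }, numeric(1))
  expect_true(all(diff(chosen) < 0))
  res <- solve_iol_power_raytrace(make_record(al = 23.5, k = 43), iol)
  expect_lt(abs(res$predicted_se), 0.35)
  # within 1.5 D of Holladay 1 for a normal eye
  h1 <- holladay1(make_record(al = 23.5, k = 43), 1.45)
  expect_lt(abs(res$emmetropic_power - h1$emmetropic_power), 1.5)
  # geometry-less model is a capability error
  thin <- iol_model("T", a_constant = 118.4)
  expect_error(solve_iol_power_raytrace(make_record(), thin),
               class = "iolray_capability_error")
})
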