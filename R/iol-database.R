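## IOL model database: per-model formula constants plus, for ray tracing,
## a table of physical lens geometry indexed by labeled power.

#' Construct an IOL geometry entry
#'
#' Signed vertex radii follow the raytracer's convention: positive radius
#' means the centre of curvature lies toward the retina (a front surface
#' convex toward the cornea has positive radius, a biconvex back surface a
#' negative one). `q` is the conic constant (0 = sphere, -1 = parabola).
#'
#' @param r_front,r_back signed vertex radii, mm (nonzero)
#' @param thickness central thickness, mm, in (0, 2.5)
#' @param n_iol refractive index of the lens material, in (1.4, 1.6)
#' @param q_front,q_back conic asphericities (default 0 = spherical)
#' @return list of class `iol_geometry`
#' @export
iol_geometry <- function(r_front, r_back, thickness, n_iol,
                         q_front = 0, q_back = 0) {
  if (!is.finite(r_front) || !is.finite(r_back) || r_front == 0 || r_back == 0) {
    iolray_stop("iolray_validation_error", "IOL vertex radii must be nonzero")
  }
  if (!(thickness > 0 && thickness < 2.5)) {
    iolray_stop("iolray_validation_error", "IOL thickness must be in (0, 2.5) mm")
  }
  if (!(n_iol > 1.4 && n_iol < 1.6)) {
    iolray_stop("iolray_validation_error", "IOL refractive index must be in (1.4, 1.6)")
  }
  structure(list(r_front = r_front, r_back = r_back, thickness = thickness,
                 n_iol = n_iol, q_front = q_front, q_back = q_back),
            class = "iol_geometry")
}

#' Construct an IOL model
#'
#' An IOL model carries the constants used by the thin-lens formulas
#' (A-constant for SRK/T, personalized ACD for Hoffer Q, surgeon factor for
#' Holladay 1, a0/a1/a2 for Haigis), the mean-eye IOL centre depth `am_mm`
#' used by the AL-scaled position formula, and optionally a geometry table
#' (one [iol_geometry()] per labeled power) enabling ray tracing.
#'
#' @param model_id model name (unique within a database)
#' @param a_constant,pacd,sf,a0,a1,a2 formula constants (NA when not available)
#' @param am_mm distance from the posterior cornea to the optical centre of
#'   this model in a mean-sized eye, mm (needed by the AL-scaled ELP formula)
#' @param geometry data.frame with columns `power, r_front, r_back, thickness,
#'   n_iol, q_front, q_back`, powers strictly increasing within \[-10, 40\] D,
#'   or NULL when the model supports thin-lens calculation only
#' @return list of class `iol_model`
#' @export
iol_model <- function(model_id, a_constant = NA, pacd = NA, sf = NA,
                      a0 = NA, a1 = NA, a2 = NA, am_mm = NA, geometry = NULL) {
  have_haigis <- !any(is.na(c(a0, a1, a2)))
  if (is.na(a_constant) && is.na(pacd) && is.na(sf) && !have_haigis) {
    iolray_stop("iolray_validation_error",
                sprintf("model %s: at least one constant set is required", model_id))
  }
  if (!is.null(geometry)) {
    need <- c("power", "r_front", "r_back", "thickness", "n_iol", "q_front", "q_back")
    if (!all(need %in% names(geometry))) {
      iolray_stop("iolray_schema_error",
                  sprintf("model %s: geometry table must have columns %s",
                          model_id, paste(need, collapse = ", ")))
    }
    if (any(diff(geometry$power) <= 0)) {
      iolray_stop("iolray_validation_error",
                  sprintf("model %s: geometry powers must be strictly increasing", model_id))
    }
    if (any(geometry$power < -10 | geometry$power > 40)) {
      iolray_stop("iolray_validation_error",
                  sprintf("model %s: geometry powers must lie in [-10, 40] D", model_id))
    }
    for (i in seq_len(nrow(geometry))) {  # validates each row
      iol_geometry(geometry$r_front[i], geometry$r_back[i], geometry$thickness[i],
                   geometry$n_iol[i], geometry$q_front[i], geometry$q_back[i])
    }
  }
  structure(list(model_id = model_id, a_constant = a_constant, pacd = pacd,
                 sf = sf, a0 = a0, a1 = a1, a2 = a2, am_mm = am_mm,
                 geometry = geometry),
            class = "iol_model")
}

#' Does an IOL model support ray tracing?
#' @param model an `iol_model`
#' @return TRUE when a geometry table is present
#' @export
has_raytrace_geometry <- function(model) {
  !is.null(model$geometry) && nrow(model$geometry) > 0
}

#' Look up (or interpolate) IOL geometry at a labeled power
#'
#' Exact table keys are returned as stored. Between labeled powers the
#' surfaces are interpolated linearly in curvature (1/radius), and linearly
#' in thickness, index and asphericity; curvature, not radius, scales
#' near-linearly with labeled power.
#'
#' @param model an `iol_model` with a geometry table
#' @param power labeled power, D, inside the table's range
#' @return an [iol_geometry()]
#' @export
iol_geometry_at <- function(model, power) {
  if (!has_raytrace_geometry(model)) {
    iolray_stop("iolray_capability_error",
                sprintf("model %s has no geometry table; ray tracing unavailable",
                        model$model_id))
  }
  g <- model$geometry
  if (power < min(g$power) || power > max(g$power)) {
    iolray_stop("iolray_domain_error",
                sprintf("power %.2f D outside geometry table range [%.2f, %.2f]",
                        power, min(g$power), max(g$power)))
  }
  hit <- which(abs(g$power - power) < 1e-9)
  if (length(hit) == 1) {
    i <- hit
    return(iol_geometry(g$r_front[i], g$r_back[i], g$thickness[i],
                        g$n_iol[i], g$q_front[i], g$q_back[i]))
  }
  i <- findInterval(power, g$power)
  w <- (power - g$power[i]) / (g$power[i + 1] - g$power[i])
  lerp <- function(a, b) (1 - w) * a + w * b
  # interpolate in curvature; keep a tiny floor so a sign change across the
  # interval yields an optically plano (huge-radius) surface, not 1/0
  inv <- function(c_) sign(c_ + (c_ == 0) * 1e-12) / pmax(abs(c_), 1e-7)
  cf <- lerp(1 / g$r_front[i], 1 / g$r_front[i + 1])
  cb <- lerp(1 / g$r_back[i], 1 / g$r_back[i + 1])
  iol_geometry(inv(cf), inv(cb),
               lerp(g$thickness[i], g$thickness[i + 1]),
               lerp(g$n_iol[i], g$n_iol[i + 1]),
               lerp(g$q_front[i], g$q_front[i + 1]),
               lerp(g$q_back[i], g$q_back[i + 1]))
}

#' Read an IOL database from JSON
#'
#' The file holds a list of objects `{model_id, a_constant, pacd, sf, a0, a1,
#' a2, am_mm, geometry:[{power_d, r_front_mm, r_back_mm, thickness_mm, n_iol,
#' q_front, q_back}]}`; all constants and the geometry block are optional.
#'
#' @param path path to the JSON file
#' @return named list of [iol_model()] objects (class `iol_database`)
#' @export
read_iol_database <- function(path) {
  if (!file.exists(path)) {
    iolray_stop("iolray_io_error", paste0("file not found: ", path))
  }
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- list()
  grab <- function(e, f) if (is.null(e[[f]])) NA_real_ else as.numeric(e[[f]])
  for (e in entries) {
    if (is.null(e$model_id)) {
      iolray_stop("iolray_schema_error", "IOL database entry without model_id")
    }
    if (e$model_id %in% names(models)) {
      iolray_stop("iolray_validation_error",
                  sprintf("duplicate model_id '%s' in IOL database", e$model_id))
    }
    geometry <- NULL
    if (!is.null(e$geometry) && length(e$geometry)) {
      rows <- lapply(e$geometry, function(g) {
        data.frame(power = as.numeric(g$power_d),
                   r_front = as.numeric(g$r_front_mm),
                   r_back = as.numeric(g$r_back_mm),
                   thickness = as.numeric(g$thickness_mm),
                   n_iol = as.numeric(g$n_iol),
                   q_front = if (is.null(g$q_front)) 0 else as.numeric(g$q_front),
                   q_back = if (is.null(g$q_back)) 0 else as.numeric(g$q_back))
      })
      geometry <- do.call(rbind, rows)
      geometry <- geometry[order(geometry$power), , drop = FALSE]
    }
    models[[e$model_id]] <- iol_model(
      e$model_id, a_constant = grab(e, "a_constant"), pacd = grab(e, "pacd"),
      sf = grab(e, "sf"), a0 = grab(e, "a0"), a1 = grab(e, "a1"),
      a2 = grab(e, "a2"), am_mm = grab(e, "am_mm"), geometry = geometry)
  }
  structure(models, class = "iol_database")
}

#' Write an IOL database to JSON
#' @param db an `iol_database`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_iol_database <- function(db, path) {
  entries <- lapply(unname(db), function(m) {
    e <- list(model_id = m$model_id)
    for (f in c("a_constant", "pacd", "sf", "a0", "a1", "a2", "am_mm")) {
      if (!is.na(m[[f]])) e[[f]] <- m[[f]]
    }
    if (has_raytrace_geometry(m)) {
      g <- m$geometry
      e$geometry <- lapply(seq_len(nrow(g)), function(i) list(
        power_d = g$power[i], r_front_mm = g$r_front[i], r_back_mm = g$r_back[i],
        thickness_mm = g$thickness[i], n_iol = g$n_iol[i],
        q_front = g$q_front[i], q_back = g$q_back[i]))
    }
    e
  })
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Built-in synthetic IOL database
#'
#' Two fully synthetic lens models used by the simulation study and the
#' examples (they resemble no commercial lens): `SYN-SPH`, a spherical
#' equiconvex acrylic design (n = 1.46), and `SYN-ASPH`, the same design
#' with a prolate posterior surface. Geometry is tabulated from -10 D to
#' 40 D in 2 D steps; surface curvature scales linearly with labeled power
#' (`1/r = P / (2 (n - 1.336) 1000)` per surface) and central thickness grows
#' from 0.3 mm to about 1.1 mm across the range. Thin-lens constants are
#' typical monofocal values (A = 118.4 and standard conversions).
#'
#' @return an `iol_database` with models `SYN-SPH` and `SYN-ASPH`
#' @export
synthetic_iol_database <- function() {
  powers <- seq(-10, 40, by = 2)
  n_iol <- 1.46
  curv <- powers / (2 * (n_iol - 1.336) * 1000)        # per-surface curvature, 1/mm
  curv_safe <- sign(curv + (curv == 0) * 1e-12) / pmax(abs(curv), 1e-7)
  geom <- function(q_back) data.frame(
    power = powers,
    r_front = curv_safe, r_back = -curv_safe,
    thickness = pmax(0.3, 0.5 + 0.016 * powers),
    n_iol = n_iol, q_front = 0, q_back = q_back)
  db <- list(
    `SYN-SPH` = iol_model("SYN-SPH", a_constant = 118.4, pacd = 5.20,
                          sf = 1.45, a0 = 1.30, a1 = 0.4, a2 = 0.1,
                          am_mm = 4.7, geometry = geom(0)),
    `SYN-ASPH` = iol_model("SYN-ASPH", a_constant = 118.4, pacd = 5.20,
                           sf = 1.45, a0 = 1.30, a1 = 0.4, a2 = 0.1,
                           am_mm = 4.7, geometry = geom(-1.0)))
  structure(db, class = "iol_database")
}

#' @export
print.iol_database <- function(x, ...) {
  cat(sprintf("<iol_database> %d model(s)\n", length(x)))
  for (m in x) {
    cat(sprintf("  %-10s A=%s pACD=%s SF=%s a0/a1/a2=%s/%s/%s raytrace=%s\n",
                m$model_id, format(m$a_constant), format(m$pacd), format(m$sf),
                format(m$a0), format(m$a1), format(m$a2),
                if (has_raytrace_geometry(m)) "yes" else "no"))
  }
  invisible(x)
}
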