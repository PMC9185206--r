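## Effective lens position (ELP) prediction.
##
## The position the IOL settles at after surgery is the hidden variable of
## every power calculation. Distances here are measured from the posterior
## corneal vertex to the IOL optical centre (elp_center); the anterior-vertex
## value follows exactly as elp_center - thickness/2.

elp_prediction <- function(elp_center, thickness = 0, method) {
  structure(list(elp_center = elp_center,
                 elp_front_vertex = elp_center - thickness / 2,
                 method = method),
            class = "elp_prediction")
}

#' @export
print.elp_prediction <- function(x, ...) {
  cat(sprintf("<elp_prediction> %s: centre %.4f mm (front vertex %.4f mm)\n",
              x$method, x$elp_center, x$elp_front_vertex))
  invisible(x)
}

#' AL-scaled IOL position formula
#'
#' Scales a reference postoperative depth with axial length:
#' `A_a = C_m (a / a_m)^0.7 + A_m - C_m - 0.5 (d - d_m)`, where `C_m` is the
#' posterior-cornea-to-centre distance of a 21 D reference IOL in a mean-sized
#' eye (4.6 mm), `a_m` the mean axial length (23.6 mm), `A_m` the mean-eye
#' depth of the model of interest and `d`, `d_m` the central thicknesses of
#' the lens of interest and the 21 D reference lens. At `a = a_m` and
#' `d = d_m` the formula returns `A_m` identically, for any exponent.
#'
#' @param al axial length of the eye of interest, mm (15-40)
#' @param am_mm mean-eye IOL centre depth of the model of interest, mm
#' @param d_mm central thickness of the IOL of interest, mm
#' @param dm_mm central thickness of the 21 D reference IOL, mm
#' @param cm_mm reference depth of the 21 D IOL in the mean eye (default 4.6)
#' @param alm_mm mean axial length (default 23.6)
#' @param exponent axial-length scaling exponent (default 0.7)
#' @return an `elp_prediction` (method `"scaled_al"`)
#' @export
elp_scaled_al <- function(al, am_mm, d_mm, dm_mm,
                          cm_mm = 4.6, alm_mm = 23.6, exponent = 0.7) {
  if (!is.finite(al) || al < 15 || al > 40) {
    iolray_stop("iolray_domain_error", sprintf("al=%.4g outside [15, 40] mm", al))
  }
  if (!is.finite(d_mm) || d_mm <= 0 || !is.finite(dm_mm) || dm_mm <= 0) {
    iolray_stop("iolray_domain_error", "IOL thicknesses must be positive")
  }
  centre <- cm_mm * (al / alm_mm)^exponent + am_mm - cm_mm - 0.5 * (d_mm - dm_mm)
  elp_prediction(centre, d_mm, "scaled_al")
}

#' ACD + lens-thickness IOL position formula
#'
#' Predicts the postoperative IOL centre from the preoperative anterior
#' chamber depth and crystalline lens thickness:
#' `A = A_p + 0.574 t_L - 0.632 - 0.5 d`.
#'
#' @param acd preoperative anterior chamber depth `A_p`, mm (1.5-5.5),
#'   referenced to the posterior cornea
#' @param lt crystalline lens thickness `t_L`, mm (2.5-6.5)
#' @param d_mm central thickness of the IOL, mm
#' @param strict validate physiologic input ranges (disable only for
#'   degenerate algebraic checks)
#' @return an `elp_prediction` (method `"lens_thickness"`)
#' @export
elp_lens_thickness <- function(acd, lt, d_mm, strict = TRUE) {
  if (strict) {
    if (!is.finite(acd) || acd < 1.5 || acd > 5.5) {
      iolray_stop("iolray_domain_error", sprintf("acd=%.4g outside [1.5, 5.5] mm", acd))
    }
    if (!is.finite(lt) || lt < 2.5 || lt > 6.5) {
      iolray_stop("iolray_domain_error", sprintf("lt=%.4g outside [2.5, 6.5] mm", lt))
    }
  }
  if (!is.finite(d_mm) || d_mm < 0) {
    iolray_stop("iolray_domain_error", "IOL thickness must be nonnegative")
  }
  centre <- acd + 0.574 * lt - 0.632 - 0.5 * d_mm
  elp_prediction(centre, d_mm, "lens_thickness")
}

#' Haigis effective lens position
#'
#' The linear Haigis predictor `d = a0 + a1 ACD + a2 AL` with the three
#' IOL-specific constants tied to the lens, the anterior chamber depth and
#' the axial length respectively.
#'
#' @param acd preoperative anterior chamber depth, mm
#' @param al axial length, mm
#' @param a0,a1,a2 Haigis constants (finite)
#' @param d_mm IOL central thickness used to derive the front-vertex value
#'   (default 0: the thin-lens usage needs only the effective plane)
#' @return an `elp_prediction` (method `"haigis"`)
#' @export
elp_haigis <- function(acd, al, a0, a1, a2, d_mm = 0) {
  if (!all(is.finite(c(acd, al, a0, a1, a2)))) {
    iolray_stop("iolray_domain_error", "Haigis ELP inputs must be finite")
  }
  elp_prediction(a0 + a1 * acd + a2 * al, d_mm, "haigis")
}

#' Predict the postoperative IOL position for a biometry record
#'
#' The raytracer's lens-position algorithm: the AL-scaled formula
#' ([elp_scaled_al()]) and the ACD/lens-thickness formula
#' ([elp_lens_thickness()]) are evaluated and, in the default `"auto"` mode,
#' averaged when both ACD and LT are available (method tag `"mean"`),
#' falling back to the AL-scaled formula otherwise. The preoperative ACD is
#' converted from the device's epithelium reference to the posterior-cornea
#' reference by subtracting `cct/1000` when CCT is present.
#'
#' @param record one cohort row (data.frame or list with `al`, `acd`, `lt`,
#'   `cct`)
#' @param geometry an [iol_geometry()] for the implanted/planned lens
#' @param mode `"auto"`, `"mean"`, `"scaled_al"` or `"lens_thickness"`
#' @param am_mm mean-eye IOL centre depth of the model (required by
#'   `scaled_al` and `mean`)
#' @param dm_mm reference (21 D) IOL thickness; defaults to the geometry's own
#'   thickness when not supplied
#' @param cm_mm,alm_mm,exponent constants of the AL-scaled formula
#' @return an `elp_prediction`
#' @export
predict_iol_position <- function(record, geometry,
                                 mode = c("auto", "mean", "scaled_al", "lens_thickness"),
                                 am_mm = NA, dm_mm = NULL,
                                 cm_mm = 4.6, alm_mm = 23.6, exponent = 0.7) {
  mode <- match.arg(mode)
  d <- geometry$thickness
  if (is.null(dm_mm)) dm_mm <- d
  has_acd <- !is.null(record$acd) && !is.na(record$acd)
  has_lt <- !is.null(record$lt) && !is.na(record$lt)
  if (mode == "auto") mode <- if (has_acd && has_lt) "mean" else "scaled_al"
  acd_post <- if (has_acd) {
    record$acd - (if (!is.null(record$cct) && !is.na(record$cct)) record$cct / 1000 else 0)
  } else NA_real_

  scaled <- function() {
    if (is.na(am_mm)) {
      iolray_stop("iolray_capability_error",
                  "AL-scaled ELP requires the model mean-eye depth am_mm")
    }
    elp_scaled_al(record$al, am_mm, d, dm_mm, cm_mm, alm_mm, exponent)
  }
  lens <- function() {
    if (!has_acd || !has_lt) {
      iolray_stop("iolray_capability_error",
                  "lens-thickness ELP requires both acd and lt")
    }
    elp_lens_thickness(acd_post, record$lt, d)
  }
  switch(mode,
    scaled_al = scaled(),
    lens_thickness = lens(),
    mean = {
      a <- scaled(); b <- lens()
      elp_prediction((a$elp_center + b$elp_center) / 2, d, "mean")
    })
}
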