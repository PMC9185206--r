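## Paraxial (Gaussian) vergence chain shared by all thin-lens formulas:
## object at infinity (or at the spectacle-corrected far point), refraction
## at a thin cornea, translation through aqueous to the thin IOL, and the
## requirement that the image lands on the retina.

#' Refraction plane conversions
#'
#' Transfers a refraction between the spectacle plane and the corneal plane
#' across a vertex distance (default 12 mm):
#' `R_cornea = R_spec / (1 - v R_spec)`, and back.
#'
#' @param rx refraction at the spectacle plane, D
#' @param rc refraction at the corneal plane, D
#' @param vertex_mm vertex distance, mm
#' @return diopters at the other plane
#' @export
corneal_plane_refraction <- function(rx, vertex_mm = 12) {
  rx / (1 - vertex_mm / 1000 * rx)
}

#' @rdname corneal_plane_refraction
#' @export
spectacle_plane_refraction <- function(rc, vertex_mm = 12) {
  rc / (1 + vertex_mm / 1000 * rc)
}

#' Predicted refraction from the two-element paraxial vergence chain
#'
#' For a thin cornea of power `k_d`, a thin IOL of power `p_iol` at depth
#' `elp` and a retina at `al`, returns the spectacle-plane refraction that
#' focuses a distant object on the retina. The chain runs in aqueous/vitreous
#' of index 1.336 throughout; the predicted refraction is strictly
#' decreasing in `p_iol`.
#'
#' @param al optical axial length, mm
#' @param k_d corneal power, D
#' @param elp effective lens position (corneal plane to thin IOL), mm
#' @param p_iol IOL power, D
#' @param n_aqueous index between cornea and retina (default 1.336)
#' @param vertex_mm spectacle vertex distance, mm (default 12)
#' @return predicted spherical-equivalent refraction at the spectacle plane, D
#' @examples
#' predict_refraction_vergence(23.5, 43, 5, 20.97)  # ~0 D
#' @export
predict_refraction_vergence <- function(al, k_d, elp, p_iol,
                                        n_aqueous = 1.336, vertex_mm = 12) {
  if (!(elp > 0 && elp < al)) {
    iolray_stop("iolray_domain_error", "elp must lie strictly inside (0, al)")
  }
  nk <- n_aqueous * 1000
  v_retina <- nk / (al - elp)          # vergence the IOL must produce
  v2 <- v_retina - p_iol               # vergence arriving at the IOL plane
  den <- 1 + elp * v2 / nk
  if (abs(den) < 1e-12) {
    iolray_stop("iolray_numeric_error",
                "vergence singularity: image at infinity between cornea and IOL")
  }
  v1 <- v2 / den                       # vergence leaving the cornea
  rc <- v1 - k_d                       # required corneal-plane refraction
  den2 <- 1 + vertex_mm / 1000 * rc
  if (abs(den2) < 1e-12) {
    iolray_stop("iolray_numeric_error",
                "vergence singularity at the spectacle plane")
  }
  spectacle_plane_refraction(rc, vertex_mm)
}

#' Emmetropizing IOL power from the vergence chain
#'
#' The IOL power that makes the chain of [predict_refraction_vergence()]
#' return exactly the target spectacle refraction.
#'
#' @inheritParams predict_refraction_vergence
#' @param target_d target spectacle refraction, D (default 0)
#' @return IOL power, D
#' @export
solve_power_vergence <- function(al, k_d, elp, target_d = 0,
                                 n_aqueous = 1.336, vertex_mm = 12) {
  if (!(elp > 0 && elp < al)) {
    iolray_stop("iolray_domain_error", "elp must lie strictly inside (0, al)")
  }
  nk <- n_aqueous * 1000
  v1 <- k_d + corneal_plane_refraction(target_d, vertex_mm)
  den <- 1 - elp * v1 / nk
  if (abs(den) < 1e-12) {
    iolray_stop("iolray_numeric_error",
                "vergence singularity: corneal image at the IOL plane")
  }
  nk / (al - elp) - v1 / den
}
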