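#' Keratometric power/radius conversion
#'
#' Keratometers report the front corneal curvature as a dioptric power through
#' a fictitious keratometric index: `P = (n_k - 1) * 1000 / r`. The standard
#' index is 1.3375 (so a 7.5 mm radius reads 45.0 D); the Haigis formula uses
#' 1.3315 on the same measured radius.
#'
#' @param radius_mm front corneal radius of curvature, mm
#' @param k_d keratometric reading, diopters
#' @param n_k keratometric index (default 1.3375)
#' @return `corneal_power()` returns diopters; `corneal_radius()` millimetres.
#' @examples
#' corneal_power(7.5)               # 45 D
#' corneal_radius(45)               # 7.5 mm
#' corneal_power(7.5, n_k = 1.3315) # 44.2 D (Haigis convention)
#' @export
corneal_power <- function(radius_mm, n_k = 1.3375) {
  stopifnot(is.numeric(radius_mm), n_k > 1.3, n_k < 1.4)
  if (any(radius_mm <= 0)) {
    iolray_stop("iolray_domain_error", "corneal radius must be positive")
  }
  (n_k - 1) * 1000 / radius_mm
}

#' @rdname corneal_power
#' @export
corneal_radius <- function(k_d, n_k = 1.3375) {
  stopifnot(is.numeric(k_d), n_k > 1.3, n_k < 1.4)
  if (any(k_d <= 0)) {
    iolray_stop("iolray_domain_error", "keratometry reading must be positive")
  }
  (n_k - 1) * 1000 / k_d
}

# mean keratometry of a record row (SE convention: mean of the two meridians)
mean_k <- function(record) (record$k1 + record$k2) / 2
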