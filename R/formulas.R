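## The four classic thin-lens IOL formulas. Each one is its published ELP
## model composed with the shared paraxial vergence chain (vergence.R); the
## formula-specific parts are the effective corneal power convention, the
## optical axial length and the predicted lens plane.

formula_result <- function(formula_id, emmetropic_power, chosen_power,
                           predicted_se, elp_used, constants_used, target_d) {
  structure(list(formula_id = formula_id,
                 emmetropic_power = emmetropic_power,
                 chosen_power = chosen_power,
                 predicted_se = predicted_se,
                 elp_used = elp_used,
                 constants_used = constants_used,
                 target_d = target_d),
            class = "formula_result")
}

#' @export
print.formula_result <- function(x, ...) {
  cat(sprintf("<formula_result> %s: emmetropic %.3f D, chosen %.2f D, predicted SE %+.3f D (ELP %.3f mm)\n",
              x$formula_id, x$emmetropic_power, x$chosen_power,
              x$predicted_se, x$elp_used))
  invisible(x)
}

# pick the grid power whose predicted refraction is closest to target;
# exact midpoint ties resolve to the higher power (the more myopic outcome)
choose_iol_power <- function(ref_fun, p_emme, target_d, step = 0.5, span = 2) {
  cand <- seq(floor((p_emme - span) / step) * step,
              ceiling((p_emme + span) / step) * step, by = step)
  se <- vapply(cand, ref_fun, numeric(1))
  d <- abs(se - target_d)
  i <- which(d < min(d) + 1e-9)
  i <- i[length(i)]
  list(power = cand[i], se = se[i])
}

# shared tail: given the formula's (al_opt, k_eff, elp), solve and select
thin_lens_solution <- function(formula_id, al_opt, k_eff, elp, target_d,
                               step, constants) {
  ref_fun <- function(p) predict_refraction_vergence(al_opt, k_eff, elp, p)
  p_emme <- solve_power_vergence(al_opt, k_eff, elp, target_d = 0)
  sel <- choose_iol_power(ref_fun, p_emme, target_d, step)
  formula_result(formula_id, p_emme, sel$power, sel$se, elp, constants, target_d)
}

record_mean_k <- function(record) {
  if (is.na(record$k1) || is.na(record$k2)) {
    iolray_stop("iolray_capability_error", "keratometry (k1, k2) required")
  }
  (record$k1 + record$k2) / 2
}

#' SRK/T formula
#'
#' The third-generation SRK/T calculation: axial-length correction for long
#' eyes, corneal width and corneal height, the A-constant-derived ACD
#' constant, a retinal-thickness term added to the optical axial length, and
#' the vergence chain with the SRK/T corneal index (1.333). When the
#' corneal-height radicand is negative (extreme K/AL combinations) it is
#' clamped to zero, as in the original publication, with a warning.
#'
#' @param record one cohort row (needs `al`, `k1`, `k2`)
#' @param a_constant SRK/T A-constant
#' @param target_d target spectacle refraction, D
#' @param step IOL power grid step, D (default 0.5)
#' @return a `formula_result`
#' @export
srkt <- function(record, a_constant, target_d = 0, step = 0.5) {
  if (is.na(a_constant)) {
    iolray_stop("iolray_capability_error", "SRK/T requires an A-constant")
  }
  L <- record$al
  K <- record_mean_k(record)
  r <- 337.5 / K
  lcor <- if (L > 24.2) -3.446 + 1.715 * L - 0.0237 * L^2 else L
  cw <- -5.41 + 0.58412 * lcor + 0.098 * K
  arg <- r^2 - cw^2 / 4
  if (arg < 0) {
    warning("SRK/T corneal-height radicand negative; clamped to zero")
    arg <- 0
  }
  h <- r - sqrt(arg)
  acd_const <- 0.62467 * a_constant - 68.747
  elp <- h + acd_const - 3.336
  l_opt <- L + 0.65696 - 0.02029 * L
  k_eff <- 0.333 * 1000 / r
  thin_lens_solution("srkt", l_opt, k_eff, elp, target_d, step,
                     list(a_constant = a_constant))
}

#' Hoffer Q formula
#'
#' The Hoffer Q predicted chamber depth (personalized ACD constant, a 0.3
#' mm/mm axial-length slope, the tangent keratometry term and the short/long
#' eye correction with the axial length clamped to \[18.5, 31\] mm) composed
#' with the vergence chain at the 1.3375 keratometric power.
#'
#' @inheritParams srkt
#' @param pacd personalized ACD constant
#' @return a `formula_result`
#' @export
hofferq <- function(record, pacd, target_d = 0, step = 0.5) {
  if (is.na(pacd)) {
    iolray_stop("iolray_capability_error", "Hoffer Q requires a pACD constant")
  }
  L <- record$al
  K <- record_mean_k(record)
  A <- min(max(L, 18.5), 31)
  if (A <= 23) { M <- 1; G <- 28 } else { M <- -1; G <- 23.5 }
  tand <- function(x) tan(x * pi / 180)
  acd <- pacd + 0.3 * (A - 23.5) + tand(K)^2 +
    0.1 * M * (23.5 - A)^2 * tand(0.1 * (G - A)^2) - 0.99166
  # the published power equation uses elp + 0.05 on both sides of the lens
  thin_lens_solution("hofferq", L, K, acd + 0.05, target_d, step,
                     list(pacd = pacd))
}

#' Holladay 1 formula
#'
#' Corneal-height anatomical ACD (corneal radius clamped at 7 mm, corneal
#' width 12.5 AL/23.45 capped at 13.5 mm) plus the surgeon factor, a 0.2 mm
#' retinal-thickness addition to the axial length, and the vergence chain at
#' the 4/3 corneal index.
#'
#' @inheritParams srkt
#' @param sf surgeon factor, mm
#' @return a `formula_result`
#' @export
holladay1 <- function(record, sf, target_d = 0, step = 0.5) {
  if (is.na(sf)) {
    iolray_stop("iolray_capability_error", "Holladay 1 requires a surgeon factor")
  }
  L <- record$al
  K <- record_mean_k(record)
  r <- 337.5 / K
  rag <- max(r, 7)
  ag <- min(12.5 * L / 23.45, 13.5)
  acd <- 0.56 + rag - sqrt(rag^2 - ag^2 / 4)
  elp <- acd + sf
  l_opt <- L + 0.2
  k_eff <- (1 / 3) * 1000 / r
  thin_lens_solution("holladay1", l_opt, k_eff, elp, target_d, step,
                     list(sf = sf))
}

#' Haigis formula
#'
#' The fourth-generation Haigis calculation: effective lens position from the
#' triple-constant linear predictor [elp_haigis()] and the vergence chain
#' with the corneal power re-expressed at the 1.3315 keratometric index.
#'
#' @inheritParams srkt
#' @param a0,a1,a2 Haigis constants
#' @return a `formula_result`
#' @export
haigis_formula <- function(record, a0, a1, a2, target_d = 0, step = 0.5) {
  if (any(is.na(c(a0, a1, a2)))) {
    iolray_stop("iolray_capability_error", "Haigis requires a0, a1 and a2")
  }
  if (is.null(record$acd) || is.na(record$acd)) {
    iolray_stop("iolray_capability_error", "Haigis requires the preoperative ACD")
  }
  L <- record$al
  K <- record_mean_k(record)
  r <- 337.5 / K
  elp <- elp_haigis(record$acd, L, a0, a1, a2)$elp_center
  k_eff <- 331.5 / r
  thin_lens_solution("haigis", L, k_eff, elp, target_d, step,
                     list(a0 = a0, a1 = a1, a2 = a2))
}

#' Axial-length based formula selection
#'
#' The clinical selection rule used for implanted-power planning: Hoffer Q
#' below 22 mm, Holladay 1 from 22 through 26 mm, SRK/T above 26 mm.
#'
#' @param al axial length, mm
#' @return one of `"hofferq"`, `"holladay1"`, `"srkt"`
#' @export
select_formula_by_al <- function(al) {
  stopifnot(is.finite(al))
  if (al < 22) "hofferq" else if (al <= 26) "holladay1" else "srkt"
}

#' Run one thin-lens formula (or the AL-based automatic choice) on a record
#'
#' @param record one cohort row
#' @param iol an [iol_model()] supplying the constants
#' @param formula `"auto"` (AL rule), `"srkt"`, `"hofferq"`, `"holladay1"` or
#'   `"haigis"`
#' @param target_d target spectacle refraction, D
#' @param step IOL power grid step, D
#' @return a `formula_result`
#' @export
calculate_formula <- function(record, iol,
                              formula = c("auto", "srkt", "hofferq",
                                          "holladay1", "haigis"),
                              target_d = 0, step = 0.5) {
  formula <- match.arg(formula)
  if (formula == "auto") formula <- select_formula_by_al(record$al)
  switch(formula,
    srkt = srkt(record, iol$a_constant, target_d, step),
    hofferq = hofferq(record, iol$pacd, target_d, step),
    holladay1 = holladay1(record, iol$sf, target_d, step),
    haigis = haigis_formula(record, iol$a0, iol$a1, iol$a2, target_d, step))
}

#' Predicted refraction of a thin-lens formula at a given implanted power
#'
#' @inheritParams calculate_formula
#' @param power implanted IOL power, D
#' @return predicted spectacle-plane spherical equivalent, D
#' @export
formula_predicted_se <- function(record, iol, power,
                                 formula = c("srkt", "hofferq", "holladay1",
                                             "haigis")) {
  formula <- match.arg(formula)
  res <- calculate_formula(record, iol, formula, target_d = 0)
  # re-evaluate the same chain at the requested power
  elp <- res$elp_used
  al_k <- switch(formula,
    srkt = {
      r <- 337.5 / record_mean_k(record)
      c(record$al + 0.65696 - 0.02029 * record$al, 333 / r)
    },
    hofferq = c(record$al, record_mean_k(record)),
    holladay1 = {
      r <- 337.5 / record_mean_k(record)
      c(record$al + 0.2, (1000 / 3) / r)
    },
    haigis = {
      r <- 337.5 / record_mean_k(record)
      c(record$al, 331.5 / r)
    })
  predict_refraction_vergence(al_k[1], al_k[2], elp, power)
}
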