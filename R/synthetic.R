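## Synthetic biometry cohorts with a known-truth optical forward model.
##
## The generator reproduces the statistical structure of a cataract-surgery
## biometry population: a two-component truncated-normal axial-length
## mixture calibrated to the study's printed AL distribution (mean 23.66 mm,
## SD 2.07, range 19-35, bin frequencies 11.7 / 59.6 / 19.7 / 6.9 / 2.1 %),
## physiologically correlated ACD / LT / K, a small fraction of bilateral
## patients sharing a patient-level random effect, and a forward model in
## which the "true" postoperative refraction is computed by the package's
## own ray tracer at a noise-perturbed true lens position.

#' Synthetic cohort configuration
#'
#' All distributional defaults are fixed study conditions (see the package
#' vignette for their provenance); `n` and `seed` are the knobs a user
#' normally touches.
#'
#' @param n number of eyes to generate
#' @param seed integer RNG seed; the whole pipeline is reproducible given it
#' @param al_mixture truncated-normal mixture for axial length: list with
#'   `weights`, `means`, `sds` (two components) and `range`
#' @param k_model mean-keratometry model: `k = mean + slope (al - 23.66) +
#'   N(0, sd)` plus a half-normal corneal cylinder of scale `cyl_sd`
#' @param acd_model,lt_model linear-in-AL models `intercept + slope * al +
#'   N(0, sd)` for anterior chamber depth and lens thickness, mm
#' @param cct_dist,wtw_dist,pupil_dist mean/SD of central corneal thickness
#'   (um), corneal diameter (mm) and photopic pupil (mm)
#' @param elp_noise_sd SD of the true-minus-predicted lens position, mm
#' @param refraction_noise_sd SD of the refraction measurement noise, D
#' @param patient_noise_share share of the ELP/refraction noise variance
#'   carried by a patient-level component shared between fellow eyes (drives
#'   the inter-eye correlation of prediction errors; 0 = independent eyes)
#' @param refraction_rounding rounding step of the recorded refraction, D
#'   (0 disables rounding)
#' @param bilateral_fraction share of patients contributing both eyes
#' @param iol_model id of the IOL model implanted in every eye
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n = 188, seed = 1L,
                          al_mixture = list(weights = c(0.6777, 0.3223),
                                            means = c(23.4258, 21.7461),
                                            sds = c(0.6933, 5.0872),
                                            range = c(19, 35)),
                          k_model = list(mean = 43.5, slope = -0.21,
                                         sd = 1.35, cyl_sd = 0.75),
                          acd_model = list(intercept = 1.10, slope = 0.098,
                                           sd = 0.22),
                          lt_model = list(intercept = 7.15, slope = -0.115,
                                          sd = 0.20),
                          cct_dist = list(mean = 540, sd = 32),
                          wtw_dist = list(mean = 11.8, sd = 0.35),
                          pupil_dist = list(mean = 3.2, sd = 0.5),
                          elp_noise_sd = 0.25,
                          refraction_noise_sd = 0.35,
                          patient_noise_share = 0.5,
                          refraction_rounding = 0.25,
                          bilateral_fraction = 8 / 180,
                          iol_model = "SYN-SPH") {
  stopifnot(n >= 1, abs(sum(al_mixture$weights) - 1) < 1e-8,
            all(al_mixture$sds > 0), elp_noise_sd >= 0,
            refraction_noise_sd >= 0, refraction_rounding >= 0,
            patient_noise_share >= 0, patient_noise_share <= 1,
            bilateral_fraction >= 0, bilateral_fraction <= 1)
  if (al_mixture$range[1] >= al_mixture$range[2]) {
    iolray_stop("iolray_config_error", "infeasible AL truncation range")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 al_mixture = al_mixture, k_model = k_model,
                 acd_model = acd_model, lt_model = lt_model,
                 cct_dist = cct_dist, wtw_dist = wtw_dist,
                 pupil_dist = pupil_dist, elp_noise_sd = elp_noise_sd,
                 refraction_noise_sd = refraction_noise_sd,
                 patient_noise_share = patient_noise_share,
                 refraction_rounding = refraction_rounding,
                 bilateral_fraction = bilateral_fraction,
                 iol_model = iol_model),
            class = "cohort_config")
}

# draw n axial lengths from the mixture of component-wise truncated normals
# (each component renormalized on the range, matching the calibration)
draw_al <- function(n, mix) {
  comp <- sample.int(2L, n, replace = TRUE, prob = mix$weights)
  x <- rnorm(n, mix$means[comp], mix$sds[comp])
  bad <- which(x < mix$range[1] | x > mix$range[2])
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mix$means[comp[bad]], mix$sds[comp[bad]])
    bad <- bad[x[bad] < mix$range[1] | x[bad] > mix$range[2]]
    guard <- guard + 1L
    if (guard > 10000L) {
      iolray_stop("iolray_config_error", "infeasible AL truncation range")
    }
  }
  x
}

#' Generate a synthetic biometry cohort
#'
#' Patients are drawn until `n` eyes are produced; a `bilateral_fraction`
#' share of patients contribute both eyes, whose biometry shares a
#' patient-level random effect (the second eye's AL, ACD, LT and K are
#' tightly correlated with the first's). The result is a fully validated
#' [read_cohort_csv()]-compatible cohort.
#'
#' @param config a [cohort_config()]
#' @return a `biometry_cohort` data.frame of `config$n` eyes
#' @export
generate_biometry <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    rng <- config$al_mixture$range
    # patients until n eyes are covered (bilateral patients contribute two)
    bilateral <- runif(n) < config$bilateral_fraction
    eyes_per <- 1L + bilateral
    n_pat <- which(cumsum(eyes_per) >= n)[1]
    bilateral <- bilateral[seq_len(n_pat)]
    eyes_per <- eyes_per[seq_len(n_pat)]
    # patient-level draws (shared by fellow eyes)
    al_p <- draw_al(n_pat, config$al_mixture)
    k_eps <- rnorm(n_pat, 0, config$k_model$sd)
    acd_eps <- rnorm(n_pat, 0, config$acd_model$sd)
    lt_eps <- rnorm(n_pat, 0, config$lt_model$sd)
    first_od <- runif(n_pat) < 0.5
    # expand to eyes, trimming the final fellow eye when it overshoots n
    idx <- rep.int(seq_len(n_pat), eyes_per)[seq_len(n)]
    rank <- sequence(eyes_per)[seq_len(n)]
    second <- rank == 2L
    al <- al_p[idx]
    al[second] <- clamp(al[second] + rnorm(sum(second), 0, 0.12), rng[1], rng[2])
    k_mean <- config$k_model$mean + config$k_model$slope * (al - 23.66) +
      k_eps[idx] + second * rnorm(n, 0, 0.25)
    k_mean <- clamp(k_mean, 36, 52)
    cyl <- abs(rnorm(n, 0, config$k_model$cyl_sd))
    acd <- clamp(config$acd_model$intercept + config$acd_model$slope * al +
                   acd_eps[idx] + second * rnorm(n, 0, 0.08), 1.8, 5.4)
    lt <- clamp(config$lt_model$intercept + config$lt_model$slope * al +
                  lt_eps[idx] + second * rnorm(n, 0, 0.07), 3.0, 6.2)
    cohort <- data.frame(
      patient_id = sprintf("P%05d", idx),
      eye = ifelse((rank == 1L) == first_od[idx], "OD", "OS"),
      al = al, acd = acd, lt = lt,
      cct = clamp(rnorm(n, config$cct_dist$mean, config$cct_dist$sd), 450, 650),
      k1 = k_mean - cyl / 2, k2 = k_mean + cyl / 2,
      wtw = clamp(rnorm(n, config$wtw_dist$mean, config$wtw_dist$sd), 10, 13.5),
      pupil = clamp(rnorm(n, config$pupil_dist$mean, config$pupil_dist$sd), 1.5, 6),
      iol_model = NA_character_, iol_power = NA_real_,
      postop_se = NA_real_, stringsAsFactors = FALSE)
    validate_cohort(cohort)
    class(cohort) <- unique(c("biometry_cohort", class(cohort)))
    cohort
  })
}

#' Simulate surgery and the postoperative refraction
#'
#' For each eye: the implanted power is chosen by the study's AL-based
#' formula selection rule ([select_formula_by_al()]) at a 0.00 D target; the
#' true lens position is the ACD/LT-algorithm prediction perturbed by
#' `N(0, elp_noise_sd)`; the true refraction is computed by the ray tracer
#' at that position; and the recorded refraction adds
#' `N(0, refraction_noise_sd)` measurement noise, rounded to
#' `refraction_rounding` steps. The returned cohort carries the implanted
#' lens, the observed refraction, and truth-provenance columns
#' (`true_elp`, `true_se`, `formula_used`).
#'
#' @param cohort a [generate_biometry()] cohort
#' @param iol_db an `iol_database` providing geometry for
#'   `config$iol_model`
#' @param config the [cohort_config()] used to generate the cohort
#' @param rt_config a [raytrace_config()]
#' @return the completed `biometry_cohort`
#' @export
simulate_surgery <- function(cohort, iol_db, config,
                             rt_config = raytrace_config()) {
  iol <- iol_db[[config$iol_model]]
  if (is.null(iol)) {
    iolray_stop("iolray_capability_error",
                sprintf("IOL model %s not in the database", config$iol_model))
  }
  if (!has_raytrace_geometry(iol)) {
    iolray_stop("iolray_capability_error",
                sprintf("IOL model %s lacks geometry; the truth model needs ray tracing",
                        config$iol_model))
  }
  with_seed(config$seed + 1L, {
    n <- nrow(cohort)
    # noise = shared patient component + eye component, total variance fixed
    pid <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
    rho <- config$patient_noise_share
    mix_noise <- function(sd_total) {
      z_pat <- rnorm(nlevels(pid))[pid]
      z_eye <- rnorm(n)
      sd_total * (sqrt(rho) * z_pat + sqrt(1 - rho) * z_eye)
    }
    elp_noise <- mix_noise(config$elp_noise_sd)
    ref_noise <- mix_noise(config$refraction_noise_sd)
    rng <- range(iol$geometry$power)
    out <- cohort
    out$iol_model <- iol$model_id
    out$iol_power <- NA_real_
    out$postop_se <- NA_real_
    out$true_elp <- NA_real_
    out$true_se <- NA_real_
    out$formula_used <- NA_character_
    dm <- iol_geometry_at(iol, 21)$thickness
    for (i in seq_len(n)) {
      rec <- out[i, ]
      fid <- select_formula_by_al(rec$al)
      res <- calculate_formula(rec, iol, fid, target_d = 0)
      power <- min(max(res$chosen_power, rng[1]), rng[2])
      geometry <- iol_geometry_at(iol, power)
      elp <- predict_iol_position(rec, geometry, mode = "auto",
                                  am_mm = iol$am_mm, dm_mm = dm)
      true_elp <- elp$elp_center + elp_noise[i]
      eye <- build_pseudophakic_eye(rec, geometry,
                                    elp_prediction(true_elp, geometry$thickness,
                                                   "true"),
                                    rt_config)
      true_se <- best_focus_refraction(eye, rt_config)
      observed <- true_se + ref_noise[i]
      if (config$refraction_rounding > 0) {
        observed <- round(observed / config$refraction_rounding) *
          config$refraction_rounding
      }
      out$iol_power[i] <- power
      out$formula_used[i] <- fid
      out$true_elp[i] <- true_elp
      out$true_se[i] <- true_se
      out$postop_se[i] <- observed
    }
    out
  })
}

#' Predict the implanted-power refraction with every method
#'
#' Evaluates, for each eye's implanted power, the predicted spherical
#' equivalent of the four thin-lens formulas and of the ray-tracing method,
#' producing the long prediction table consumed by [prediction_errors()].
#'
#' @param cohort a completed cohort (with `iol_power` and `postop_se`)
#' @param iol_db an `iol_database`
#' @param methods methods to run (default all five)
#' @param rt_config a [raytrace_config()]
#' @return long data.frame: one row per eye and method
#' @export
predict_cohort <- function(cohort, iol_db,
                           methods = c("srkt", "hofferq", "holladay1",
                                       "haigis", "raytrace"),
                           rt_config = raytrace_config()) {
  rows <- vector("list", nrow(cohort) * length(methods))
  j <- 0L
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    iol <- iol_db[[rec$iol_model]]
    if (is.null(iol)) {
      iolray_stop("iolray_capability_error",
                  sprintf("IOL model %s not in the database", rec$iol_model))
    }
    for (m in methods) {
      se <- if (m == "raytrace") {
        raytrace_predicted_se(rec, iol, rec$iol_power, rt_config)
      } else {
        formula_predicted_se(rec, iol, rec$iol_power, m)
      }
      j <- j + 1L
      rows[[j]] <- data.frame(patient_id = rec$patient_id, eye = rec$eye,
                              formula_id = m, al = rec$al,
                              predicted_se = se, postop_se = rec$postop_se)
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic formula-accuracy study
#'
#' Generate, operate, predict with all five methods, and analyze: the result
#' bundles the cohort AL summary, the per-formula error table, mixed-model
#' pairwise contrasts of absolute error, Levene variance heterogeneity of
#' PE, GEE within-threshold comparisons at 0.25/0.50/1.00 D, and the
#' AL-subgroup report. Identical configurations give identical reports.
#'
#' @param config a [cohort_config()]
#' @param iol_db an `iol_database` (default [synthetic_iol_database()])
#' @param rt_config a [raytrace_config()]
#' @return list of class `iolray_report`
#' @export
run_study_pipeline <- function(config, iol_db = synthetic_iol_database(),
                               rt_config = raytrace_config()) {
  cohort <- generate_biometry(config)
  cohort <- simulate_surgery(cohort, iol_db, config, rt_config)
  predictions <- predict_cohort(cohort, iol_db, rt_config = rt_config)
  errors <- prediction_errors(predictions)
  al_bins <- table(assign_al_bin(cohort$al))
  report <- list(
    config = config,
    cohort_summary = list(
      n_eyes = nrow(cohort),
      n_patients = length(unique(cohort$patient_id)),
      al_mean = mean(cohort$al), al_sd = sd(cohort$al),
      al_median = median(cohort$al), al_range = range(cohort$al),
      al_bins = al_bins),
    errors = errors,
    error_summary = summarize_errors(errors),
    mixed_contrasts = compare_mae_mixed(errors),
    levene = levene_heterogeneity(errors$pe, errors$formula_id),
    gee = gee_threshold_comparison(errors),
    subgroups = subgroup_report(errors))
  class(report) <- "iolray_report"
  report
}

#' @export
print.iolray_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("<iolray_report> %d eyes / %d patients; AL %.2f +/- %.2f mm (%.1f-%.1f)\n",
              cs$n_eyes, cs$n_patients, cs$al_mean, cs$al_sd,
              cs$al_range[1], cs$al_range[2]))
  cat("\nPrediction error by formula:\n")
  print(x$error_summary, digits = 3)
  cat("\nPairwise AE contrasts (mixed model, Bonferroni):\n")
  print(x$mixed_contrasts, digits = 3)
  cat(sprintf("\nLevene heterogeneity of PE: F = %.3f, p = %.4g\n",
              x$levene$statistic, x$levene$p.value))
  invisible(x)
}
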