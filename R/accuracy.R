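## Prediction-error computation and the formula-comparison statistics:
## per-formula summaries, mixed-model pairwise contrasts with Bonferroni
## correction, Levene variance heterogeneity, GEE within-threshold rate
## comparisons, and axial-length subgroup reports.

.al_bin_levels <- c("<22", "22-24", "24-26", "26-30", ">30")

#' Refractive prediction error
#'
#' `pe = predicted - actual` (the formula's predicted spherical equivalent
#' minus the observed postoperative refraction); the absolute error is
#' `|pe|`. A positive PE therefore means the formula predicted more hyperopia
#' than observed.
#'
#' @param predicted_se predicted spherical equivalent, D
#' @param actual_se observed postoperative spherical equivalent, D
#' @return prediction error, D (vectorized)
#' @export
compute_pe <- function(predicted_se, actual_se) {
  if (any(!is.finite(predicted_se)) || any(!is.finite(actual_se))) {
    iolray_stop("iolray_domain_error", "prediction errors need finite inputs")
  }
  predicted_se - actual_se
}

#' Axial-length subgroup bin
#'
#' The five study bins: below 22 mm, then half-open intervals
#' \[22, 24), \[24, 26), \[26, 30), and 30 mm and above.
#'
#' @param al axial length, mm (vectorized)
#' @return factor with levels `<22, 22-24, 24-26, 26-30, >30`
#' @export
assign_al_bin <- function(al) {
  cut(al, breaks = c(-Inf, 22, 24, 26, 30, Inf), right = FALSE,
      labels = .al_bin_levels)
}

#' Assemble a prediction-error table
#'
#' @param predictions long data.frame with columns `patient_id`, `eye`,
#'   `formula_id`, `al`, `predicted_se`, `postop_se`
#' @return data.frame of class `prediction_errors` adding `pe`, `ae`, `al_bin`
#' @export
prediction_errors <- function(predictions) {
  need <- c("patient_id", "eye", "formula_id", "al", "predicted_se", "postop_se")
  missing_cols <- setdiff(need, names(predictions))
  if (length(missing_cols)) {
    iolray_stop("iolray_schema_error",
                paste0("missing prediction column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  out <- predictions
  out$pe <- compute_pe(out$predicted_se, out$postop_se)
  out$ae <- abs(out$pe)
  out$al_bin <- assign_al_bin(out$al)
  class(out) <- unique(c("prediction_errors", class(out)))
  out
}

#' Per-formula error summary
#'
#' For each formula: mean, SD (n-1 denominator), median and range of PE and
#' AE, plus the percentage of eyes with absolute error at or below 0.25,
#' 0.50 and 1.00 D (inclusive thresholds, reported to two decimals).
#'
#' @param errors a [prediction_errors()] table
#' @return data.frame, one row per formula
#' @export
summarize_errors <- function(errors) {
  if (nrow(errors) == 0) {
    iolray_stop("iolray_empty_group", "no prediction errors to summarize")
  }
  res <- lapply(split(errors, errors$formula_id, drop = TRUE), function(g) {
    if (nrow(g) == 0) {
      iolray_stop("iolray_empty_group", "empty formula group")
    }
    data.frame(
      formula_id = g$formula_id[1], n = nrow(g),
      mean_pe = mean(g$pe), sd_pe = sd(g$pe), median_pe = median(g$pe),
      min_pe = min(g$pe), max_pe = max(g$pe),
      mean_ae = mean(g$ae), sd_ae = sd(g$ae), median_ae = median(g$ae),
      min_ae = min(g$ae), max_ae = max(g$ae),
      pct_within_025 = round(100 * mean(g$ae <= 0.25), 2),
      pct_within_050 = round(100 * mean(g$ae <= 0.50), 2),
      pct_within_100 = round(100 * mean(g$ae <= 1.00), 2))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mixed-model pairwise comparison of absolute errors
#'
#' Absolute error is modelled with the formula as fixed effect and a
#' patient-level random intercept (both eyes of a bilateral patient share
#' it), fitted by REML with Satterthwaite degrees of freedom. All pairwise
#' formula contrasts are reported with Bonferroni-adjusted p-values
#' (`p_adj = min(1, p * m)`, m = number of pairwise contrasts) and
#' Bonferroni-adjusted 95% confidence intervals.
#'
#' @param errors a [prediction_errors()] table with at least two formulas,
#'   every eye evaluated by every formula
#' @param response which error column to compare (default `"ae"`)
#' @return data.frame of contrasts (estimate, SE, df, t, p_adj, lower, upper)
#' @export
compare_mae_mixed <- function(errors, response = "ae") {
  errors$formula_id <- factor(errors$formula_id)
  k <- nlevels(errors$formula_id)
  if (k < 2) {
    iolray_stop("iolray_contract_error",
                "at least two formulas are needed for pairwise comparison")
  }
  eye_id <- interaction(errors$patient_id, errors$eye, drop = TRUE)
  counts <- table(eye_id, errors$formula_id)
  if (any(counts != 1)) {
    iolray_stop("iolray_contract_error",
                "design must be fully crossed: every eye once per formula")
  }
  dat <- data.frame(y = errors[[response]],
                    formula_id = errors$formula_id,
                    patient_id = factor(errors$patient_id))
  m <- k * (k - 1) / 2
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ formula_id + (1 | patient_id), data = dat)))
  if (stats::sigma(fit) < 1e-8) {
    # degenerate: identical responses across formulas within eyes
    means <- tapply(dat$y, dat$formula_id, mean)
    combs <- utils::combn(names(means), 2)
    return(data.frame(
      contrast = paste(combs[1, ], "-", combs[2, ]),
      estimate = means[combs[1, ]] - means[combs[2, ]],
      se = 0, df = NA_real_, t = NA_real_,
      p_adj = 1, lower = means[combs[1, ]] - means[combs[2, ]],
      upper = means[combs[1, ]] - means[combs[2, ]], row.names = NULL))
  }
  emm <- emmeans::emmeans(fit, "formula_id", lmer.df = "satterthwaite")
  prs <- emmeans::contrast(emm, "pairwise", adjust = "bonferroni")
  tab <- as.data.frame(prs)
  ci <- as.data.frame(stats::confint(prs, level = 0.95, adjust = "bonferroni"))
  out <- data.frame(contrast = tab$contrast, estimate = tab$estimate,
                    se = tab$SE, df = tab$df, t = tab$t.ratio,
                    p_adj = pmin(1, tab$p.value),
                    lower = ci$lower.CL, upper = ci$upper.CL)
  out$p_adj[!is.finite(out$p_adj) & abs(out$estimate) < 1e-8] <- 1
  out
}

#' Levene test of variance heterogeneity
#'
#' The classic (mean-centred) Levene test: a one-way ANOVA on the absolute
#' deviations from each group's mean, `F` on `(k-1, N-k)` degrees of
#' freedom. Location shifts of individual groups leave the statistic
#' unchanged.
#'
#' @param values numeric vector (e.g. prediction errors)
#' @param groups grouping factor (e.g. formula), at least two groups of
#'   size two or more
#' @return an object of class `htest`
#' @export
levene_heterogeneity <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    iolray_stop("iolray_contract_error",
                "Levene's test needs >= 2 groups with >= 2 observations each")
  }
  dev <- abs(values - ave(values, groups))
  a <- anova(aov(dev ~ groups))
  structure(list(
    statistic = c(F = a$`F value`[1]),
    parameter = c(df1 = a$Df[1], df2 = a$Df[2]),
    p.value = a$`Pr(>F)`[1],
    method = "Levene's test for homogeneity of variance (mean-centred)",
    data.name = deparse(substitute(values))), class = "htest")
}

#' Axial-length subgroup report
#'
#' Splits the error table by AL bin and produces, per populated bin, the
#' per-formula summary, the mixed-model pairwise contrasts (when the bin has
#' enough patients to fit), and an across-bin PE variability profile (SD of
#' PE per bin and formula) describing how stable each formula is over the
#' axial-length range. Empty bins are absent from the report, not zero-filled.
#'
#' @param errors a [prediction_errors()] table
#' @param min_n minimum eyes per bin to attempt the mixed-model contrasts
#' @return list with `bins` (named list of summary + contrasts) and
#'   `variability` (data.frame bin x formula SD of PE)
#' @export
subgroup_report <- function(errors, min_n = 10) {
  errors$al_bin <- factor(errors$al_bin, levels = .al_bin_levels)
  bins <- split(errors, errors$al_bin, drop = TRUE)
  bins <- bins[vapply(bins, nrow, 0L) > 0]
  report <- lapply(bins, function(b) {
    contrasts <- NULL
    n_eyes <- length(unique(interaction(b$patient_id, b$eye, drop = TRUE)))
    if (n_eyes >= min_n) {
      contrasts <- tryCatch(compare_mae_mixed(b), error = function(e) NULL)
    }
    list(summary = summarize_errors(b), contrasts = contrasts, n_eyes = n_eyes)
  })
  prof <- aggregate(pe ~ al_bin + formula_id, data = errors,
                    FUN = sd, drop = TRUE)
  names(prof)[names(prof) == "pe"] <- "sd_pe"
  list(bins = report, variability = prof)
}
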