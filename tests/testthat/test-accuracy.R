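# build a long error table from per-formula PE vectors (one eye per patient
# unless patient ids are supplied)
make_errors <- function(pe_by_formula, patient_id = NULL, al = 23.5) {
  n <- length(pe_by_formula[[1]])
  if (is.null(patient_id)) patient_id <- sprintf("P%04d", seq_len(n))
  do.call(rbind, lapply(names(pe_by_formula), function(f) {
    data.frame(patient_id = patient_id, eye = "OD", formula_id = f,
               al = rep_len(al, n), predicted_se = pe_by_formula[[f]],
               postop_se = 0)
  })) |> prediction_errors()
}

test_that("prediction error is predicted minus actual", {
  expect_identical(compute_pe(0.50, 0.25), 0.25)
  expect_identical(compute_pe(0.25, 0.25), 0)
  expect_identical(compute_pe(-0.50, 0.50), -1.00)
  errs <- make_errors(list(f = c(-0.5)))
  expect_identical(errs$ae, 1 * abs(errs$pe))
  expect_error(compute_pe(NA, 1), class = "iolray_domain_error")
})

test_that("AL bins follow the half-open study convention", {
  expect_identical(as.character(assign_al_bin(21.9)), "<22")
  expect_identical(as.character(assign_al_bin(22.0)), "22-24")
  expect_identical(as.character(assign_al_bin(24.0)), "24-26")
  expect_identical(as.character(assign_al_bin(30.0)), ">30")
  expect_identical(as.character(assign_al_bin(35.0)), ">30")
  expect_identical(levels(assign_al_bin(23)),
                   c("<22", "22-24", "24-26", "26-30", ">30"))
})

test_that("the error summary reproduces hand arithmetic", {
  errs <- make_errors(list(f = c(-1.0, 0.5, 0.25)))
  s <- summarize_errors(errs)
  expect_equal(s$mean_pe, -0.25 / 3, tolerance = 1e-12)
  expect_equal(s$mean_ae, 1.75 / 3, tolerance = 1e-12)
  expect_equal(s$median_ae, 0.5)
  expect_equal(s$pct_within_050, 66.67)
  expect_equal(s$sd_pe, sd(c(-1, 0.5, 0.25)))
  expect_equal(s$min_pe, -1); expect_equal(s$max_pe, 0.5)
  # all-zero errors: perfect summary
  s0 <- summarize_errors(make_errors(list(f = rep(0, 5))))
  expect_equal(s0$mean_ae, 0)
  expect_equal(s0$pct_within_025, 100)
  # the Table-2 column set is complete
  expect_true(all(c("mean_pe", "sd_pe", "median_pe", "min_pe", "max_pe",
                    "mean_ae", "sd_ae", "median_ae", "min_ae", "max_ae",
                    "pct_within_025", "pct_within_050", "pct_within_100")
                  %in% names(s)))
  expect_error(summarize_errors(errs[0, ]), class = "iolray_empty_group")
})

test_that("within-threshold percentages are monotone and inclusive", {
  set.seed(3)
  errs <- make_errors(list(a = rnorm(60, 0, 0.8), b = rnorm(60, 0.2, 0.5)))
  s <- summarize_errors(errs)
  expect_true(all(s$pct_within_025 <= s$pct_within_050))
  expect_true(all(s$pct_within_050 <= s$pct_within_100))
  # inclusive at the boundary: ae exactly 0.25 counts
  s2 <- summarize_errors(make_errors(list(f = c(0.25, 0.25))))
  expect_equal(s2$pct_within_025, 100)
})

test_that("Levene matches hand arithmetic and is location invariant", {
  x <- c(1, 2, 3, 2, 4, 6)
  g <- rep(c("a", "b"), each = 3)
  lv <- levene_heterogeneity(x, g)
  expect_equal(unname(lv$statistic), 0.8, tolerance = 1e-12)
  expect_equal(unname(lv$parameter), c(1, 4))
  # shifting one group leaves the statistic unchanged
  lv2 <- levene_heterogeneity(x + c(0, 0, 0, 100, 100, 100), g)
  expect_equal(lv2$statistic, lv$statistic, tolerance = 1e-12)
  # identical groups: zero statistic, p = 1
  lv0 <- levene_heterogeneity(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(unname(lv0$statistic), 0)
  expect_equal(lv0$p.value, 1)
  expect_error(levene_heterogeneity(1:3, c("a", "a", "b")),
               class = "iolray_contract_error")
})

test_that("Levene agrees with the independent car implementation", {
  skip_if_not_installed("car")
  set.seed(11)
  x <- c(rnorm(20, 0, 1), rnorm(25, 0, 2), rnorm(15, 1, 1.5))
  g <- factor(rep(c("a", "b", "c"), c(20, 25, 15)))
  lv <- levene_heterogeneity(x, g)
  ref <- car::leveneTest(x, g, center = mean)
  expect_equal(unname(lv$statistic), ref$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("mixed-model contrasts reduce to the paired t-test", {
  set.seed(42)
  n <- 40
  base <- abs(rnorm(n, 0.6, 0.3))
  a <- base + rnorm(n, 0, 0.08)
  b <- base + 0.12 + rnorm(n, 0, 0.08)
  errs <- make_errors(list(a = a, b = b))
  cmp <- compare_mae_mixed(errs)
  tt <- t.test(abs(a), abs(b), paired = TRUE)
  expect_equal(nrow(cmp), 1)
  expect_equal(cmp$estimate, unname(tt$estimate), tolerance = 1e-6)
  expect_equal(cmp$p_adj, tt$p.value, tolerance = 1e-3)
  expect_equal(cmp$df, unname(tt$parameter), tolerance = 1e-3)
})

test_that("identical formulas give a zero contrast with p = 1", {
  set.seed(9)
  v <- abs(rnorm(25, 0.5, 0.2))
  errs <- make_errors(list(a = v, b = v))
  cmp <- compare_mae_mixed(errs)
  expect_equal(cmp$estimate, 0)
  expect_equal(cmp$p_adj, 1)
})

test_that("five formulas yield all ten Bonferroni-adjusted contrasts", {
  set.seed(15)
  n <- 30
  base <- abs(rnorm(n, 0.6, 0.25))
  errs <- make_errors(setNames(lapply(1:5, function(i) {
    base + rnorm(n, 0, 0.1) + 0.03 * i
  }), c("srkt", "hofferq", "holladay1", "haigis", "raytrace")))
  cmp <- compare_mae_mixed(errs)
  expect_equal(nrow(cmp), 10)
  expect_true(all(cmp$p_adj >= 0 & cmp$p_adj <= 1))
  expect_true(all(cmp$lower <= cmp$estimate & cmp$estimate <= cmp$upper))
})

test_that("non-crossed designs and single formulas are contract errors", {
  errs <- make_errors(list(a = rnorm(10), b = rnorm(10)))
  expect_error(compare_mae_mixed(errs[errs$formula_id == "a", ]),
               class = "iolray_contract_error")
  expect_error(compare_mae_mixed(errs[-1, ]), class = "iolray_contract_error")
})

test_that("Bonferroni adjustment is conservative under the null", {
  # permutation-style simulation: three exchangeable formulas, no true
  # differences; the family-wise rejection rate must stay near/below alpha
  set.seed(2024)
  n_rep <- 200
  n <- 24
  rejections <- 0
  for (r in seq_len(n_rep)) {
    base <- abs(rnorm(n, 0.6, 0.3))
    errs <- make_errors(list(a = base + rnorm(n, 0, 0.12),
                             b = base + rnorm(n, 0, 0.12),
                             c = base + rnorm(n, 0, 0.12)))
    cmp <- compare_mae_mixed(errs)
    if (any(cmp$p_adj < 0.05, na.rm = TRUE)) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("GEE reduces to the independence model for singleton clusters", {
  skip_if_not_installed("sandwich")
  set.seed(31)
  n <- 120
  a <- rnorm(n, 0.4, 0.45); b <- rnorm(n, 0.6, 0.45)
  # two independent groups: distinct patients per formula observation
  errs <- rbind(
    data.frame(patient_id = sprintf("A%04d", 1:n), eye = "OD",
               formula_id = "a", al = 23.5, predicted_se = a, postop_se = 0),
    data.frame(patient_id = sprintf("B%04d", 1:n), eye = "OD",
               formula_id = "b", al = 23.5, predicted_se = b, postop_se = 0))
  errs <- prediction_errors(errs)
  res <- gee_threshold_comparison(errs, thresholds = 0.5)[["0.50"]]
  # oracle: glm with HC0 cluster sandwich (one row per cluster)
  dat <- data.frame(y = as.numeric(errs$ae <= 0.5), f = factor(errs$formula_id),
                    id = errs$patient_id)
  fit <- glm(y ~ f - 1, family = binomial(), data = dat)
  expect_equal(res$proportions$proportion,
               unname(plogis(coef(fit))), tolerance = 1e-6)
  vc <- sandwich::vcovCL(fit, cluster = dat$id, type = "HC0", cadjust = FALSE)
  se_or <- sqrt(vc[1, 1] + vc[2, 2] - 2 * vc[1, 2])
  est_or <- unname(coef(fit)[1] - coef(fit)[2])
  expect_equal(res$contrasts$estimate, est_or, tolerance = 1e-6)
  expect_equal(res$contrasts$se, se_or, tolerance = 1e-4)
  z <- est_or / se_or
  expect_equal(res$contrasts$p, 2 * pnorm(-abs(z)), tolerance = 1e-3)
})

test_that("GEE handles identical columns, separation and fixed thresholds", {
  set.seed(8)
  v <- rnorm(40, 0.4, 0.3)
  errs <- make_errors(list(a = v, b = v))
  res <- gee_threshold_comparison(errs)
  expect_named(res, c("0.25", "0.50", "1.00"))
  expect_equal(res[["0.50"]]$contrasts$estimate, 0, tolerance = 1e-10)
  expect_equal(res[["0.50"]]$contrasts$p_adj, 1)
  # a formula entirely within threshold: proportions reported, contrast NA
  errs2 <- make_errors(list(a = rep(0.1, 40), b = v, c = v + 0.1))
  res2 <- gee_threshold_comparison(errs2, thresholds = 0.5)[["0.50"]]
  expect_equal(res2$proportions$proportion[res2$proportions$formula_id == "a"], 1)
  na_rows <- grepl("a", res2$contrasts$contrast, fixed = TRUE)
  expect_true(all(is.na(res2$contrasts$p_adj[na_rows])))
  expect_true(all(!is.na(res2$contrasts$p_adj[!na_rows])))
})

test_that("subgroup report covers populated bins and tracks PE variability", {
  # single-bin cohort: exactly one bin in the report
  errs1 <- make_errors(list(a = rnorm(20, 0, 0.3), b = rnorm(20, 0, 0.3)),
                       al = 23.0)
  rep1 <- subgroup_report(errs1)
  expect_named(rep1$bins, "22-24")
  # noise inflated beyond 26 mm: variability profile strictly larger there
  set.seed(5)
  al <- c(runif(40, 22.2, 25.8), runif(40, 26.2, 29.8))
  noise_sd <- ifelse(al > 26, 1.2, 0.3)
  errs2 <- make_errors(list(a = rnorm(80, 0, noise_sd),
                            b = rnorm(80, 0, noise_sd)), al = al)
  rep2 <- subgroup_report(errs2)
  v <- rep2$variability
  for (f in c("a", "b")) {
    expect_gt(v$sd_pe[v$formula_id == f & v$al_bin == "26-30"],
              v$sd_pe[v$formula_id == f & v$al_bin == "24-26"])
  }
  expect_true(all(as.character(v$al_bin) %in%
                    c("<22", "22-24", "24-26", "26-30", ">30")))
})

test_that("report figures build from an error table", {
  set.seed(2)
  errs <- make_errors(list(a = rnorm(30, 0, 0.5), b = rnorm(30, 0.2, 0.6)),
                      al = runif(30, 20, 30))
  expect_s3_class(plot_mae_by_formula(errs), "ggplot")
  expect_s3_class(plot_pe_by_al(errs), "ggplot")
  expect_s3_class(plot_within_thresholds(errs), "ggplot")
})
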