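## Generalized estimating equations for correlated binary outcomes
## (fellow eyes and repeated formulas within a patient): binomial family,
## logit link, exchangeable working correlation, moment estimators for the
## dispersion and correlation, and the robust (sandwich) covariance.

# Fit a logistic GEE with exchangeable working correlation.
# y: 0/1 outcome; x: model matrix; id: cluster factor.
gee_exchangeable_logit <- function(y, x, id, tol = 1e-10, max_iter = 50) {
  id <- factor(id)
  p <- ncol(x)
  beta <- coef(glm.fit2(x, y))
  idx <- split(seq_along(y), id)
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    mu <- plogis(drop(x %*% beta))
    v <- mu * (1 - mu)
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (length(y) - p)
    # moment estimator of the exchangeable correlation
    cross <- 0; npairs <- 0
    for (ii in idx) {
      m <- length(ii)
      if (m > 1) {
        s <- sum(e[ii])
        cross <- cross + (s^2 - sum(e[ii]^2)) / 2
        npairs <- npairs + m * (m - 1) / 2
      }
    }
    alpha <- if (npairs > p) cross / ((npairs - p) * phi) else 0
    m_max <- max(vapply(idx, length, 0L))
    alpha <- min(max(alpha, -1 / max(m_max - 1, 1) + 1e-6), 0.99)
    score <- numeric(p)
    info <- matrix(0, p, p)
    for (ii in idx) {
      m <- length(ii)
      xi <- x[ii, , drop = FALSE]
      di <- xi * v[ii]                       # d mu / d beta
      ai_inv <- 1 / sqrt(v[ii])
      # R^-1 for exchangeable: (I - a/(1+(m-1)a) J) / (1-a)
      ri <- y[ii] - mu[ii]
      if (m == 1) {
        vinv_r <- ai_inv * ai_inv * ri / phi
        vinv_d <- (ai_inv * ai_inv / phi) * di
      } else {
        f1 <- 1 / (1 - alpha)
        f2 <- alpha / ((1 - alpha) * (1 + (m - 1) * alpha))
        zr <- ai_inv * ri
        vinv_r <- ai_inv * (f1 * zr - f2 * sum(zr)) / phi
        zd <- di * ai_inv
        vinv_d <- ai_inv * (f1 * zd - f2 * matrix(colSums(zd), m, p, byrow = TRUE)) / phi
      }
      score <- score + drop(crossprod(di, vinv_r))
      info <- info + crossprod(di, vinv_d)
    }
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  # sandwich covariance
  mu <- plogis(drop(x %*% beta))
  v <- mu * (1 - mu)
  meat <- matrix(0, p, p)
  bread <- matrix(0, p, p)
  for (ii in idx) {
    m <- length(ii)
    xi <- x[ii, , drop = FALSE]
    di <- xi * v[ii]
    ai_inv <- 1 / sqrt(v[ii])
    ri <- y[ii] - mu[ii]
    if (m == 1) {
      vinv_r <- ai_inv * ai_inv * ri
      vinv_d <- (ai_inv * ai_inv) * di
    } else {
      f1 <- 1 / (1 - alpha)
      f2 <- alpha / ((1 - alpha) * (1 + (m - 1) * alpha))
      zr <- ai_inv * ri
      vinv_r <- ai_inv * (f1 * zr - f2 * sum(zr))
      zd <- di * ai_inv
      vinv_d <- ai_inv * (f1 * zd - f2 * matrix(colSums(zd), m, p, byrow = TRUE))
    }
    g <- drop(crossprod(di, vinv_r))
    meat <- meat + tcrossprod(g)
    bread <- bread + crossprod(di, vinv_d)
  }
  bread_inv <- solve(bread)
  vcov_robust <- bread_inv %*% meat %*% bread_inv
  list(coefficients = drop(beta), vcov = vcov_robust, alpha = alpha,
       phi = phi, fitted = mu)
}

# minimal IRLS logistic start (avoids a formula interface for speed)
glm.fit2 <- function(x, y) {
  fit <- glm.fit(x, y, family = binomial())
  list(coefficients = fit$coefficients)
}

#' GEE comparison of within-threshold rates
#'
#' For each threshold `t`, the indicator `ae <= t` is modelled on the
#' formula factor with a logit link and an exchangeable working correlation
#' clustered on patient (all eyes and formulas of a patient share a
#' cluster); robust sandwich standard errors give Wald pairwise contrasts
#' with Bonferroni adjustment. Per-formula raw proportions are always
#' reported; when a formula is completely separated (all eyes inside or all
#' outside the threshold) its contrasts are flagged undefined (`NA`).
#'
#' @param errors a [prediction_errors()] table
#' @param thresholds absolute-error thresholds, D (default 0.25, 0.5, 1.0)
#' @return named list (one element per threshold) with `proportions` and
#'   `contrasts` data.frames and the estimated working correlation `alpha`
#' @export
gee_threshold_comparison <- function(errors, thresholds = c(0.25, 0.5, 1.0)) {
  errors$formula_id <- factor(errors$formula_id)
  k <- nlevels(errors$formula_id)
  if (k < 2) {
    iolray_stop("iolray_contract_error", "need at least two formulas")
  }
  out <- lapply(thresholds, function(t) {
    y <- as.numeric(errors$ae <= t)
    f <- errors$formula_id
    props <- data.frame(
      formula_id = levels(f),
      n = as.vector(table(f)),
      proportion = as.vector(tapply(y, f, mean)))
    separated <- levels(f)[props$proportion %in% c(0, 1)]
    usable <- setdiff(levels(f), separated)
    combs <- utils::combn(levels(f), 2)
    m <- ncol(combs)
    contrasts <- data.frame(contrast = paste(combs[1, ], "-", combs[2, ]),
                            estimate = NA_real_, se = NA_real_,
                            z = NA_real_, p = NA_real_, p_adj = NA_real_)
    alpha <- NA_real_
    if (length(usable) >= 2) {
      keep <- f %in% usable
      fk <- droplevels(f[keep])
      x <- model.matrix(~ fk - 1)        # one column per formula: cell means
      fit <- gee_exchangeable_logit(y[keep], x, errors$patient_id[keep])
      alpha <- fit$alpha
      names(fit$coefficients) <- levels(fk)
      for (j in seq_len(m)) {
        a <- combs[1, j]; b <- combs[2, j]
        if (a %in% usable && b %in% usable) {
          ia <- match(a, levels(fk)); ib <- match(b, levels(fk))
          est <- fit$coefficients[ia] - fit$coefficients[ib]
          se <- sqrt(max(fit$vcov[ia, ia] + fit$vcov[ib, ib] -
                           2 * fit$vcov[ia, ib], 0))
          z <- if (se > 0) est / se else NA_real_
          contrasts$estimate[j] <- est
          contrasts$se[j] <- se
          contrasts$z[j] <- z
          contrasts$p[j] <- 2 * pnorm(-abs(z))
          contrasts$p_adj[j] <- min(1, contrasts$p[j] * m)
        }
      }
      # identical columns give exact zero contrasts: p = 1 by convention
      zero <- !is.na(contrasts$estimate) & abs(contrasts$estimate) < 1e-12
      contrasts$p[zero] <- 1
      contrasts$p_adj[zero] <- 1
    }
    list(threshold = t, proportions = props, contrasts = contrasts,
         alpha = alpha, separated = separated)
  })
  names(out) <- sprintf("%.2f", thresholds)
  out
}
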