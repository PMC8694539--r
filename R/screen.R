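## Per-feature linear mixed-model screen: material fixed effect (water vs
## barium), participant random intercept, Wald test at alpha = 0.05 with no
## multiplicity correction (each feature is reported at its raw p-value).

#' Fit the material mixed model for one feature
#'
#' REML fit of `y ~ material + (1 | participant)` with materials coded so
#' the fixed-effect estimate is the water-minus-barium mean difference. The
#' p-value is a two-sided Wald test of the material effect against a normal
#' reference. If the REML optimizer fails, a grid profile over the
#' variance-ratio (random-intercept vs residual) with closed-form GLS at
#' each grid point is used as a fallback; if that also fails the feature is
#' reported unscreened (`converged = FALSE`, `p_value = NA`).
#'
#' @param values Numeric response (one feature).
#' @param material Factor/character with levels barium and water.
#' @param participant Participant identifiers.
#' @param alpha Significance level.
#' @return List with `beta1_hat`, `std_error`, `p_value`, `rejected`,
#'   `n_used`, `converged`.
#' @export
fit_material_mixed_model <- function(values, material, participant,
                                     alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  keep <- is.finite(values)
  values <- values[keep]
  material <- factor(as.character(material)[keep], levels = c("barium", "water"))
  participant <- factor(as.character(participant)[keep])
  if (any(is.na(material))) stopf("material labels must be barium or water")
  if (nlevels(droplevels(material)) < 2L) {
    stopf("both materials must be present")
  }
  if (nlevels(participant) < 2L) stopf("need at least 2 participants")

  res <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(values ~ material + (1 | participant), REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    ))
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    list(beta1 = unname(cf["materialwater"]),
         se = unname(se[2L]), converged = TRUE)
  }, error = function(e) NULL)

  if (is.null(res)) {
    res <- tryCatch(profile_gls_fallback(values, material, participant),
                    error = function(e) NULL)
  }
  if (is.null(res)) {
    return(list(beta1_hat = NA_real_, std_error = NA_real_,
                p_value = NA_real_, rejected = NA, n_used = length(values),
                converged = FALSE))
  }
  z <- res$beta1 / res$se
  p <- 2 * pnorm(-abs(z))
  list(beta1_hat = res$beta1, std_error = res$se, p_value = p,
       rejected = p < alpha, n_used = length(values),
       converged = res$converged)
}

## Fallback estimator: profile the REML criterion over the variance ratio
## r = sigma_u^2 / sigma^2 on a fixed grid, with closed-form per-participant
## GLS (Woodbury inverse of I + r * J) at each grid point.
profile_gls_fallback <- function(values, material, participant) {
  X <- cbind(1, as.numeric(material == "water"))
  groups <- split(seq_along(values), participant)
  best <- NULL
  best_crit <- Inf
  for (r in c(0, 10^seq(-3, 2, length.out = 40))) {
    XtVX <- matrix(0, 2, 2)
    XtVy <- numeric(2)
    logdet <- 0
    for (g in groups) {
      ni <- length(g)
      Xi <- X[g, , drop = FALSE]
      yi <- values[g]
      w <- r / (1 + ni * r)
      ## Vi^{-1} = I - w * J  (up to the common residual variance)
      XtVX <- XtVX + crossprod(Xi) - w * tcrossprod(colSums(Xi))
      XtVy <- XtVy + crossprod(Xi, yi) - w * colSums(Xi) * sum(yi)
      logdet <- logdet + log1p(ni * r)
    }
    beta <- solve(XtVX, XtVy)
    rss <- 0
    for (g in groups) {
      ri <- values[g] - X[g, , drop = FALSE] %*% beta
      w <- r / (1 + length(g) * r)
      rss <- rss + sum(ri^2) - w * sum(ri)^2
    }
    n <- length(values)
    s2 <- rss / (n - 2)
    crit <- (n - 2) * log(s2) + logdet + log(det(XtVX))
    if (is.finite(crit) && crit < best_crit) {
      best_crit <- crit
      best <- list(beta1 = beta[2], se = sqrt(s2 * solve(XtVX)[2, 2]),
                   converged = TRUE)
    }
  }
  best
}

#' Screen all features of a cohort table
#'
#' Fits the material mixed model to every feature column, reporting the
#' estimate, Wald standard error, raw p-value and the rejection flag at
#' `alpha`. Rows with a missing value are dropped per feature (not
#' listwise); features that cannot be fit are counted as unscreened.
#'
#' @param table Feature table (as from [generate_feature_table()] or
#'   [extract_feature_table()]).
#' @param alpha Significance level (default 0.05; no multiple-testing
#'   correction is applied).
#' @return An object of class `hrca_screen`: list with `per_feature` data
#'   frame, `n_rejected`, `n_total`, `alpha`.
#' @export
run_feature_screen <- function(table, alpha = 0.05) {
  if (is.null(table) || nrow(table) == 0L) stopf("empty feature table")
  feat_cols <- setdiff(names(table), KEY_COLUMNS)
  if (length(feat_cols) == 0L) stopf("no feature columns in table")
  rows <- lapply(feat_cols, function(fc) {
    r <- tryCatch(
      fit_material_mixed_model(table[[fc]], table$material,
                               table$participant_id, alpha),
      error = function(e) list(beta1_hat = NA_real_, std_error = NA_real_,
                               p_value = NA_real_, rejected = NA,
                               n_used = 0L, converged = FALSE)
    )
    data.frame(feature = fc, beta1_hat = r$beta1_hat,
               std_error = r$std_error, p_value = r$p_value,
               rejected = isTRUE(r$rejected), n_used = r$n_used,
               converged = r$converged, stringsAsFactors = FALSE)
  })
  per_feature <- do.call(rbind, rows)
  rownames(per_feature) <- NULL
  screened <- per_feature$converged & !is.na(per_feature$p_value)
  structure(
    list(per_feature = per_feature,
         n_rejected = sum(per_feature$rejected[screened]),
         n_total = sum(screened),
         alpha = alpha),
    class = "hrca_screen"
  )
}

#' @export
print.hrca_screen <- function(x, ...) {
  cat(sprintf("<hrca_screen> %d of %d features rejected at alpha = %g\n",
              x$n_rejected, x$n_total, x$alpha))
  rej <- x$per_feature[x$per_feature$rejected %in% TRUE, c("feature", "beta1_hat", "p_value")]
  if (nrow(rej) > 0) {
    print(rej, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
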