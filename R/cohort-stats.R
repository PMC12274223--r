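# Group-comparison statistics: multicollinearity, normality and
# heteroscedasticity checks, overdispersion assessment, assumption-driven
# model-family assignment, GLM fits with group/sex/age predictors,
# Benjamini-Hochberg correction, and the stuttering-frequency (%SS)
# correlation battery.

default_predictors <- function(table)
  intersect(c("group", "sex", "age"), names(table))

# Coded design matrix (no intercept column) with AWNS/female reference levels.
predictor_matrix <- function(table, predictors) {
  df <- table[predictors]
  if ("group" %in% predictors)
    df$group <- factor(df$group, levels = c("AWNS", "AWS"))
  if ("sex" %in% predictors)
    df$sex <- factor(df$sex, levels = c("female", "male"))
  mm <- model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Variance inflation factors for the cohort predictors
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` by regressing each (coded) predictor
#' column on the others. Perfect collinearity is reported as an infinite
#' VIF with the flag raised, not as an error. VIFs of 10 or more are
#' flagged as severe.
#'
#' @param table A cohort table.
#' @param predictors Predictor column names (default group, sex, age).
#' @param threshold Severity threshold (default 10).
#' @return Data frame `predictor`, `vif`, `severe`.
#' @export
check_multicollinearity <- function(table, predictors = default_predictors(table),
                                    threshold = 10) {
  mm <- predictor_matrix(stats::na.omit(table[predictors]), predictors)
  if (nrow(mm) < ncol(mm) + 2) stopf("too few complete rows for VIF")
  vifs <- vapply(seq_len(ncol(mm)), function(j) {
    if (ncol(mm) == 1) return(1)
    # a perfect auxiliary fit is the expected collinear case, not a fault
    fit <- suppressWarnings(lm(mm[, j] ~ mm[, -j, drop = FALSE]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(predictor = colnames(mm), vif = vifs,
             severe = vifs >= threshold, row.names = NULL)
}

#' Normality assessment with log-transform recommendations
#'
#' Shapiro-Wilk per metric; when normality is rejected at `alpha` and all
#' values are strictly positive, a log transform is recommended and the
#' test is repeated on the log scale so both p-values can be compared.
#' Constant or too-short columns are reported as missing.
#'
#' @param table A cohort table.
#' @param metrics Metric columns to assess (default all 13).
#' @param alpha Rejection level (default .05).
#' @return Data frame `metric`, `shapiro_p`, `log_recommended`,
#'   `shapiro_p_log`, `log_improved`.
#' @export
assess_distributions <- function(table, metrics = metric_names(), alpha = 0.05) {
  rows <- lapply(metrics, function(nm) {
    x <- table[[nm]]
    x <- x[!is.na(x)]
    p <- if (length(x) >= 3 && length(unique(x)) > 1) shapiro.test(x)$p.value
         else NA_real_
    rec <- isTRUE(p < alpha) && all(x > 0)
    p_log <- if (rec) shapiro.test(log(x))$p.value else NA_real_
    if (isTRUE(p < alpha) && !all(x > 0))
      warning(sprintf("log transform withheld for %s: nonpositive values", nm),
              call. = FALSE)
    data.frame(metric = nm, shapiro_p = p, log_recommended = rec,
               shapiro_p_log = p_log,
               log_improved = if (rec) p_log > p else NA)
  })
  do.call(rbind, rows)
}

#' Breusch-Pagan heteroscedasticity check for one metric
#'
#' Fits the ordinary least-squares model `metric ~ predictors` and applies
#' the studentized Breusch-Pagan (Koenker) test: the LM statistic
#' `n * R^2` of the auxiliary regression of squared residuals on the
#' predictors, referred to a chi-square with as many degrees of freedom as
#' coded predictors. A p-value below `alpha` raises the weighted-regression
#' flag.
#'
#' @param table A cohort table.
#' @param metric Metric column name.
#' @param predictors Predictor columns.
#' @param alpha Flag level (default .05).
#' @return List `p`, `statistic`, `weighted` (flag); `p` is `NA` for
#'   degenerate fits.
#' @export
check_heteroscedasticity <- function(table, metric,
                                     predictors = default_predictors(table),
                                     alpha = 0.05) {
  df <- stats::na.omit(table[c(metric, predictors)])
  if (nrow(df) < length(predictors) + 3 || length(unique(df[[metric]])) < 2)
    return(list(p = NA_real_, statistic = NA_real_, weighted = FALSE))
  df$group <- if ("group" %in% predictors) factor(df$group, c("AWNS", "AWS")) else NULL
  f <- stats::reformulate(predictors, response = metric)
  fit <- lm(f, data = df)
  bp <- tryCatch(lmtest::bptest(fit), error = function(e) NULL)
  if (is.null(bp) || is.na(bp$p.value))
    return(list(p = NA_real_, statistic = NA_real_, weighted = FALSE))
  list(p = unname(bp$p.value), statistic = unname(bp$statistic),
       weighted = unname(bp$p.value) < alpha)
}

#' Overdispersion assessment for a count metric
#'
#' Fits a Poisson GLM of the count on the predictors, computes the Pearson
#' dispersion (Pearson chi-square over residual degrees of freedom), and
#' runs the auxiliary Cameron-Trivedi regression
#' `((y - mu)^2 - y) / mu ~ mu` (no intercept, one-sided test). The
#' negative-binomial flag is raised when dispersion exceeds 1 and the
#' auxiliary p-value is below `alpha`.
#'
#' @param table A cohort table.
#' @param count_metric Name of a nonnegative-integer metric column.
#' @param predictors Predictor columns.
#' @param alpha Flag level (default .05).
#' @return List `dispersion`, `p`, `overdispersed`.
#' @export
check_overdispersion <- function(table, count_metric,
                                 predictors = default_predictors(table),
                                 alpha = 0.05) {
  df <- stats::na.omit(table[c(count_metric, predictors)])
  y <- df[[count_metric]]
  if (!is_count_vector(y)) stopf("%s is not a count metric", count_metric)
  if (all(y == 0) || length(unique(y)) < 2)
    return(list(dispersion = NA_real_, p = NA_real_, overdispersed = FALSE))
  f <- stats::reformulate(predictors, response = count_metric)
  fit <- glm(f, data = df, family = stats::poisson())
  mu <- fitted(fit)
  disp <- sum(stats::residuals(fit, "pearson")^2) / fit$df.residual
  z <- ((y - mu)^2 - y) / mu
  aux <- lm(z ~ mu - 1)
  tval <- coef(summary(aux))[1, "t value"]
  p <- pt(tval, df = aux$df.residual, lower.tail = FALSE)  # one-sided
  list(dispersion = disp, p = unname(p),
       overdispersed = disp > 1 && !is.na(p) && p < alpha)
}

#' Run every assumption check over a cohort table
#'
#' Convenience wrapper producing the diagnostics that feed
#' [build_model_plan()]: normality (with log recommendations),
#' heteroscedasticity per metric, and overdispersion for the count metrics.
#'
#' @param table A cohort table.
#' @param metrics Metric columns (default all 13).
#' @param predictors Predictor columns.
#' @return Data frame with one row per metric: `metric`, `is_count`,
#'   `shapiro_p`, `log_recommended`, `log_improved`, `bp_p`, `weighted`,
#'   `dispersion`, `overdispersed`, `all_positive`.
#' @export
assess_cohort <- function(table, metrics = metric_names(),
                          predictors = default_predictors(table)) {
  dist <- assess_distributions(table, metrics)
  rows <- lapply(metrics, function(nm) {
    x <- table[[nm]]
    is_count <- is_count_vector(x)
    het <- check_heteroscedasticity(table, nm, predictors)
    od <- if (is_count) check_overdispersion(table, nm, predictors)
          else list(dispersion = NA_real_, p = NA_real_, overdispersed = FALSE)
    d <- dist[dist$metric == nm, ]
    data.frame(metric = nm, is_count = is_count,
               shapiro_p = d$shapiro_p,
               log_recommended = d$log_recommended,
               log_improved = isTRUE(d$log_improved),
               bp_p = het$p, weighted = isTRUE(het$weighted),
               dispersion = od$dispersion,
               overdispersed = isTRUE(od$overdispersed),
               all_positive = all(x > 0, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Assign a model family to each metric from the assumption checks
#'
#' Encodes the family-selection procedure: count metrics with
#' overdispersion get a negative binomial (log link); continuous metrics
#' whose normality is not repaired by a log transform and that show
#' heteroscedasticity get a weighted gamma GLM (log link, requires positive
#' values); heteroscedastic but otherwise well-behaved metrics get a
#' weighted Gaussian GLM; metrics whose normality a log transform does
#' repair are modeled as Gaussian on the log scale; everything else is a
#' plain Gaussian GLM. A gamma assignment with nonpositive values falls
#' back to Gaussian with a warning.
#'
#' @param assessments Output of [assess_cohort()].
#' @return A `model_plan` data frame: `metric`, `family`, `weighted`,
#'   `log_transform`, `link`, `model_label`.
#' @export
build_model_plan <- function(assessments) {
  rows <- lapply(seq_len(nrow(assessments)), function(i) {
    a <- assessments[i, ]
    fam <- "gaussian"; weighted <- FALSE; logt <- FALSE; link <- "identity"
    if (a$is_count && a$overdispersed) {
      fam <- "negative_binomial"; link <- "log"
    } else if (!a$is_count) {
      log_fixes <- a$log_recommended && isTRUE(a$log_improved)
      if (a$weighted && a$log_recommended && !log_fixes) {
        if (a$all_positive) { fam <- "gamma"; link <- "log"; weighted <- TRUE }
        else {
          warning("gamma family needs positive values; falling back to gaussian",
                  call. = FALSE)
          weighted <- TRUE
        }
      } else if (a$weighted) {
        weighted <- TRUE
      } else if (log_fixes) {
        logt <- TRUE
      }
    }
    label <- if (fam == "negative_binomial") "Negative binomial"
      else if (fam == "gamma") "Weighted gamma GLM"
      else if (weighted) "Weighted GLM Gaussian"
      else "GLM Gaussian"
    data.frame(metric = a$metric, family = fam, weighted = weighted,
               log_transform = logt, link = link, model_label = label)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_plan", "data.frame")
  out
}

# Two-stage heteroscedasticity weights: inverse fitted variance from an
# auxiliary log-linear regression of squared OLS residuals on the predictors.
aux_weights <- function(df, formula) {
  ols <- lm(formula, data = df)
  adf <- df
  adf$.log_sq_resid <- log(pmax(resid(ols)^2, 1e-12))
  aux <- lm(stats::update(formula, .log_sq_resid ~ .), data = adf)
  1 / exp(fitted(aux))
}

#' Fit the planned group-comparison model for every metric
#'
#' For each metric, fits a GLM of the metric on group, sex and age (AWNS
#' and female are the reference levels) with the family, link, weighting
#' and log transform the plan assigns. Weighted fits use inverse
#' fitted-variance weights from an auxiliary log-linear regression of
#' squared OLS residuals on the predictors (one refit, no iteration).
#' Negative-binomial fits report the dispersion `alpha` (the NB2
#' parameterization, variance `mu + alpha * mu^2`). Rows with missing
#' metric values are dropped listwise per metric. Coefficient tests use
#' `z = B / SE` with a normal reference (t with residual df for unweighted
#' Gaussian fits).
#'
#' @param table A cohort table.
#' @param plan A `model_plan` from [build_model_plan()].
#' @param predictors Predictor columns (default group, sex, age).
#' @return Data frame with one row per metric and term: `metric`, `model`,
#'   `predictor`, `B`, `SE`, `z`, `p`, plus `Dispersion (alpha)` rows for
#'   negative-binomial fits. Metrics whose fit fails to converge are
#'   recorded with `NA` coefficients, not dropped.
#' @export
fit_group_models <- function(table, plan,
                             predictors = default_predictors(table)) {
  validate_cohort(table)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    nm <- plan$metric[i]
    df <- stats::na.omit(table[c(nm, predictors)])
    df$group <- factor(df$group, levels = c("AWNS", "AWS"))
    if ("sex" %in% predictors)
      df$sex <- factor(df$sex, levels = c("female", "male"))
    y <- df[[nm]]
    if (plan$log_transform[i]) {
      if (any(y <= 0)) {
        warning(sprintf("log transform withheld for %s: nonpositive values", nm),
                call. = FALSE)
      } else df[[nm]] <- log(y)
    }
    f <- stats::reformulate(predictors, response = nm)
    # glm.nb emits iteration warnings near the Poisson limit; absorb them
    res <- tryCatch(suppressWarnings({
      if (plan$family[i] == "negative_binomial") {
        fit <- MASS::glm.nb(f, data = df)
        theta <- fit$theta
        list(cf = coef(summary(fit)), alpha = 1 / theta,
             alpha_se = fit$SE.theta / theta^2,  # delta method
             df_resid = fit$df.residual, use_t = FALSE)
      } else if (plan$family[i] == "gamma") {
        w <- if (plan$weighted[i]) aux_weights(df, f) else NULL
        fit <- glm(f, data = df, family = Gamma(link = "log"), weights = w)
        list(cf = coef(summary(fit)), alpha = NULL, df_resid = fit$df.residual,
             use_t = FALSE)
      } else {
        w <- if (plan$weighted[i]) aux_weights(df, f) else NULL
        fit <- glm(f, data = df, family = gaussian(), weights = w)
        list(cf = coef(summary(fit)), alpha = NULL, df_resid = fit$df.residual,
             use_t = !plan$weighted[i])
      }
    }), error = function(e) e)
    term_names <- c("(Intercept)", paste0(predictors, c("AWS", "male", "")[
      match(predictors, c("group", "sex", "age"))]))
    pretty <- c("Intercept", c(group = "Group", sex = "Sex",
                               age = "Age")[predictors])
    if (inherits(res, "condition")) {
      rows[[length(rows) + 1]] <- data.frame(
        metric = nm, model = plan$model_label[i], predictor = pretty,
        B = NA_real_, SE = NA_real_, z = NA_real_, p = NA_real_,
        note = conditionMessage(res))
      next
    }
    cf <- res$cf
    idx <- match(term_names, rownames(cf))
    B <- cf[idx, 1]; SE <- cf[idx, 2]
    z <- B / SE
    p <- if (isTRUE(res$use_t)) 2 * pt(-abs(z), df = res$df_resid)
         else 2 * pnorm(-abs(z))
    block <- data.frame(metric = nm, model = plan$model_label[i],
                        predictor = pretty, B = unname(B), SE = unname(SE),
                        z = unname(z), p = unname(p), note = "")
    if (!is.null(res$alpha)) {
      block <- rbind(block, data.frame(
        metric = nm, model = plan$model_label[i],
        predictor = "Dispersion (alpha)", B = res$alpha, SE = res$alpha_se,
        z = res$alpha / res$alpha_se,
        p = 2 * pnorm(-abs(res$alpha / res$alpha_se)), note = ""))
    }
    rows[[length(rows) + 1]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up procedure at rate `q`: sort the p-values ascending,
#' find the largest `i` with `p_(i) <= i * q / m`, and reject hypotheses
#' 1..i. Adjusted p-values are the usual monotone step-up values (capped at
#' 1), so `significant` is equivalent to `p_adjusted <= q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Designated FDR (default .1).
#' @return Data frame `p`, `p_adjusted`, `significant` in input order;
#'   empty input gives an empty frame.
#' @export
adjust_fdr <- function(p_values, q = 0.1) {
  if (length(p_values) == 0)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adjusted = adj,
             significant = !is.na(adj) & adj <= q)
}

#' Correlate each metric with stuttering frequency (%SS)
#'
#' Pearson correlation (two-sided) of every metric against percent
#' syllables stuttered over the rows where `%SS` is defined. Because it is
#' unstated whether the non-stuttering group enters at `%SS = 0`, both
#' variants are available: `subset = "ss_defined"` (default; rows with a
#' recorded `%SS`) or `"all_zero_fill"` (missing `%SS` treated as 0).
#'
#' @param table A cohort table with a `percent_ss` column.
#' @param metrics Metric columns (default all 13).
#' @param subset One of `"ss_defined"`, `"all_zero_fill"`.
#' @return Data frame `metric`, `r`, `p`, `n`; constant columns give
#'   `NA` correlations.
#' @export
correlate_with_ss <- function(table, metrics = metric_names(),
                              subset = c("ss_defined", "all_zero_fill")) {
  subset <- match.arg(subset)
  ss <- table$percent_ss
  if (subset == "all_zero_fill") ss[is.na(ss)] <- 0
  rows <- lapply(metrics, function(nm) {
    x <- table[[nm]]
    ok <- !is.na(x) & !is.na(ss)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 || length(unique(ss[ok])) < 2)
      return(data.frame(metric = nm, r = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- cor.test(x[ok], ss[ok], method = "pearson")
    data.frame(metric = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, rows)
}
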