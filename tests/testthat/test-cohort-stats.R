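# Assumption checks, model-family assignment, GLM fits, FDR, correlations.

paper_narrative_assessments <- function() {
  base <- data.frame(metric = metric_names(), is_count = FALSE,
                     shapiro_p = 0.5, log_recommended = FALSE,
                     log_improved = FALSE, bp_p = 0.5, weighted = FALSE,
                     dispersion = NA_real_, overdispersed = FALSE,
                     all_positive = TRUE)
  set <- function(d, m, ...) { v <- list(...); for (nm in names(v)) d[d$metric == m, nm] <- v[[nm]]; d }
  base <- set(base, "speech_rate_wpm", weighted = TRUE)
  base <- set(base, "total_pause_time_s", weighted = TRUE,
              log_recommended = TRUE, log_improved = FALSE, shapiro_p = 0.01)
  base <- set(base, "long_pause_cv", weighted = TRUE,
              log_recommended = TRUE, log_improved = FALSE, shapiro_p = 0.01)
  base <- set(base, "mean_pause_ms", log_recommended = TRUE,
              log_improved = TRUE, shapiro_p = 0.01)
  for (m in c("pause_count", "long_pause_count", "short_pause_count"))
    base <- set(base, m, is_count = TRUE, overdispersed = TRUE, dispersion = 5)
  base
}

test_that("VIF is 1 for orthogonal predictors and infinite under duplication", {
  tb <- data.frame(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  v <- check_multicollinearity(tb, c("a", "b"))
  expect_equal(v$vif, c(1, 1))
  expect_false(any(v$severe))

  tb$c <- tb$a
  v2 <- check_multicollinearity(tb, c("a", "c"))
  expect_true(all(is.infinite(v2$vif)))
  expect_true(all(v2$severe))
})

test_that("VIF equals 1/(1 - R^2) for a constructed R^2 of 0.75", {
  n <- 16
  u <- scale(seq_len(n))[, 1]; u <- u / sqrt(sum(u^2))
  raw <- sin(seq_len(n)); raw <- raw - mean(raw)
  v <- raw - sum(raw * u) * u; v <- v / sqrt(sum(v^2))
  tb <- data.frame(x1 = u, x2 = sqrt(0.75) * u + sqrt(0.25) * v)
  out <- check_multicollinearity(tb, c("x1", "x2"))
  expect_equal(out$vif, c(4, 4), tolerance = 1e-8)
})

test_that("definitional VIF agrees with the model-based reference", {
  withr::with_seed(21, {
    tb <- data.frame(x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
    tb$x2 <- 0.6 * tb$x1 + 0.8 * tb$x2
    tb$y <- rnorm(40)
    ours <- check_multicollinearity(tb, c("x1", "x2", "x3"))$vif
    ref <- unname(car::vif(lm(y ~ x1 + x2 + x3, tb)))
    expect_equal(ours, ref, tolerance = 1e-8)
  })
})

test_that("VIF on the standard cohort predictors is well-behaved", {
  v <- check_multicollinearity(fake_covariates())
  expect_equal(nrow(v), 3)
  expect_true(all(v$vif >= 1 & v$vif < 10))
})

test_that("normality assessment recommends logs for skewed positive data", {
  withr::with_seed(5, {
    tb <- data.frame(m1 = rnorm(35, 100, 10), m2 = rlnorm(35, 0, 1),
                     m3 = rep(1, 35))
    out <- assess_distributions(tb, c("m1", "m2", "m3"))
    expect_gt(out$shapiro_p[1], 0.05)
    expect_false(out$log_recommended[1])
    expect_lt(out$shapiro_p[2], 0.05)
    expect_true(out$log_recommended[2])
    expect_gt(out$shapiro_p_log[2], out$shapiro_p[2])
    expect_true(is.na(out$shapiro_p[3]))
  })
  # log-normal power: the transform is recommended in most replicates
  withr::with_seed(6, {
    rate <- mean(replicate(200, {
      tb <- data.frame(m = rlnorm(35, 0, 1))
      assess_distributions(tb, "m")$log_recommended
    }))
    expect_gt(rate, 0.8)
  })
})

test_that("the transform is withheld for nonpositive values", {
  withr::with_seed(7, {
    tb <- data.frame(m = c(-1, rlnorm(34, 0, 2)))
    expect_warning(out <- assess_distributions(tb, "m"), "nonpositive")
    expect_false(out$log_recommended[1])
  })
})

test_that("heteroscedasticity is flagged when variance tracks a predictor", {
  withr::with_seed(8, {
    n <- 200
    tb <- fake_covariates(100, 100)
    tb$m <- 50 + tb$age + rnorm(n, sd = 0.2 * tb$age)
    out <- check_heteroscedasticity(tb, "m")
    expect_lt(out$p, 0.05)
    expect_true(out$weighted)
    tb$m2 <- rep(3, n)
    expect_true(is.na(check_heteroscedasticity(tb, "m2")$p))
  })
})

test_that("overdispersed counts raise the negative-binomial flag", {
  withr::with_seed(9, {
    tb <- fake_covariates()
    tb$c <- rnbinom(35, size = 1 / 0.15, mu = ifelse(tb$group == "AWS", 86, 58))
    out <- check_overdispersion(tb, "c")
    expect_gt(out$dispersion, 1)
    expect_true(out$overdispersed)
    tb$c2 <- rep(7L, 35)
    expect_false(check_overdispersion(tb, "c2")$overdispersed)
    tb$c3 <- tb$age  # not integers
    expect_error(check_overdispersion(tb, "c3"), "count")
  })
})

test_that("the model plan reproduces the published family assignment", {
  plan <- build_model_plan(paper_narrative_assessments())
  lab <- setNames(plan$model_label, plan$metric)
  expect_equal(unname(lab["speech_rate_wpm"]), "Weighted GLM Gaussian")
  expect_equal(unname(lab["total_pause_time_s"]), "Weighted gamma GLM")
  expect_equal(unname(lab["long_pause_cv"]), "Weighted gamma GLM")
  expect_equal(unname(lab[c("pause_count", "long_pause_count", "short_pause_count")]),
               rep("Negative binomial", 3))
  expect_true(plan$log_transform[plan$metric == "mean_pause_ms"])
  others <- setdiff(metric_names(),
                    c("speech_rate_wpm", "total_pause_time_s", "long_pause_cv",
                      "pause_count", "long_pause_count", "short_pause_count"))
  expect_true(all(lab[others] == "GLM Gaussian"))
})

test_that("clean assessments give all-Gaussian models", {
  a <- paper_narrative_assessments()
  a$weighted <- FALSE; a$log_recommended <- FALSE; a$log_improved <- FALSE
  a$overdispersed <- FALSE
  plan <- build_model_plan(a)
  expect_true(all(plan$family == "gaussian"))
  expect_false(any(plan$weighted | plan$log_transform))
})

test_that("a gamma request with nonpositive values falls back to Gaussian", {
  a <- paper_narrative_assessments()[2, ]  # total pause time: weighted gamma
  a$all_positive <- FALSE
  expect_warning(plan <- build_model_plan(a), "gaussian")
  expect_equal(plan$family, "gaussian")
  expect_true(plan$weighted)
})

test_that("unweighted Gaussian GLM reproduces least squares exactly", {
  withr::with_seed(10, {
    tb <- fake_covariates()
    tb$speech_rate_wpm <- 160 - 35 * (tb$group == "AWS") + rnorm(35, sd = 20)
    plan <- data.frame(metric = "speech_rate_wpm", family = "gaussian",
                       weighted = FALSE, log_transform = FALSE,
                       link = "identity", model_label = "GLM Gaussian")
    r <- fit_group_models(tb, plan)
    df <- tb
    df$group <- factor(df$group, c("AWNS", "AWS"))
    df$sex <- factor(df$sex, c("female", "male"))
    ls <- coef(lm(speech_rate_wpm ~ group + sex + age, df))
    expect_equal(r$B[1:4], unname(ls), tolerance = 1e-8)
  })
})

test_that("relabeling the groups flips only the group coefficient's sign", {
  withr::with_seed(11, {
    tb <- fake_covariates()
    tb$vocal_cv <- 0.74 + 0.08 * (tb$group == "AWS") + rnorm(35, sd = 0.08)
    plan <- data.frame(metric = "vocal_cv", family = "gaussian",
                       weighted = FALSE, log_transform = FALSE,
                       link = "identity", model_label = "GLM Gaussian")
    r1 <- fit_group_models(tb, plan)
    tb2 <- tb
    tb2$group <- ifelse(tb$group == "AWS", "AWNS", "AWS")
    r2 <- fit_group_models(tb2, plan)
    expect_equal(r2$B[r2$predictor == "Group"], -r1$B[r1$predictor == "Group"],
                 tolerance = 1e-8)
    expect_equal(r2$B[r2$predictor %in% c("Sex", "Age")],
                 r1$B[r1$predictor %in% c("Sex", "Age")], tolerance = 1e-8)
    # intercept SE changes with the reference level; the others must not
    expect_equal(r2$SE[-1], r1$SE[-1], tolerance = 1e-8)
  })
})

test_that("negative-binomial fits recover the generating dispersion", {
  tb <- make_synthetic_cohort(cohort_spec(n_awns = 250, n_aws = 250, seed = 9))
  plan <- data.frame(metric = "long_pause_count", family = "negative_binomial",
                     weighted = FALSE, log_transform = FALSE, link = "log",
                     model_label = "Negative binomial")
  r <- fit_group_models(tb, plan)
  a <- r[r$predictor == "Dispersion (alpha)", ]
  expect_lt(abs(a$B - 0.18), 3 * a$SE)
  expect_gt(a$B, 0)
})

test_that("the negative binomial approaches the Poisson as dispersion vanishes", {
  withr::with_seed(12, {
    tb <- fake_covariates(250, 250, seed = 12)
    tb$c <- rnbinom(500, size = 1 / 1e-4, mu = exp(3 + 0.4 * (tb$group == "AWS")))
    plan <- data.frame(metric = "c", family = "negative_binomial",
                       weighted = FALSE, log_transform = FALSE, link = "log",
                       model_label = "Negative binomial")
    r <- fit_group_models(tb, plan)
    df <- tb; df$group <- factor(df$group, c("AWNS", "AWS"))
    df$sex <- factor(df$sex, c("female", "male"))
    pois <- coef(glm(c ~ group + sex + age, df, family = poisson()))
    expect_equal(r$B[1:4], unname(pois), tolerance = 1e-2)
  })
})

test_that("BH correction matches the step-up definition", {
  out <- adjust_fdr(c(.01, .02, .03, .04), q = .1)
  expect_true(all(out$significant))
  expect_false(any(adjust_fdr(rep(1, 5))$significant))
  expect_true(adjust_fdr(.05, q = .1)$significant)
  withr::with_seed(13, {
    for (i in 1:50) {
      p <- runif(sample(1:12, 1))^sample(1:3, 1)
      got <- adjust_fdr(p, q = .1)
      want <- brute_force_bh(p, .1)
      expect_equal(got$significant, want$reject)
      expect_equal(got$p_adjusted, want$adjusted, tolerance = 1e-12)
    }
  })
  expect_equal(nrow(adjust_fdr(numeric(0))), 0)
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("%SS correlations recover exact and simulated associations", {
  tb <- fake_covariates()
  tb$m <- -tb$percent_ss
  out <- correlate_with_ss(tb, "m")
  expect_equal(out$r, -1)
  expect_equal(out$n, 17)

  withr::with_seed(14, {
    rho <- 0.86
    z <- rnorm(35); e <- rnorm(35)
    tb2 <- fake_covariates()
    tb2$percent_ss <- 5 + 2 * z
    tb2$m <- rho * z + sqrt(1 - rho^2) * e
    got <- correlate_with_ss(tb2, "m")$r
    se <- (1 - rho^2) / sqrt(32)
    expect_lt(abs(got - rho), 3 * se)
  })

  tb$m2 <- 1
  expect_true(is.na(correlate_with_ss(tb, "m2")$r))
  # zero-filled variant includes the whole cohort (metric defined everywhere)
  expect_equal(correlate_with_ss(tb, "age", subset = "all_zero_fill")$n, 35)
  expect_equal(correlate_with_ss(tb, "age")$n, 17)
})

test_that("the full assessment pipeline runs on a synthetic cohort", {
  tb <- make_synthetic_cohort(cohort_spec(seed = 30))
  a <- assess_cohort(tb)
  expect_equal(nrow(a), 13)
  expect_true(all(a$is_count == (a$metric %in%
    c("pause_count", "long_pause_count", "short_pause_count"))))
  plan <- build_model_plan(a)
  res <- suppressWarnings(fit_group_models(tb, plan))
  expect_true(all(metric_names() %in% res$metric))
  grp <- res[res$predictor == "Group", ]
  expect_true(all(is.finite(grp$p)))
  fdr <- adjust_fdr(grp$p, q = 0.1)
  expect_equal(nrow(fdr), 13)
})
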