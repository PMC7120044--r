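test_that("Kaplan-Meier curve matches the product-limit closed form", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-14)
  # all censored: constant 1
  km0 <- km_curve(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # time-scale equivariance: doubling times rescales the x axis only
  km2 <- km_curve(c(2, 4, 6), c(1, 1, 1))
  expect_equal(km2$surv, km$surv)
  expect_equal(km2$time, 2 * km$time)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  expect_error(km_curve(c(-1, 2), c(1, 1)), "positive")
})

test_that("KM curves are probabilities, start at 1 and never increase", {
  set.seed(9)
  for (i in 1:10) {
    t <- rexp(30, 0.01); e <- rbinom(30, 1, 0.7)
    km <- km_curve(t, e)
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(km$surv) <= 1e-15))
    expect_lte(km$surv[1], 1)
  }
})

test_that("median-split log-rank matches hand arithmetic and null case", {
  # two groups of 3, all events, interleaved times
  cl <- clinical_table(data.frame(
    sample_id = paste0("s", 1:6),
    time = c(1, 3, 5, 2, 4, 6), event = 1))
  expr <- setNames(c(10, 10, 10, 1, 1, 1), cl$sample_id)
  res <- median_split_logrank(expr, cl)
  grp <- ifelse(expr > median(expr), "high", "low")
  expect_equal(res$statistic,
               logrank_oracle(cl$time, cl$event, grp),
               tolerance = 1e-10)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_identical(c(res$n_high, res$n_low), c(3L, 3L))
  # identical survival in both groups: statistic ~ 0, p ~ 1
  cl2 <- clinical_table(data.frame(
    sample_id = paste0("t", 1:6),
    time = c(1, 2, 3, 1, 2, 3), event = 1))
  null_res <- median_split_logrank(
    setNames(c(2, 2, 2, 1, 1, 1), cl2$sample_id), cl2)
  expect_lt(null_res$statistic, 1e-10)
  expect_gt(null_res$p, 0.99)
})

test_that("median split sends ties to the low group deterministically", {
  cl <- clinical_table(data.frame(
    sample_id = paste0("s", 1:5), time = 1:5, event = 1))
  expr <- setNames(c(1, 2, 3, 4, 5), cl$sample_id)
  res <- median_split_logrank(expr, cl)
  # median value 3 itself goes low: 2 high, 3 low
  expect_identical(c(res$n_high, res$n_low), c(2L, 3L))
  expect_error(median_split_logrank(setNames(rep(1, 5), cl$sample_id), cl),
               "empty")
})

test_that("Cox fits recover planted hazards", {
  # null hazard: coefficient near zero at n = 200
  betas0 <- vapply(1:10, function(s) {
    co <- generate_cohort(surv_config(200, hazard_beta = 0, seed = s))
    lnc <- names(co$truth$prognostic_lncrnas)[1]
    unname(coef(cox_fit(co$rna, co$clinical, lnc)))
  }, numeric(1))
  expect_lt(abs(mean(betas0)), 0.1)
  # positive hazard: positive fitted sign in (nearly) all seeds
  signs <- vapply(1:20, function(s) {
    co <- generate_cohort(surv_config(200, hazard_beta = 0.8,
                                      seed = 100 + s))
    lnc <- names(co$truth$prognostic_lncrnas)[1]
    sign(unname(coef(cox_fit(co$rna, co$clinical, lnc))))
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("Cox coefficient bias is small at large n on the hazard scale", {
  # the planted hazard acts per standard deviation of expression; the
  # per-unit coefficient is rescaled by the covariate SD before comparison
  betas <- vapply(1:10, function(s) {
    co <- generate_cohort(surv_config(500, hazard_beta = 0.8,
                                      seed = 4000 + s))
    lnc <- names(co$truth$prognostic_lncrnas)[1]
    expr <- co$rna$values[lnc, co$clinical$sample_id]
    unname(coef(cox_fit(co$rna, co$clinical, lnc))) * sd(expr)
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.8) / 0.8, 0.1)
})

test_that("a binary covariate reproduces the median-split ordering", {
  co <- generate_cohort(surv_config(100, hazard_beta = 1, seed = 77))
  lnc <- names(co$truth$prognostic_lncrnas)[1]
  expr <- co$rna$values[lnc, co$clinical$sample_id]
  split_var <- as.numeric(expr > median(expr))
  em <- tiny_expr(matrix(split_var, 1), co$rna$groups[co$clinical$sample_id],
                  features = "HIGH", samples = co$clinical$sample_id)
  fit <- cox_fit(em, co$clinical, "HIGH")
  scr <- median_split_logrank(expr, co$clinical)
  km_high <- km_curve(co$clinical$time[split_var == 1],
                      co$clinical$event[split_var == 1])
  km_low <- km_curve(co$clinical$time[split_var == 0],
                     co$clinical$event[split_var == 0])
  # the high-expression group dies faster, so its Cox risk is positive and
  # the screen flags the feature
  expect_gt(unname(coef(fit)), 0)
  expect_lt(scr$p, 0.05)
  expect_lt(min(km_high$surv), min(km_low$surv))
})

test_that("overfitted Cox designs warn and degenerate inputs error", {
  co <- generate_cohort(surv_config(15, hazard_beta = 0.5, seed = 5))
  feats <- rownames(co$rna$values)
  expect_warning(cox_fit(co$rna, co$clinical, feats), "overfitting")
  cl_noev <- clinical_table(data.frame(
    sample_id = co$clinical$sample_id, time = co$clinical$time,
    event = 0))
  expect_error(cox_fit(co$rna, cl_noev, feats[1]), "no events")
})

test_that("horizon AUC behaves as a Mann-Whitney probability", {
  cl <- clinical_table(data.frame(
    sample_id = paste0("s", 1:8),
    time = c(100, 200, 300, 400, 2000, 2100, 2200, 2300),
    event = c(1, 1, 1, 1, 0, 0, 0, 0)))
  # perfectly separating score
  sep <- setNames(c(8:5, 4:1), cl$sample_id)
  expect_equal(as.numeric(auc_at_horizon(sep, cl, horizon = 1095)), 1)
  # monotone transform invariance
  expect_equal(as.numeric(auc_at_horizon(exp(sep / 2), cl, horizon = 1095)),
               1)
  # ties count one half
  tied <- setNames(rep(1, 8), cl$sample_id)
  expect_equal(as.numeric(auc_at_horizon(tied, cl, horizon = 1095)), 0.5)
  # early-censored samples are excluded from both groups
  cl2 <- clinical_table(data.frame(
    sample_id = paste0("s", 1:5),
    time = c(100, 500, 1200, 1300, 900), event = c(1, 0, 0, 0, 1)))
  sc <- setNames(c(5, 4, 3, 2, 1), cl2$sample_id)
  auc <- auc_at_horizon(sc, cl2, horizon = 1095)
  expect_identical(attr(auc, "n_cases"), 2L)
  expect_identical(attr(auc, "n_controls"), 2L)
  expect_error(auc_at_horizon(sc, cl2, horizon = 50), "no cases")
})

test_that("random scores give near-chance AUC on simulated cohorts", {
  set.seed(123)
  aucs <- vapply(1:30, function(s) {
    co <- generate_cohort(surv_config(100, hazard_beta = 1,
                                      censor_frac = 0.1, seed = 300 + s))
    rand <- setNames(rnorm(nrow(co$clinical)), co$clinical$sample_id)
    as.numeric(auc_at_horizon(rand, co$clinical))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
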