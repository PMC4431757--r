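# direct product-moment evaluation, the oracle for pearson_correlation
pm_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(pearson_correlation(x, y)$r, 0.6, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 5)$r, -1)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:200, 1L)
    a <- rnorm(n); b <- rnorm(n)
    res <- pearson_correlation(a, b)
    expect_equal(res$r, pm_r(a, b), tolerance = 1e-12)
    expect_lte(abs(res$r), 1)
    # symmetry in the pair
    expect_equal(pearson_correlation(b, a)$r, res$r)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

# cohort where BMI follows the M5 linear form exactly
exact_m5_cohort <- function(n = 120L, seed = 51L) {
  set.seed(seed)
  co <- data.frame(
    subject_id = sprintf("e%03d", 1:n),
    age = sample(40:84, n, TRUE),
    sex = sample(c("man", "woman"), n, TRUE),
    energy_intake_kcal = runif(n, 1500, 3200),
    energy_expenditure_mets_h = runif(n, 25, 50),
    gps = runif(n, 15, 40),
    efficiency = runif(n, 0.3, 1),
    stringsAsFactors = FALSE
  )
  co$bmi_baseline <- 28.84 + 0.25 * (co$sex == "woman") + 0.05 * co$age +
    0.03 * co$gps - 19.47 * co$efficiency
  co
}

test_that("noise-free linear data is interpolated to full precision", {
  co <- exact_m5_cohort()
  for (m in c("ols", "mm")) {
    # lm warns about the (intended) perfect fit in OLS mode
    f <- suppressWarnings(fit_model(model_spec("M5"), co, method = m))
    est <- setNames(f$coefficients$estimate, f$coefficients$term)
    expect_equal(unname(est[c("intercept", "sex_woman", "age", "gps", "efficiency")]),
                 c(28.84, 0.25, 0.05, 0.03, -19.47), tolerance = 1e-7,
                 label = m)
    expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  }
})

test_that("OLS mode reproduces the normal-equations solution and R2 algebra", {
  set.seed(61)
  co <- exact_m5_cohort(200L, seed = 61L)
  co$bmi_baseline <- co$bmi_baseline + rnorm(200, 0, 1.5)
  f <- fit_model(model_spec("M5"), co, method = "ols")
  X <- cbind(1, as.numeric(co$sex == "woman"), co$age, co$gps, co$efficiency)
  beta_ne <- solve(t(X) %*% X, t(X) %*% co$bmi_baseline)
  expect_equal(f$coefficients$estimate, as.numeric(beta_ne), tolerance = 1e-10)
  res <- co$bmi_baseline - X %*% beta_ne
  r2 <- 1 - sum(res^2) / sum((co$bmi_baseline - mean(co$bmi_baseline))^2)
  expect_equal(f$r2, r2, tolerance = 1e-12)
  expect_equal(f$adj_r2, 1 - (1 - r2) * (200 - 1) / (200 - 4 - 1),
               tolerance = 1e-12)
  expect_lte(f$adj_r2, 1)
})

test_that("MM fits resist gross BMI outliers far better than OLS", {
  set.seed(71)
  n <- 600L
  co <- exact_m5_cohort(n, seed = 71L)
  co$bmi_baseline <- co$bmi_baseline + rnorm(n, 0, 1)
  clean_ols <- fit_model(model_spec("M5"), co, method = "ols")
  # gross +10 kg/m2 outliers planted on the 5% most efficient subjects, so
  # the leverage falls on the efficiency coefficient
  bad <- order(co$efficiency, decreasing = TRUE)[seq_len(n %/% 20)]
  co2 <- co
  co2$bmi_baseline[bad] <- co2$bmi_baseline[bad] + 10
  dirty_ols <- fit_model(model_spec("M5"), co2, method = "ols")
  dirty_mm <- fit_model(model_spec("M5"), co2, method = "mm")
  pick <- function(f, term) f$coefficients$estimate[f$coefficients$term == term]
  ols_shift <- abs(pick(dirty_ols, "efficiency") - pick(clean_ols, "efficiency"))
  mm_shift <- abs(pick(dirty_mm, "efficiency") - pick(clean_ols, "efficiency"))
  expect_gt(ols_shift, 1)  # the contamination visibly bends OLS
  expect_lt(mm_shift, 0.2 * ols_shift)
})

test_that("model comparison covers the five specifications and nests properly", {
  cfg <- sim_config(n_subjects = 500L, seed = 81L)
  sim <- simulate_cohort(cfg)
  co <- simulate_followup(sim$cohort, cfg)
  co$efficiency <- unname(efficiency_scores(build_dea_frame(co)))
  mc <- model_comparison(co, "bmi_baseline", method = "ols")
  expect_named(mc$fits, c("M1", "M2", "M3", "M4", "M5"))
  expect_equal(unique(vapply(mc$fits, function(f) f$n, 0)), nrow(co))
  # nesting: adding efficiency to (sex, age, gps) cannot lower in-sample R2
  expect_gte(mc$fits$M5$r2, mc$fits$M3$r2)
  expect_gte(mc$fits$M2$r2,
             fit_model_r2_sex_age <- summary(lm(bmi_baseline ~ I(sex == "woman") + age,
                                                data = co))$r.squared)
  # duplicating all rows leaves OLS estimates unchanged
  dup <- rbind(co, transform(co, subject_id = paste0(subject_id, "_b")))
  f1 <- fit_model(model_spec("M4"), co, method = "ols")
  f2 <- fit_model(model_spec("M4"), dup, method = "ols")
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
  # pure-noise drift: all five change models sit near zero adjusted R2
  mc_ch <- model_comparison(co, "yearly_bmi_change", method = "ols")
  expect_true(all(vapply(mc_ch$fits, function(f) f$adj_r2, 0) < 0.04))
  expect_lt(nrow(change_analysis_filter(co)), nrow(co))
})

test_that("rank deficiency and short data are rejected with clear errors", {
  co <- exact_m5_cohort(60L)
  co$gps <- 2 * co$age  # collinear with age
  expect_error(fit_model(model_spec("M5"), co, method = "ols"),
               "rank-deficient.*gps")
  tiny <- exact_m5_cohort(4L)
  expect_error(fit_model(model_spec("M5"), tiny), "complete rows")
  expect_error(fit_model(model_spec("M2"), toy_cohort()[-7]),
               "lacks covariate")
})

test_that("age subgroups partition the cohort and agree under homogeneity", {
  co <- exact_m5_cohort(800L, seed = 91L)
  set.seed(92)
  co$bmi_baseline <- co$bmi_baseline + rnorm(800, 0, 1)
  fits <- age_subgroup_fits(co, cutoff = 60, method = "ols")
  expect_equal(fits$younger$n + fits$older$n, 800L)
  # a homogeneous generating effect appears in both strata within noise
  pick <- function(f, term) f$coefficients[f$coefficients$term == term, ]
  for (term in c("gps", "efficiency")) {
    a <- pick(fits$younger, term); b <- pick(fits$older, term)
    expect_lt(abs(a$estimate - b$estimate),
              3 * sqrt(a$se^2 + b$se^2), label = term)
  }
  expect_error(age_subgroup_fits(co, cutoff = 10), "empty stratum")
})

test_that("efficiency quartiles are near-equal groups with sane input means", {
  cfg <- sim_config(n_subjects = 402L, seed = 95L, sigma_noise = 0.5)
  co <- simulate_cohort(cfg)$cohort
  co$efficiency <- unname(efficiency_scores(build_dea_frame(co)))
  qs <- quartile_summary(co)
  expect_equal(qs$quartile, 1:4)
  expect_equal(sum(qs$n), 402L)
  expect_lte(diff(range(qs$n)), 1)
  expect_true(all(diff(qs$mean_efficiency) > 0))
  # tied scores still split into near-equal groups
  co2 <- co; co2$efficiency <- rep(0.5, nrow(co2))
  qs2 <- quartile_summary(co2)
  expect_lte(diff(range(qs2$n)), 1)
  expect_equal(qs2$mean_efficiency, rep(0.5, 4))
  expect_error(quartile_summary(co[1:3, ]), "at least 4")
  expect_error(quartile_summary(toy_cohort()), "efficiency")
})
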