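test_that("fit_ols reproduces the normal-equations solution", {
  # fixed small fixture
  X <- cbind(x1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             x2 = c(2, 1, 4, 3, 6, 5, 8, 7))
  y <- c(1.2, 0.8, 2.9, 2.6, 5.1, 4.4, 7.0, 6.3)
  fit <- fit_ols(y, X)
  or <- oracle_ols(y, X)
  expect_equal(unname(c(fit$intercept, coef(fit))), unname(or$coef), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(or$se[-1]), tolerance = 1e-10)
  expect_equal(fit$r_squared, or$r2, tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, or$adj_r2, tolerance = 1e-10)
  expect_equal(fit$f_statistic, or$f, tolerance = 1e-10)
  expect_equal(unname(fit$f_df), or$df)

  set.seed(201)
  for (i in 1:100) {
    n <- sample(15:60, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    fit <- fit_ols(y, X); or <- oracle_ols(y, X)
    expect_equal(unname(c(fit$intercept, coef(fit))), unname(or$coef), tolerance = 1e-8)
    expect_equal(fit$adj_r_squared, or$adj_r2, tolerance = 1e-8)
  }
})

test_that("fit_ols degenerate and exact cases behave", {
  x <- 1:20
  y <- 2 * x + 1
  fit <- suppressWarnings(fit_ols(y, cbind(x = as.numeric(x)))) # exact fit warns
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(coef(fit)), 2)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$beta), 1) # standardized slope of exact line

  X <- cbind(a = rnorm(30), b = 0)
  X[, "b"] <- 2 * X[, "a"]
  expect_error(fit_ols(rnorm(30), X), "rank deficient.*b")
  expect_error(fit_ols(rnorm(3), cbind(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               "insufficient")
  # standardized beta equals the coefficient from a z-scored refit
  set.seed(202)
  X <- cbind(x1 = rnorm(50), x2 = rbinom(50, 1, .4))
  y <- rnorm(50)
  fit <- fit_ols(y, X)
  zfit <- fit_ols(drop(scale(y)), scale(X))
  expect_equal(fit$coefficients$beta, zfit$coefficients$estimate, tolerance = 1e-10)
})

test_that("listwise deletion and noise columns behave as expected", {
  set.seed(203)
  X <- cbind(x1 = rnorm(40), x2 = rnorm(40))
  y <- X[, 1] + rnorm(40)
  ym <- y; ym[5] <- NA
  expect_identical(fit_ols(ym, X)$n_used, 39L)
  # adding pure noise never decreases R^2
  for (i in 1:20) {
    f1 <- fit_ols(y, X)
    f2 <- fit_ols(y, cbind(X, junk = rnorm(40)))
    expect_gte(f2$r_squared, f1$r_squared - 1e-12)
  }
})

test_that("MANOVA on a single outcome reduces exactly to the OLS overall F", {
  set.seed(204)
  n <- 80
  X <- cbind(score = rnorm(n), age = rnorm(n), flag = rbinom(n, 1, .3))
  y <- 0.5 * X[, 1] + rnorm(n)
  mv <- fit_manova(matrix(y, ncol = 1, dimnames = list(NULL, "y")), X)
  ols <- fit_ols(y, X)
  expect_equal(mv$overall$approx_f, ols$f_statistic, tolerance = 1e-8)
  expect_equal(mv$overall$p_value, unname(ols$f_p), tolerance = 1e-8)
  # per-predictor Pillai F equals the squared t test with one DV
  expect_equal(mv$terms$approx_f, ols$coefficients$t^2, tolerance = 1e-8)
})

test_that("MANOVA reports per-predictor Pillai traces within bounds", {
  p <- apply_exclusions(generate_admissions(generator_config(), seed = 61))$patients
  d <- build_design(p)
  mv <- fit_manova(d$Y, d$X)
  expect_identical(nrow(mv$terms), ncol(d$X))
  expect_true(all(mv$terms$pillai >= 0 & mv$terms$pillai <= ncol(d$Y)))
  expect_true(all(mv$terms$p_value >= 0 & mv$terms$p_value <= 1))
  # the planted score effect is detected
  expect_lt(mv$terms$p_value[mv$terms$predictor == "whole_brain_score"], 0.05)
  # duplicated outcome -> singular residual covariance
  Y2 <- cbind(d$Y, again = d$Y[, 1])
  expect_error(fit_manova(Y2, d$X), "singular residual covariance")
})

test_that("build_design assembles the 12-predictor matrix with listwise deletion", {
  p <- apply_exclusions(generate_admissions(generator_config(), seed = 71))$patients
  d <- build_design(p)
  expect_identical(ncol(d$X), 12L)
  expect_identical(d$n_used, nrow(p))
  expect_identical(colnames(d$Y)[1], "log1p_fiv")
  expect_equal(unname(d$Y[, "log1p_fiv"]), log1p(p$fiv))
  draw <- build_design(p, fiv_transform = "raw")
  expect_identical(colnames(draw$Y)[1], "fiv")

  p$age[3] <- NA
  d2 <- build_design(p)
  expect_identical(d2$n_used, nrow(p) - 1L)
  expect_identical(d2$dropped, 1L)

  p$treatment <- "none"
  d3 <- build_design(p)
  expect_true(all(d3$X[, c("treat_iv", "treat_ia", "treat_thrombectomy")] == 0))
  expect_error(build_design(p[, setdiff(names(p), "age")]), "missing required column.*age")
})

test_that("subgroup filtering honours specs and the minimum-n guard", {
  co <- apply_exclusions(generate_admissions(generator_config(), seed = 81))
  all_sg <- subgroup_filter(co, subgroup_spec("all"))
  expect_identical(all_sg$patients, co$patients)
  expect_true(attr(all_sg, "analyzable"))

  mca <- subgroup_filter(co, subgroup_spec("mca", territory = "MCA"))
  expect_true(all(mca$patients$territory == "MCA"))

  med <- subgroup_filter(co, subgroup_spec("medium", fiv_range = c(15, 100)))
  expect_true(all(med$patients$fiv >= 15 & med$patients$fiv < 100))

  none <- subgroup_filter(co, subgroup_spec("none", fiv_range = c(1e6, 1e7)))
  expect_identical(nrow(none$patients), 0L)
  expect_false(attr(none, "analyzable"))

  sev <- subgroup_filter(co, subgroup_spec("severe", nihss_min = 17))
  expect_true(all(sev$patients$nihss_discharge > 17))

  expect_error(subgroup_spec("bad", min_n = 5), "at least")
  expect_error(subgroup_spec("bad", fiv_range = c(100, 15)))
})
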