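test_that("generation is deterministic given (config, seed) and requires a seed", {
  cfg <- small_config(120L)
  a <- generate_admissions(cfg, seed = 9)
  b <- generate_admissions(cfg, seed = 9)
  expect_identical(a, b)
  d <- withr::local_tempdir()
  write_cohort_csv(a, file.path(d, "a.csv"))
  write_cohort_csv(b, file.path(d, "b.csv"))
  expect_identical(readLines(file.path(d, "a.csv")), readLines(file.path(d, "b.csv")))
  expect_false(identical(a$patients,
                         generate_admissions(cfg, seed = 10)$patients))
  expect_error(generate_admissions(cfg), "seed is required")
})

test_that("config validation enforces probability and exclusion invariants", {
  expect_error(generator_config(p_male = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(p_treatment = c(iv = .5, ia = .2, thrombectomy = .1, none = .1)),
               "sum to 1")
  expect_error(generator_config(n_admissions = 100, n_excluded_quality = 80,
                                n_excluded_diagnosis = 30), "exceed")
  bad <- default_effects(); bad$fiv$resid_sd <- 0
  expect_error(generator_config(effects = bad), "residual SDs")
})

test_that("exclusion stage reproduces the configured accounting", {
  co <- generate_admissions(generator_config(), seed = 3)
  expect_identical(nrow(co$patients), 686L)
  an <- apply_exclusions(co)
  expect_identical(nrow(an$patients), 530L)
  removed <- attr(an, "exclusions")
  expect_identical(unname(removed[c("data_quality", "alternative_diagnosis")]),
                   c(69L, 87L))
  expect_identical(sum(removed), 156L)
  # admission order is preserved
  expect_identical(an$patients$patient_id,
                   co$patients$patient_id[co$patients$exclusion == "none"])
  # no flags -> identity
  co0 <- generate_admissions(small_config(50L), seed = 4)
  an0 <- apply_exclusions(co0)
  expect_identical(an0$patients, co0$patients)
  expect_identical(sum(attr(an0, "exclusions")), 0L)
})

test_that("configured marginals are recovered within 3 binomial SE at n = 530", {
  cfg <- generator_config()
  p <- apply_exclusions(generate_admissions(cfg, seed = 21))$patients
  n <- nrow(p)
  expect_marginal <- function(obs, target) {
    se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(obs - target), 3 * se + 1e-12)
  }
  expect_marginal(mean(p$atherosclerosis), cfg$prevalence$atherosclerosis)
  expect_marginal(mean(p$smoking), cfg$prevalence$smoking)
  expect_marginal(mean(p$glucose_elevated), cfg$prevalence$glucose)
  expect_marginal(mean(p$male), cfg$p_male)
  expect_marginal(mean(p$fiv < 15), 0.66)
  for (lev in names(cfg$p_treatment)) {
    expect_marginal(mean(p$treatment == lev), cfg$p_treatment[[lev]])
  }
  expect_true(all(p$age >= 19 & p$age <= 90))
  expect_true(all(p$fiv >= 0))
  expect_true(all(p$nihss_discharge %in% 0:42))
  expect_true(all(p$mrs_discharge %in% 0:6))
  expect_true(all(p$fiv[p$tia] == 0))
})

test_that("vasculature degrades monotonely in the latent burden", {
  expect_error(generate_vasculature(1.5), "\\[0, 1\\]")
  set.seed(31)
  mean_score <- function(burden, reps = 200) {
    mean(vapply(seq_len(reps), function(i) {
      whole_brain_score(generate_vasculature(burden))$whole_brain_score
    }, integer(1)))
  }
  m0 <- mean_score(0); m5 <- mean_score(0.5); m1 <- mean_score(1)
  expect_gt(m0, 50)        # near the 56 maximum
  expect_lt(m1, m0 - 40)   # well below the healthy mean
  expect_gt(m5, m1)
  expect_lt(m5, m0)
})

test_that("a zero-effect configuration yields a null score-outcome association", {
  cfg <- small_config(530L, effects = null_effects())
  p <- generate_admissions(cfg, seed = 17)$patients
  r <- cor(p$whole_brain_score, log1p(p$fiv))
  expect_lt(abs(r), 3 / sqrt(nrow(p)))
})

test_that("planted effects leave the advertised signature in the cohort", {
  cfg <- generator_config()
  p <- apply_exclusions(generate_admissions(cfg, seed = 29))$patients
  # negative score-outcome correlations, as planted
  expect_lt(cor(p$whole_brain_score, log1p(p$fiv)), -0.2)
  expect_lt(cor(p$whole_brain_score, p$mrs_discharge), -0.2)
  # inter-outcome correlations in the plausible 0.3-0.8 band
  expect_gt(cor(p$mrs_discharge, p$nihss_discharge), 0.3)
  expect_gt(cor(p$mrs_discharge, log1p(p$fiv)), 0.3)
  # treatment allocation is severity-tilted: treated patients have worse scores
  expect_lt(mean(p$whole_brain_score[p$treatment != "none"]),
            mean(p$whole_brain_score[p$treatment == "none"]))
})
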