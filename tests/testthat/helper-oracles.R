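# Independent brute-force oracles (definitional formulas) and small fixtures.

# textbook covariance / SD correlation with its t test
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = 2 * stats::pt(-abs(t), n - 2))
}

# expected-counts chi-squared and Cramer's V from first principles
oracle_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(v = sqrt(chi2 / (n * (min(dim(tab)) - 1))), chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# normal-equations least squares with classical SEs, F, adjusted R^2
oracle_ols <- function(y, X) {
  Xf <- cbind(1, X)
  n <- nrow(Xf); k <- ncol(Xf)
  b <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  res <- y - Xf %*% b
  s2 <- sum(res^2) / (n - k)
  se <- sqrt(diag(s2 * solve(t(Xf) %*% Xf)))
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  r2 <- 1 - rss / tss
  f <- ((tss - rss) / (k - 1)) / (rss / (n - k))
  list(coef = drop(b), se = se, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k), f = f,
       df = c(k - 1, n - k))
}

# a complete random-but-valid grading sheet (uses current RNG state)
random_sheet <- function() {
  sch <- vessel_slots()
  grade <- integer(nrow(sch))
  g_idx <- sch$kind == "graded"
  grade[g_idx] <- sample(c(-4L, -3L, -2L, -1L, 0L, 1L), sum(g_idx), replace = TRUE)
  grade[!g_idx] <- sample(c(0L, 1L), sum(!g_idx), replace = TRUE)
  vasculature(data.frame(vessel = sch$vessel, side = sch$side, grade = grade),
              pial_cortical = sample(0:15, 1), pial_cerebellar = sample(0:6, 1))
}

# small fast generator config (analysis set only, no exclusions)
small_config <- function(n = 200L, ...) {
  generator_config(n_admissions = n, n_excluded_quality = 0L,
                   n_excluded_diagnosis = 0L, ...)
}

# predictors planted on log1p(FIV) by the generator, for recovery checks
planted_fiv_design <- function(patients, config) {
  cbind(
    z_score = (patients$whole_brain_score - config$score_center) / config$score_scale,
    athero = as.numeric(patients$atherosclerosis),
    glucose = as.numeric(patients$glucose_elevated),
    iv = as.numeric(patients$treatment == "iv"),
    ia = as.numeric(patients$treatment == "ia"),
    thrombectomy = as.numeric(patients$treatment == "thrombectomy")
  )
}

planted_fiv_coefs <- function(config) {
  f <- config$effects$fiv
  c("(Intercept)" = f$intercept, z_score = f$score, athero = f$athero,
    glucose = f$glucose, iv = unname(f$treatment["iv"]),
    ia = unname(f$treatment["ia"]),
    thrombectomy = unname(f$treatment["thrombectomy"]))
}
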