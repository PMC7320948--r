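# Multivariate stage: OLS outcome models (standardized beta, t, p, overall F,
# adjusted R^2), MANOVA (Pillai's trace), and subgroup machinery.

#' Ordinary least-squares outcome model
#'
#' Fits `y ~ X` by least squares (via [stats::lm()]), reporting per-predictor
#' coefficient, SE, t, two-sided p and standardized beta (the coefficient
#' rescaled by `sd(x)/sd(y)`; binary dummies are rescaled like continuous
#' columns), plus the overall F test, R-squared and adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Rows with missing values are deleted
#' listwise before fitting.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix (or data frame) with named columns,
#'   without an intercept column.
#' @param intercept Include an intercept (default `TRUE`).
#' @param outcome Label for the response.
#' @return An object of class `collateral_ols`.
#' @export
fit_ols <- function(y, X, intercept = TRUE, outcome = "y") {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || any(!nzchar(colnames(X)))) {
    stop("design matrix must have named columns", call. = FALSE)
  }
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + intercept) {
    stop("insufficient observations: n = ", n, " for ", p, " predictors", call. = FALSE)
  }
  Xf <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrx$pivot[(qrx$rank + 1L):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    if (!intercept) "- 1" else ""))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  ct <- sm$coefficients
  keep <- rownames(ct) != "(Intercept)"
  sdy <- stats::sd(y)
  sdx <- apply(X, 2, stats::sd)
  coefs <- data.frame(
    predictor = gsub("`", "", rownames(ct)[keep]),
    estimate = ct[keep, 1], se = ct[keep, 2],
    t = ct[keep, 3], p_value = ct[keep, 4],
    beta = ct[keep, 1] * sdx[gsub("`", "", rownames(ct)[keep])] / sdy,
    row.names = NULL
  )
  fstat <- sm$fstatistic
  structure(list(
    outcome = outcome,
    coefficients = coefs,
    intercept = if (intercept) unname(ct["(Intercept)", 1]) else NA_real_,
    intercept_se = if (intercept) unname(ct["(Intercept)", 2]) else NA_real_,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1]),
    f_df = unname(fstat[2:3]),
    f_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    sigma = sm$sigma,
    n_used = n,
    lm_fit = fit
  ), class = "collateral_ols")
}

#' @export
print.collateral_ols <- function(x, digits = 3, ...) {
  cat("Linear outcome model:", x$outcome, sprintf("(n = %d)\n", x$n_used))
  cf <- x$coefficients
  cf[-1] <- lapply(cf[-1], function(z) round(z, digits))
  print.data.frame(cf, row.names = FALSE)
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g, R2 = %.3f, adj R2 = %.3f\n",
              x$f_df[1], x$f_df[2], x$f_statistic, x$f_p,
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' @export
coef.collateral_ols <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$predictor)
}

#' @export
summary.collateral_ols <- function(object, ...) object

#' @export
predict.collateral_ols <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::predict(object$lm_fit))
  stats::predict(object$lm_fit, newdata = as.data.frame(newdata), ...)
}

#' @export
residuals.collateral_ols <- function(object, ...) stats::residuals(object$lm_fit)

#' MANOVA over the outcome set
#'
#' Fits the multivariate linear model `Y ~ X` and reports, per predictor,
#' Pillai's trace with its approximate F and p (type-III tests via
#' [car::Manova()]), plus the overall all-predictors test from the
#' comparison against the intercept-only model. With a single outcome column
#' the overall Pillai F reduces exactly to the OLS overall F.
#'
#' @param Y Numeric outcome matrix with named columns (e.g. transformed FIV,
#'   NIHSS, mRS at discharge).
#' @param X Numeric design matrix with named columns.
#' @return An object of class `collateral_manova` with a `terms` data frame
#'   (predictor, pillai, approx_f, df1, df2, p_value) and `overall` list.
#' @export
fit_manova <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (is.null(colnames(X)) || any(!nzchar(colnames(X)))) {
    stop("design matrix must have named columns", call. = FALSE)
  }
  ok <- stats::complete.cases(Y, X)
  Y <- Y[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  n <- nrow(Y)
  if (n <= ncol(X) + ncol(Y)) stop("insufficient observations for MANOVA", call. = FALSE)
  df <- data.frame(X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "Y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  env <- new.env(parent = environment())
  assign("Y", Y, envir = env)
  environment(fml) <- env
  fit <- stats::lm(fml, data = df)
  res_rank <- qr(stats::residuals(fit))$rank
  if (res_rank < ncol(Y)) {
    stop("singular residual covariance: outcome columns are linearly dependent",
         call. = FALSE)
  }
  if (ncol(Y) == 1L) {
    # exact single-DV reduction: Pillai F per term is the squared t test,
    # the overall Pillai F is the OLS overall F
    ols <- fit_ols(Y[, 1], X, outcome = colnames(Y))
    df2 <- ols$n_used - ncol(X) - 1L
    f_t <- ols$coefficients$t^2
    terms <- data.frame(
      predictor = ols$coefficients$predictor,
      pillai = f_t / (f_t + df2), approx_f = f_t, df1 = 1, df2 = df2,
      p_value = ols$coefficients$p_value, row.names = NULL)
    f_all <- ols$f_statistic
    overall <- list(
      pillai = f_all * ols$f_df[1] / (f_all * ols$f_df[1] + ols$f_df[2]),
      approx_f = unname(f_all), df1 = unname(ols$f_df[1]),
      df2 = unname(ols$f_df[2]), p_value = unname(ols$f_p))
    return(structure(list(outcomes = colnames(Y), terms = terms,
                          overall = overall, n_used = n),
                     class = "collateral_manova"))
  }
  mv <- car::Manova(fit, type = "III", test.statistic = "Pillai")
  sm <- summary(mv, multivariate = TRUE)$multivariate.tests
  terms <- do.call(rbind, lapply(names(sm), function(nm) {
    if (nm == "(Intercept)") return(NULL)
    tt <- sm[[nm]]
    # Pillai trace and F approximation from the hypothesis/error SSP pair
    st <- pillai_from_ssp(tt$SSPH, tt$SSPE, tt$df, tt$df.residual)
    data.frame(predictor = gsub("`", "", nm), pillai = st$pillai,
               approx_f = st$f, df1 = st$df1, df2 = st$df2,
               p_value = st$p, row.names = NULL)
  }))
  fit0 <- stats::lm(Y ~ 1)
  an <- stats::anova(fit0, fit, test = "Pillai")
  overall <- list(pillai = an$Pillai[2], approx_f = an$`approx F`[2],
                  df1 = an$`num Df`[2], df2 = an$`den Df`[2],
                  p_value = an$`Pr(>F)`[2])
  structure(list(outcomes = colnames(Y), terms = terms, overall = overall,
                 n_used = n), class = "collateral_manova")
}

# Pillai's trace and its standard F approximation for a hypothesis/error
# sum-of-squares-and-products pair.
pillai_from_ssp <- function(H, E, q, df_res) {
  ev <- Re(eigen(solve(E + H) %*% H, only.values = TRUE)$values)
  pillai <- sum(ev)
  p <- nrow(as.matrix(H))
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (df_res - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  f <- (pillai / (s - pillai)) * (df2 / df1)
  list(pillai = pillai, f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' @export
print.collateral_manova <- function(x, digits = 3, ...) {
  cat("MANOVA (Pillai) over outcomes:", paste(x$outcomes, collapse = ", "),
      sprintf("(n = %d)\n", x$n_used))
  tt <- x$terms
  tt[-1] <- lapply(tt[-1], function(z) round(z, digits))
  print.data.frame(tt, row.names = FALSE)
  cat(sprintf("Overall: Pillai = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
              x$overall$pillai, x$overall$df1, x$overall$df2,
              x$overall$approx_f, x$overall$p_value))
  invisible(x)
}

# ---- design matrix ----------------------------------------------------------

#' Outcome-model design matrix
#'
#' Builds the 12-column predictor matrix used by the outcome models:
#' whole-brain score, pial-only score, atherosclerosis, elevated glucose,
#' statin, smoking, infection, age, male sex, and three treatment dummies
#' (IV thrombolysis, IA thrombolysis/bridging, thrombectomy; no intervention
#' is the reference). Rows with any missing model variable are deleted
#' listwise.
#'
#' @param patients Data frame of analysis-set patient records.
#' @param outcomes Outcome columns to carry along (listwise-deleted with the
#'   predictors).
#' @param fiv_transform `"log1p"` (default) or `"raw"`: how FIV enters the
#'   outcome block.
#' @return List with `X` (design matrix), `Y` (outcome matrix), `n_used`,
#'   and `dropped` (number of incomplete rows removed).
#' @export
build_design <- function(patients,
                         outcomes = c("fiv", "nihss_discharge", "mrs_discharge"),
                         fiv_transform = c("log1p", "raw")) {
  fiv_transform <- match.arg(fiv_transform)
  need <- c("whole_brain_score", "pial_only_score", "atherosclerosis",
            "glucose_elevated", "statin", "smoking", "infection", "age",
            "male", "treatment", outcomes)
  miss <- setdiff(need, names(patients))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  X <- cbind(
    whole_brain_score = as.numeric(patients$whole_brain_score),
    pial_only_score = as.numeric(patients$pial_only_score),
    atherosclerosis = as.numeric(patients$atherosclerosis),
    glucose_elevated = as.numeric(patients$glucose_elevated),
    statin = as.numeric(patients$statin),
    smoking = as.numeric(patients$smoking),
    infection = as.numeric(patients$infection),
    age = as.numeric(patients$age),
    male = as.numeric(patients$male),
    treat_iv = as.numeric(patients$treatment == "iv"),
    treat_ia = as.numeric(patients$treatment == "ia"),
    treat_thrombectomy = as.numeric(patients$treatment == "thrombectomy")
  )
  X[is.na(patients$treatment), c("treat_iv", "treat_ia", "treat_thrombectomy")] <- NA
  Y <- sapply(outcomes, function(oc) as.numeric(patients[[oc]]))
  Y <- matrix(Y, ncol = length(outcomes), dimnames = list(NULL, outcomes))
  if ("fiv" %in% colnames(Y) && fiv_transform == "log1p") {
    Y[, "fiv"] <- log1p(Y[, "fiv"])
    colnames(Y)[colnames(Y) == "fiv"] <- "log1p_fiv"
  }
  ok <- stats::complete.cases(X, Y)
  list(X = X[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE],
       n_used = sum(ok), dropped = sum(!ok))
}

# ---- subgroups --------------------------------------------------------------

#' Subgroup specification
#'
#' Defines a cohort subgroup by vascular territory, FIV band and/or minimum
#' NIHSS, with a minimum-n guard below which downstream models are skipped
#' and reported as not analyzable rather than fitted.
#'
#' @param name Subgroup label.
#' @param territory Territory to keep (e.g. `"MCA"`), or `NULL` for all.
#' @param fiv_range Numeric `c(lo, hi)` band on FIV in ml (inclusive lo,
#'   exclusive hi; use `Inf`), or `NULL`.
#' @param nihss_min Keep records with discharge NIHSS strictly above this, or
#'   `NULL`.
#' @param min_n Minimum analyzable size (must be at least the number of model
#'   predictors + 2; default 30).
#' @return A `subgroup_spec` object.
#' @export
subgroup_spec <- function(name, territory = NULL, fiv_range = NULL,
                          nihss_min = NULL, min_n = 30L) {
  if (!is.null(fiv_range)) {
    stopifnot(length(fiv_range) == 2L, fiv_range[1] < fiv_range[2])
  }
  if (min_n < 14L) stop("min_n must be at least predictors + 2 (14)", call. = FALSE)
  structure(list(name = name, territory = territory, fiv_range = fiv_range,
                 nihss_min = nihss_min, min_n = as.integer(min_n)),
            class = "subgroup_spec")
}

#' Default subgroup set
#'
#' All patients, MCA-territory strokes only, medium-volume strokes
#' (FIV 15-100 ml), and the malignant profile (FIV > 100 ml or discharge
#' NIHSS > 17), the latter typically reported as not analyzable at realistic
#' cohort sizes.
#'
#' @return List of [subgroup_spec()] objects.
#' @export
default_subgroups <- function() {
  list(
    subgroup_spec("all_patients"),
    subgroup_spec("mca_only", territory = "MCA"),
    subgroup_spec("medium_fiv", fiv_range = c(15, 100)),
    subgroup_spec("malignant", fiv_range = c(100, Inf))
  )
}

#' Filter a cohort by a subgroup specification
#'
#' @param cohort A `cohort` object (analysis set).
#' @param spec A [subgroup_spec()].
#' @return The filtered `cohort` with attributes `subgroup` (the spec name)
#'   and `analyzable` (`FALSE` when fewer than `min_n` records remain, in
#'   which case downstream fits should be skipped and reported as such).
#' @export
subgroup_filter <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "subgroup_spec"))
  p <- cohort$patients
  keep <- rep(TRUE, nrow(p))
  if (!is.null(spec$territory)) keep <- keep & p$territory %in% spec$territory
  if (!is.null(spec$fiv_range)) {
    keep <- keep & !is.na(p$fiv) &
      p$fiv >= spec$fiv_range[1] & p$fiv < spec$fiv_range[2]
  }
  if (!is.null(spec$nihss_min)) {
    keep <- keep & !is.na(p$nihss_discharge) & p$nihss_discharge > spec$nihss_min
  }
  out <- cohort
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  ids <- out$patients$patient_id
  out$vasculature <- cohort$vasculature[cohort$vasculature$patient_id %in% ids, , drop = FALSE]
  out$pial <- cohort$pial[cohort$pial$patient_id %in% ids, , drop = FALSE]
  attr(out, "subgroup") <- spec$name
  attr(out, "analyzable") <- nrow(out$patients) >= spec$min_n
  out
}
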