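# Univariate association screen: Pearson's r for continuous predictors,
# chi-squared / Cramer's V for categorical ones, against each outcome.

association_result <- function(predictor, outcome, kind, effect, statistic,
                               df, p, n) {
  structure(data.frame(
    predictor = predictor, outcome = outcome, kind = kind,
    effect_size = effect, statistic = statistic, df = df,
    p_value = p, n_used = n, stringsAsFactors = FALSE
  ), class = c("association", "data.frame"))
}

#' Pearson correlation association
#'
#' Sample Pearson correlation with its t test (`n - 2` df, two-sided), after
#' pairwise deletion of incomplete pairs.
#'
#' @param x,y Numeric vectors of equal length.
#' @param predictor,outcome Labels carried into the result row.
#' @return A one-row `association` data frame with columns `predictor`,
#'   `outcome`, `kind`, `effect_size`, `statistic`, `df`, `p_value`, `n_used`.
#' @export
pearson_r <- function(x, y, predictor = "x", outcome = "y") {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n, call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in ",
         if (stats::sd(x) == 0) predictor else outcome, call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  association_result(predictor, outcome, "pearson_r",
                     unname(ct$estimate), unname(ct$statistic),
                     unname(ct$parameter), ct$p.value, n)
}

#' Cramer's V association for a contingency table
#'
#' Pearson chi-squared statistic without continuity correction,
#' `df = (r - 1)(c - 1)`, and `V = sqrt(chi2 / (n * (min(r, c) - 1)))`.
#'
#' @param tab A 2-D table/matrix of non-negative counts with at least two
#'   rows and two columns and no all-zero margin.
#' @param predictor,outcome Labels carried into the result row.
#' @return A one-row `association` data frame (see [pearson_r()]).
#' @export
cramers_v <- function(tab, predictor = "rows", outcome = "cols") {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!is.finite(tab))) {
    stop("contingency table must hold finite non-negative counts", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("Cramer's V undefined for a 1 x k table", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has an all-zero margin", call. = FALSE)
  }
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(chi$statistic) / (n * (min(dim(tab)) - 1)))
  association_result(predictor, outcome, "cramers_v",
                     v, unname(chi$statistic), unname(chi$parameter),
                     chi$p.value, n)
}

# quartile binning for categorical-vs-continuous associations; collapses tied
# quantile breaks, so heavily discrete outcomes may yield fewer than `bins`
# levels.
bin_quantiles <- function(x, bins = 4L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               na.rm = TRUE, names = FALSE))
  if (length(br) < 3L) {
    stop("cannot form at least two bins: outcome nearly constant", call. = FALSE)
  }
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Univariate association screen
#'
#' Routes each declared-continuous predictor to [pearson_r()] and each
#' categorical predictor to a chi-squared / Cramer's V test against every
#' outcome. For a categorical predictor against a continuous outcome the
#' outcome is binned into quartiles (collapsing tied breaks) before
#' tabulation. Missing values are deleted pairwise per association. No
#' multiple-testing adjustment is applied; raw p-values are reported.
#'
#' @param data Data frame (typically `cohort$patients` of an analysis set).
#' @param outcomes Character vector of outcome column names.
#' @param predictors Named character vector: names are predictor columns,
#'   values are `"continuous"` or `"categorical"`.
#' @param bins Number of quantile bins for the categorical path (default 4).
#' @return An `association_screen` data frame, one row per predictor x
#'   outcome pair.
#' @export
univariate_screen <- function(data, outcomes, predictors, bins = 4L) {
  stopifnot(is.data.frame(data))
  if (!length(predictors)) {
    out <- association_result(character(0), character(0), character(0),
                              numeric(0), numeric(0), numeric(0),
                              numeric(0), integer(0))
    class(out) <- c("association_screen", "data.frame")
    return(out)
  }
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stop("predictors must be a named vector of types", call. = FALSE)
  }
  bad_type <- setdiff(unname(predictors), c("continuous", "categorical"))
  if (length(bad_type)) {
    stop("unknown predictor type(s): ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(c(names(predictors), outcomes), names(data))
  if (length(absent)) {
    stop("columns not in data: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (oc in outcomes) {
    for (pr in names(predictors)) {
      if (pr == oc) next
      ok <- stats::complete.cases(data[[pr]], data[[oc]])
      x <- data[[pr]][ok]; y <- data[[oc]][ok]
      res <- if (predictors[[pr]] == "continuous") {
        pearson_r(as.numeric(x), as.numeric(y), predictor = pr, outcome = oc)
      } else {
        tab <- table(x, bin_quantiles(as.numeric(y), bins))
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        cramers_v(tab, predictor = pr, outcome = oc)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("association_screen", "data.frame")
  rownames(out) <- NULL
  out
}

#' Default predictor typing for the screen
#'
#' The screen's standard predictor set: binary risk factors, sex and
#' treatment as categorical; age, the collateral scores and baseline NIHSS
#' as continuous.
#'
#' @return Named character vector suitable for [univariate_screen()].
#' @export
default_screen_predictors <- function() {
  c(atherosclerosis = "categorical", infection = "categorical",
    glucose_elevated = "categorical", statin = "categorical",
    male = "categorical", smoking = "categorical",
    treatment = "categorical",
    age = "continuous", whole_brain_score = "continuous",
    pial_only_score = "continuous", nihss_admission = "continuous")
}

#' @export
print.association_screen <- function(x, digits = 3, ...) {
  cat("Univariate association screen (", nrow(x), " tests)\n", sep = "")
  df <- as.data.frame(x)
  df$effect_size <- round(df$effect_size, digits)
  df$p_value <- signif(df$p_value, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
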