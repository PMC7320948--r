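# Orchestration: simulate -> score -> screen -> model -> report.

COHORT_COLUMNS <- c(
  "patient_id", "exclusion", "tia", "age", "male", "atherosclerosis",
  "smoking", "glucose_elevated", "infection", "statin", "treatment",
  "territory", "onset_known", "pial_cortical_count", "pial_cerebellar_count",
  "whole_brain_score", "pial_only_score", "fiv", "nihss_admission",
  "nihss_discharge", "mrs_admission", "mrs_discharge"
)

#' Run configuration
#'
#' Bundles either a generator configuration or a path to an existing cohort
#' CSV (exactly one of the two) with the subgroup set, model options and
#' seed for a full pipeline run.
#'
#' @param generator A [generator_config()], or `NULL` when reading a cohort.
#' @param cohort_path Path to a cohort CSV written by [write_cohort_csv()],
#'   or `NULL` when simulating.
#' @param subgroups List of [subgroup_spec()]s.
#' @param fiv_transform `"log1p"` or `"raw"` for the FIV outcome.
#' @param alpha Significance threshold used for marking report cells.
#' @param seed Integer seed (required).
#' @return A `run_config` object.
#' @export
run_config <- function(generator = generator_config(), cohort_path = NULL,
                       subgroups = default_subgroups(),
                       fiv_transform = "log1p", alpha = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (is.null(generator) == is.null(cohort_path)) {
    stop("exactly one of generator / cohort_path must be given", call. = FALSE)
  }
  structure(list(generator = generator, cohort_path = cohort_path,
                 subgroups = subgroups, fiv_transform = fiv_transform,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) an admission cohort, applies the exclusion stage,
#' then for every configured subgroup runs the univariate screen and the
#' three outcome regressions plus the MANOVA, recording per-stage record
#' counts. Subgroups below their minimum-n guard are reported as not
#' analyzable instead of fitted. Deterministic given `(config, seed)`.
#'
#' @param config A [run_config()].
#' @return An `analysis_report` object.
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(seed = 1))
#' rep$n_analysis
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed [config %s]: %s",
                   what, substr(report_hash(config), 1, 8),
                   conditionMessage(e)), call. = FALSE)
    })
  }
  admissions <- stage("simulate", {
    if (!is.null(config$cohort_path)) {
      read_cohort_csv(config$cohort_path, seed = config$seed)
    } else {
      generate_admissions(config$generator, seed = config$seed)
    }
  })
  analysis <- stage("exclusions", apply_exclusions(admissions))
  excl <- attr(analysis, "exclusions")

  outcomes <- c("fiv", "nihss_discharge", "mrs_discharge")
  preds <- default_screen_predictors()
  subgroup_results <- list()
  for (spec in config$subgroups) {
    sub <- stage(paste0("subgroup:", spec$name), subgroup_filter(analysis, spec))
    n_sub <- nrow(sub$patients)
    if (!attr(sub, "analyzable")) {
      subgroup_results[[spec$name]] <- list(
        name = spec$name, n = n_sub, analyzable = FALSE,
        skip_reason = sprintf("not analyzable (n too small: %d < %d)",
                              n_sub, spec$min_n))
      next
    }
    screen <- stage(paste0("screen:", spec$name),
                    univariate_screen(sub$patients, outcomes, preds))
    d <- stage(paste0("design:", spec$name),
               build_design(sub$patients, outcomes,
                            fiv_transform = config$fiv_transform))
    fits <- lapply(colnames(d$Y), function(oc) {
      stage(paste0("ols:", spec$name, ":", oc),
            fit_ols(d$Y[, oc], d$X, outcome = oc))
    })
    names(fits) <- colnames(d$Y)
    manova <- stage(paste0("manova:", spec$name), fit_manova(d$Y, d$X))
    subgroup_results[[spec$name]] <- list(
      name = spec$name, n = n_sub, analyzable = TRUE, n_model = d$n_used,
      screen = screen, regressions = fits, manova = manova)
  }

  structure(list(
    n_admissions = nrow(admissions$patients),
    n_excluded = sum(excl), exclusions = excl,
    n_analysis = nrow(analysis$patients),
    cohort_summary = summarize_cohort(analysis$patients),
    subgroups = subgroup_results,
    alpha = config$alpha,
    provenance = list(seed = config$seed,
                      config_hash = report_hash(config),
                      package_version = as.character(utils::packageVersion("collaterals")))
  ), class = "analysis_report")
}

report_hash <- function(config) {
  cfg <- rapply(unclass(config), unclass, how = "replace")
  config_hash(cfg)
}

summarize_cohort <- function(p) {
  list(
    n = nrow(p),
    age_mean = mean(p$age), age_sd = stats::sd(p$age),
    male_frac = mean(p$male),
    prevalence = c(atherosclerosis = mean(p$atherosclerosis),
                   smoking = mean(p$smoking),
                   glucose_elevated = mean(p$glucose_elevated),
                   infection = mean(p$infection), statin = mean(p$statin)),
    treatment = as.list(prop.table(table(p$treatment))),
    fiv_median = stats::median(p$fiv, na.rm = TRUE),
    fiv_under_15 = mean(p$fiv < 15, na.rm = TRUE),
    fiv_over_100 = mean(p$fiv > 100, na.rm = TRUE),
    nihss_discharge_median = stats::median(p$nihss_discharge, na.rm = TRUE),
    mrs_discharge_median = stats::median(p$mrs_discharge, na.rm = TRUE),
    score_mean = mean(p$whole_brain_score), score_sd = stats::sd(p$whole_brain_score)
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Collateral analysis report\n")
  cat(sprintf("  admissions %d -> excluded %d (quality %d, alternative diagnosis %d) -> analysis %d\n",
              x$n_admissions, x$n_excluded,
              x$exclusions[["data_quality"]],
              x$exclusions[["alternative_diagnosis"]], x$n_analysis))
  for (sg in x$subgroups) {
    if (!sg$analyzable) {
      cat(sprintf("  subgroup %-12s n = %4d  %s\n", sg$name, sg$n, sg$skip_reason))
    } else {
      r2 <- vapply(sg$regressions, function(f) f$adj_r_squared, numeric(1))
      cat(sprintf("  subgroup %-12s n = %4d  adj R2: %s\n", sg$name, sg$n,
                  paste(sprintf("%s=%.3f", names(r2), r2), collapse = " ")))
    }
  }
  invisible(x)
}

# ---- cohort CSV I/O ---------------------------------------------------------

#' Read / write a cohort CSV
#'
#' One row per patient with a fixed column dictionary (patient identifier,
#' exclusion flag, demographics, risk factors, treatment, territory, pial
#' counts, scores and outcomes); the vasculature grade sheet travels in
#' the companion long-format CSV (see [write_vasculature_csv()]), written as
#' `<path minus .csv>_vasculature.csv` / `..._pial.csv`, and provenance
#' (seed, config hash) in a JSON sidecar `<path>.provenance.json`.
#' Writing then reading reproduces the table, including types and missing
#' values.
#'
#' @param cohort A `cohort` object.
#' @param path CSV path.
#' @param seed Seed to record when the sidecar is absent on read.
#' @return `read_cohort_csv()` returns a `cohort`; the writer returns `path`
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$patients[, COHORT_COLUMNS], path, row.names = FALSE)
  stem <- sub("\\.csv$", "", path)
  write_vasculature_csv(cohort$vasculature, cohort$pial,
                        paste0(stem, "_vasculature"))
  writeLines(jsonlite::toJSON(
    list(seed = cohort$seed, config_hash = cohort$config_hash),
    auto_unbox = TRUE), paste0(path, ".provenance.json"))
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, seed = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLUMNS, names(p))
  if (length(miss)) {
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(p), COHORT_COLUMNS)
  if (length(extra)) {
    stop("cohort CSV has unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("age", "pial_cortical_count", "pial_cerebellar_count",
                "whole_brain_score", "pial_only_score", "fiv",
                "nihss_admission", "nihss_discharge", "mrs_admission",
                "mrs_discharge")
  for (nm in num_cols) {
    if (is.logical(p[[nm]]) && all(is.na(p[[nm]]))) {
      p[[nm]] <- as.numeric(p[[nm]]) # all-missing column read as logical
    } else if (!is.numeric(p[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(p[[nm]]))) & !is.na(p[[nm]]))
      stop(sprintf("non-numeric value in numeric column '%s' (row %s)",
                   nm, paste(utils::head(bad, 3), collapse = ", ")), call. = FALSE)
    }
  }
  for (nm in c("tia", "male", "atherosclerosis", "smoking", "glucose_elevated",
               "infection", "statin", "onset_known")) {
    p[[nm]] <- as.logical(p[[nm]])
  }
  stem <- sub("\\.csv$", "", path)
  vpath <- paste0(stem, "_vasculature")
  vasc <- if (file.exists(paste0(vpath, ".csv"))) {
    read_vasculature_csv(vpath)
  } else {
    list(grades = data.frame(patient_id = character(0), vessel = character(0),
                             side = character(0), grade = integer(0)),
         pial = p[, c("patient_id", "pial_cortical_count", "pial_cerebellar_count")])
  }
  prov_path <- paste0(path, ".provenance.json")
  hash <- NA_character_
  if (file.exists(prov_path)) {
    prov <- jsonlite::fromJSON(prov_path)
    seed <- prov$seed
    hash <- prov$config_hash
  }
  structure(list(patients = p, vasculature = vasc$grades, pial = vasc$pial,
                 seed = as.integer(seed), config_hash = hash, config = NULL),
            class = "cohort")
}

# ---- report rendering -------------------------------------------------------

#' Render an analysis report
#'
#' Serialises the report to stable, diffable files: `report.json` (full
#' precision) and/or `report.md` (values rounded to 3 decimals; p-values
#' below the configured alpha are bolded, skipped subgroups rendered with
#' `na` entries).
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("json", "markdown")`.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("json", "markdown")) {
  stopifnot(inherits(report, "analysis_report"))
  bad <- setdiff(format, c("json", "markdown"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    writeLines(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE, na = "null"), path)
    out <- c(out, path)
  }
  if ("markdown" %in% format) {
    path <- file.path(dir, "report.md")
    writeLines(report_to_markdown(report), path)
    out <- c(out, path)
  }
  invisible(out)
}

report_to_list <- function(report) {
  sg <- lapply(report$subgroups, function(s) {
    if (!s$analyzable) {
      return(list(name = s$name, n = s$n, analyzable = FALSE,
                  skip_reason = s$skip_reason))
    }
    list(
      name = s$name, n = s$n, analyzable = TRUE, n_model = s$n_model,
      univariate = as.data.frame(s$screen),
      regressions = lapply(s$regressions, function(f) {
        list(outcome = f$outcome, coefficients = f$coefficients,
             f_statistic = f$f_statistic, f_df = f$f_df, f_p = unname(f$f_p),
             r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
             n_used = f$n_used)
      }),
      manova = list(terms = s$manova$terms, overall = s$manova$overall,
                    n_used = s$manova$n_used)
    )
  })
  list(
    n_admissions = report$n_admissions, n_excluded = report$n_excluded,
    exclusions = as.list(report$exclusions), n_analysis = report$n_analysis,
    cohort_summary = report$cohort_summary, subgroups = sg,
    alpha = report$alpha, provenance = report$provenance
  )
}

fmt3 <- function(x) vapply(x, function(z) {
  if (is.na(z)) "na" else format(round(z, 3), trim = TRUE, scientific = FALSE)
}, character(1))
fmt_p <- function(p, alpha) {
  s <- ifelse(!is.na(p) & p < 0.001, "< 0.001", fmt3(p))
  ifelse(!is.na(p) & p < alpha, paste0("**", s, "**"), s)
}

report_to_markdown <- function(report) {
  a <- report$alpha
  lines <- c(
    "# Collateral vessel analysis report", "",
    sprintf("Admissions: %d; excluded: %d (data quality %d, alternative diagnosis %d); analysis set: %d.",
            report$n_admissions, report$n_excluded,
            report$exclusions[["data_quality"]],
            report$exclusions[["alternative_diagnosis"]], report$n_analysis),
    sprintf("Seed %d, config %s.", report$provenance$seed,
            substr(report$provenance$config_hash, 1, 8)), "")
  for (s in report$subgroups) {
    lines <- c(lines, sprintf("## Subgroup: %s (n = %d)", s$name, s$n), "")
    if (!s$analyzable) {
      lines <- c(lines, s$skip_reason, "",
                 "| outcome | F | df | p | adj R2 |",
                 "|---|---|---|---|---|",
                 "| all | na | na | na | na |", "")
      next
    }
    u <- s$screen
    lines <- c(lines, "### Univariate screen", "",
               "| predictor | outcome | statistic | effect size | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s |",
                       u$predictor, u$outcome, u$kind,
                       fmt3(u$effect_size), fmt_p(u$p_value, a)), "")
    for (f in s$regressions) {
      cf <- f$coefficients
      lines <- c(lines, sprintf("### Linear model: %s (n = %d)", f$outcome, f$n_used), "",
                 "| predictor | t | p | beta |", "|---|---|---|---|",
                 sprintf("| %s | %s | %s | %s |", cf$predictor, fmt3(cf$t),
                         fmt_p(cf$p_value, a), fmt3(cf$beta)),
                 sprintf("| Overall model | F(%d, %d) = %s | %s | adj R2 = %s |",
                         f$f_df[1], f$f_df[2], fmt3(f$f_statistic),
                         fmt_p(unname(f$f_p), a), fmt3(f$adj_r_squared)), "")
    }
    mv <- s$manova$terms
    lines <- c(lines, sprintf("### MANOVA (Pillai), outcomes: %s",
                              paste(s$manova$outcomes %||% "", collapse = ", ")), "",
               "| predictor | Pillai | approx F | df | p |", "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %d, %d | %s |", mv$predictor,
                       fmt3(mv$pillai), fmt3(mv$approx_f), mv$df1, mv$df2,
                       fmt_p(mv$p_value, a)), "")
  }
  lines
}

`%||%` <- function(x, y) if (is.null(x)) y else x
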