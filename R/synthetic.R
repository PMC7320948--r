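# Synthetic stroke-admission cohort generator.
#
# Generative chain: covariates -> latent atherosclerotic burden -> vasculature
# grades -> whole-brain score -> latent severity -> treatment -> outcomes.
# Effects on outcomes are planted directly on the (standardised) whole-brain
# score and on named covariates so that parameter recovery is well-posed.

#' Generator configuration
#'
#' Builds a validated configuration for [generate_admissions()]. Defaults
#' emulate a consecutive emergency-department stroke admission cohort:
#' 686 admissions of which 69 are excluded for data quality and 87 for an
#' alternative diagnosis (analysis set 530); age truncated-normal mean 65.7,
#' SD 15, range 19-90; 60.9% male; risk-factor prevalences (atherosclerosis
#' 33%, smoking 39.1%, elevated admission glucose 5.3%, infection 2.5%,
#' statin 25%); treatment mix IV thrombolysis / IA thrombolysis (bridging) /
#' mechanical thrombectomy / none in proportions 0.322 / 0.06 / 0.02 / 0.551
#' renormalised to sum to one; 17.2% later reclassified as TIA; heavily
#' right-skewed FIV calibrated so that about 66% of analysis records fall
#' below 15 ml and about 13% above 100 ml.
#'
#' The `effects` block holds the planted standardized coefficients linking
#' the whole-brain score (entered as `z = (score - score_center)/score_scale`),
#' atherosclerosis, glucose, age and treatment to `log1p(FIV)` and to the
#' latent severity behind NIHSS/mRS, plus residual SDs. Set
#' `effects = null_effects()` for a zero-effect (pure noise) cohort.
#'
#' @param n_admissions Number of admission records.
#' @param n_excluded_quality,n_excluded_diagnosis Exclusion counts.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param p_male Male fraction.
#' @param prevalence Named list of binary risk-factor prevalences.
#' @param p_treatment Named numeric (iv, ia, thrombectomy, none); must sum
#'   to 1 within 1e-9.
#' @param p_territory Named numeric of territory proportions.
#' @param p_tia Fraction later reclassified as TIA (FIV point mass at 0).
#' @param p_onset_known Fraction with a determinable symptom onset time.
#' @param treatment_confounding SD of the independent jitter added to latent
#'   severity when rank-allocating treatments; larger = weaker confounding.
#' @param effects Planted effect block, see [default_effects()].
#' @param score_center,score_scale Standardisation constants for the
#'   whole-brain score, frozen from the default burden->vasculature chain.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    n_admissions = 686L,
    n_excluded_quality = 69L,
    n_excluded_diagnosis = 87L,
    age_mean = 65.7, age_sd = 15.0, age_range = c(19, 90),
    p_male = 0.609,
    prevalence = list(atherosclerosis = 0.33, smoking = 0.391,
                      glucose = 0.053, infection = 0.025, statin = 0.25),
    p_treatment = c(iv = 0.322, ia = 0.06, thrombectomy = 0.02, none = 0.551) / 0.953,
    p_territory = c(MCA = 0.60, PCA = 0.12, ACA = 0.05,
                    vertebrobasilar = 0.13, other = 0.10),
    p_tia = 91 / 530,
    p_onset_known = 1 - 0.164,
    treatment_confounding = 2.0,
    effects = default_effects(),
    score_center = 17.64, score_scale = 27.17) {
  cfg <- list(
    n_admissions = as.integer(n_admissions),
    n_excluded_quality = as.integer(n_excluded_quality),
    n_excluded_diagnosis = as.integer(n_excluded_diagnosis),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_male = p_male, prevalence = prevalence,
    p_treatment = p_treatment, p_territory = p_territory,
    p_tia = p_tia, p_onset_known = p_onset_known,
    treatment_confounding = treatment_confounding,
    effects = effects,
    score_center = score_center, score_scale = score_scale
  )
  validate_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

#' Default planted effect block
#'
#' Coefficients act on: `z(score)` (standardised whole-brain score, higher =
#' better collaterals), binary atherosclerosis/glucose indicators,
#' standardised age, and treatment offsets (reference: no intervention).
#' `fiv` acts on the `log1p(FIV)` scale; `nihss`/`mrs` act on unit-variance
#' latent severities that are monotonely binned into their integer ranges.
#' A shared severity noise term (`shared_sd`) induces the inter-outcome
#' correlations seen in real discharge data (~0.5-0.65).
#'
#' @return A list with components `fiv`, `nihss`, `mrs` and `shared_sd`.
#' @export
default_effects <- function() {
  list(
    shared_sd = 1.0,
    fiv = list(intercept = 2.24, score = -0.55, athero = 0.4, glucose = 0.5,
               treatment = c(iv = 0.4, ia = 1.2, thrombectomy = 1.0),
               shared = 0.55, resid_sd = 0.48),
    nihss = list(score = -0.5, athero = 0.3, glucose = 0.3, age = 0.15,
                 shared = 0.9, resid_sd = 0.6,
                 scale = 0.75, shift_discharge = 0.7, shift_admission = 1.95),
    mrs = list(score = -0.55, athero = 0.35, glucose = 0.4, age = 0.35,
               shared = 0.9, resid_sd = 0.5,
               thresholds = c(-1.2, -0.5, 0.2, 0.9, 1.6, 2.4),
               admission_shift = 0.9),
    severity = list(score = -0.8, athero = 0.4, glucose = 0.4, noise_sd = 0.8)
  )
}

#' @rdname default_effects
#' @export
null_effects <- function() {
  e <- default_effects()
  e$fiv[c("score", "athero", "glucose")] <- list(0, 0, 0)
  e$fiv$treatment[] <- 0
  for (nm in c("nihss", "mrs")) e[[nm]][c("score", "athero", "glucose", "age")] <- list(0, 0, 0, 0)
  e
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_admissions >= 1L)
  n_excl <- cfg$n_excluded_quality + cfg$n_excluded_diagnosis
  if (n_excl > cfg$n_admissions) {
    stop("exclusion counts exceed n_admissions", call. = FALSE)
  }
  probs <- c(cfg$p_male, unlist(cfg$prevalence), cfg$p_treatment,
             cfg$p_territory, cfg$p_tia, cfg$p_onset_known)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$p_treatment) - 1) > 1e-9) {
    stop("treatment probabilities must sum to 1 (got ",
         format(sum(cfg$p_treatment)), ")", call. = FALSE)
  }
  if (abs(sum(cfg$p_territory) - 1) > 1e-9) {
    stop("territory probabilities must sum to 1", call. = FALSE)
  }
  sds <- c(cfg$effects$fiv$resid_sd, cfg$effects$nihss$resid_sd,
           cfg$effects$mrs$resid_sd, cfg$effects$severity$noise_sd)
  if (any(sds <= 0)) stop("residual SDs must be > 0", call. = FALSE)
  stopifnot(cfg$score_scale > 0, cfg$age_sd > 0,
            cfg$age_range[1] < cfg$age_range[2])
  invisible(TRUE)
}

#' Hash of a generator / run configuration
#'
#' MD5 of the canonical JSON serialisation; recorded as provenance in every
#' cohort and report.
#'
#' @param cfg A configuration object (any jsonlite-serialisable list).
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# truncated normal by rejection (bounds are ~3 SD out, acceptance ~90%)
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= lo & x <= hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# ---- vasculature from latent burden -----------------------------------------

# Vectorised: burden in [0,1], length n. Returns list(grades = n x 34 int
# matrix, pial_cortical, pial_cerebellar). Higher burden -> worse grades,
# fewer assessable small vessels, fewer visible pial arteries.
r_vasculature_matrix <- function(burden) {
  stopifnot(all(burden >= 0 & burden <= 1))
  n <- length(burden)
  sch <- slot_schema()
  graded_idx <- which(sch$kind == "graded")
  assess_idx <- which(sch$kind == "assessability")
  m <- matrix(1L, n, nrow(sch))

  ng <- length(graded_idx)
  p_na <- 0.02                       # slot not assessable, burden-independent
  p_deg <- pmin(0.9 * burden, 0.98)  # degraded | assessable
  u <- matrix(stats::runif(n * ng), n, ng)
  na_mask <- matrix(stats::runif(n * ng) < p_na, n, ng)
  deg_mask <- u < p_deg              # column-constant threshold per patient
  # degraded grade: -1,-2,-3,-4 with fixed mixture
  deg_codes <- matrix(sample(c(-1L, -2L, -3L, -4L), n * ng, replace = TRUE,
                             prob = c(0.45, 0.25, 0.18, 0.12)), n, ng)
  gm <- matrix(1L, n, ng)
  gm[deg_mask] <- deg_codes[deg_mask]
  gm[na_mask] <- 0L
  m[, graded_idx] <- gm

  na_ <- length(assess_idx)
  p_assess <- pmin(pmax(0.97 - 0.4 * burden, 0), 1)
  m[, assess_idx] <- matrix(
    as.integer(stats::runif(n * na_) < p_assess), n, na_)

  list(
    grades = m,
    pial_cortical = stats::rpois(n, pmax(12 * (1 - 0.55 * burden), 0.1)),
    pial_cerebellar = stats::rpois(n, pmax(3 * (1 - 0.55 * burden), 0.05))
  )
}

#' Generate one vasculature sheet from a latent burden
#'
#' Draws a complete grading sheet whose expected whole-brain score decreases
#' strictly in the latent atherosclerotic burden: at burden 0 nearly all
#' grades are normal; at burden 1 grades concentrate on stenosis/occlusion
#' codes and pial visibility collapses. Uses the current RNG state.
#'
#' @param burden Latent severity in `[0, 1]`.
#' @return A `vasculature` object.
#' @export
generate_vasculature <- function(burden) {
  if (length(burden) != 1L || is.na(burden) || burden < 0 || burden > 1) {
    stop("burden must be a single value in [0, 1]", call. = FALSE)
  }
  d <- r_vasculature_matrix(burden)
  sch <- slot_schema()
  vasculature(
    data.frame(vessel = sch$vessel, side = sch$side, grade = d$grades[1, ]),
    pial_cortical = d$pial_cortical, pial_cerebellar = d$pial_cerebellar
  )
}

# ---- admissions -------------------------------------------------------------

#' Generate a synthetic admission cohort
#'
#' Draws `n_admissions` records with exclusion flags (exactly the configured
#' per-reason counts, assigned at random), demographics and risk factors from
#' the configured marginals, a complete vasculature sheet per patient driven
#' by a latent burden (itself a logistic function of atherosclerosis, age,
#' smoking and glucose plus noise), severity-tilted treatment allocation at
#' the exact configured counts, and outcomes (FIV in ml, NIHSS and mRS at
#' admission and discharge) from the planted effect block. TIA-flagged
#' records get FIV 0. Fully reproducible given `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; required (no silent nondeterminism).
#' @return An object of class `cohort`: list with `patients` (one row per
#'   admission), `vasculature` (long grade table), `pial` (count table), and
#'   provenance (`seed`, `config_hash`, `config`).
#' @examples
#' co <- generate_admissions(generator_config(n_admissions = 60,
#'   n_excluded_quality = 5, n_excluded_diagnosis = 7), seed = 1)
#' nrow(apply_exclusions(co)$patients)
#' @export
generate_admissions <- function(config = generator_config(), seed) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is required for cohort generation", call. = FALSE)
  }
  validate_config(config)
  set.seed(as.integer(seed))
  n <- config$n_admissions
  eff <- config$effects

  id <- sprintf("P%04d", seq_len(n))
  exclusion <- rep("none", n)
  excl_idx <- sample.int(n, config$n_excluded_quality + config$n_excluded_diagnosis)
  exclusion[excl_idx[seq_len(config$n_excluded_quality)]] <- "data_quality"
  exclusion[excl_idx[-seq_len(config$n_excluded_quality)]] <- "alternative_diagnosis"

  age <- round(rtnorm(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2]), 1)
  z_age <- (age - config$age_mean) / config$age_sd
  male <- stats::runif(n) < config$p_male
  prev <- config$prevalence
  athero <- stats::runif(n) < prev$atherosclerosis
  smoking <- stats::runif(n) < prev$smoking
  glucose <- stats::runif(n) < prev$glucose
  infection <- stats::runif(n) < prev$infection
  statin <- stats::runif(n) < prev$statin
  territory <- sample(names(config$p_territory), n, replace = TRUE,
                      prob = config$p_territory)
  tia <- stats::runif(n) < config$p_tia
  onset_known <- stats::runif(n) < config$p_onset_known

  # latent atherosclerotic burden in (0,1): drives vasculature degradation
  burden <- stats::plogis(-1.6 + 1.2 * athero + 0.5 * z_age + 0.5 * smoking +
                            0.6 * glucose + stats::rnorm(n, 0, 0.8))
  vasc <- r_vasculature_matrix(burden)
  sc <- score_grade_matrix(vasc$grades, vasc$pial_cortical, vasc$pial_cerebellar)
  z_score <- (sc$whole_brain_score - config$score_center) / config$score_scale

  # treatment: exact configured counts, allocated by observable severity +
  # independent jitter (aggressive treatment to the more severe patients)
  sev_t <- eff$severity$score * z_score + eff$severity$athero * athero +
    eff$severity$glucose * glucose +
    stats::rnorm(n, 0, eff$severity$noise_sd) +
    stats::rnorm(n, 0, config$treatment_confounding)
  counts <- round(config$p_treatment * n)
  counts["none"] <- counts["none"] + (n - sum(counts)) # make counts sum to n
  ord <- order(sev_t, decreasing = TRUE)
  treatment <- character(n)
  pos <- 1L
  for (lev in c("thrombectomy", "ia", "iv", "none")) {
    k <- counts[[lev]]
    if (k > 0) treatment[ord[pos:(pos + k - 1L)]] <- lev
    pos <- pos + k
  }
  is_iv <- treatment == "iv"; is_ia <- treatment == "ia"
  is_mt <- treatment == "thrombectomy"

  h <- stats::rnorm(n, 0, eff$shared_sd) # shared severity noise across outcomes

  f <- eff$fiv
  log_fiv <- f$intercept + f$score * z_score + f$athero * athero +
    f$glucose * glucose + f$treatment[["iv"]] * is_iv +
    f$treatment[["ia"]] * is_ia + f$treatment[["thrombectomy"]] * is_mt +
    f$shared * h + stats::rnorm(n, 0, f$resid_sd)
  fiv <- round(expm1(pmax(log_fiv, 0)), 2)
  fiv[tia] <- 0 # transient deficit, no persistent infarct

  ni <- eff$nihss
  lat_n <- ni$score * z_score + ni$athero * athero + ni$glucose * glucose +
    ni$age * z_age + ni$shared * h + stats::rnorm(n, 0, ni$resid_sd)
  nihss_discharge <- pmin(pmax(round(expm1(ni$scale * lat_n + ni$shift_discharge)), 0L), 42L)
  lat_n_adm <- lat_n + stats::rnorm(n, 0, 0.3)
  nihss_admission <- pmin(pmax(round(expm1(ni$scale * lat_n_adm + ni$shift_admission)), 0L), 42L)

  mr <- eff$mrs
  lat_m <- mr$score * z_score + mr$athero * athero + mr$glucose * glucose +
    mr$age * z_age + mr$shared * h + stats::rnorm(n, 0, mr$resid_sd)
  mrs_discharge <- findInterval(lat_m, mr$thresholds)
  lat_m_adm <- lat_m + mr$admission_shift + stats::rnorm(n, 0, 0.3)
  mrs_admission <- findInterval(lat_m_adm, mr$thresholds)

  patients <- data.frame(
    patient_id = id, exclusion = exclusion, tia = tia,
    age = age, male = male,
    atherosclerosis = athero, smoking = smoking, glucose_elevated = glucose,
    infection = infection, statin = statin,
    treatment = treatment, territory = territory, onset_known = onset_known,
    pial_cortical_count = vasc$pial_cortical,
    pial_cerebellar_count = vasc$pial_cerebellar,
    whole_brain_score = sc$whole_brain_score,
    pial_only_score = sc$pial_only_score,
    fiv = fiv,
    nihss_admission = as.integer(nihss_admission),
    nihss_discharge = as.integer(nihss_discharge),
    mrs_admission = as.integer(mrs_admission),
    mrs_discharge = as.integer(mrs_discharge),
    stringsAsFactors = FALSE
  )

  sch <- slot_schema()
  long <- data.frame(
    patient_id = rep(id, each = nrow(sch)),
    vessel = rep(sch$vessel, n),
    side = rep(sch$side, n),
    grade = as.integer(t(vasc$grades)),
    stringsAsFactors = FALSE
  )
  pial <- data.frame(patient_id = id,
                     pial_cortical_count = vasc$pial_cortical,
                     pial_cerebellar_count = vasc$pial_cerebellar)

  structure(list(
    patients = patients, vasculature = long, pial = pial,
    seed = as.integer(seed), config_hash = config_hash(config),
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$patients)
  excl <- table(x$patients$exclusion)
  cat("Synthetic admission cohort:", n, "records\n")
  cat("  exclusion flags:", paste(sprintf("%s=%d", names(excl), excl), collapse = " "), "\n")
  cat("  seed:", x$seed, " config:", substr(x$config_hash, 1, 8), "\n")
  invisible(x)
}

#' Apply exclusion flags
#'
#' Drops records flagged `data_quality` or `alternative_diagnosis`, keeping
#' the admission order, and records the per-reason removal counts in the
#' `exclusions` attribute (also available as `attr(,"exclusions")`).
#'
#' @param cohort A `cohort` object.
#' @return The filtered `cohort`; `attr(result, "exclusions")` is a named
#'   integer vector of removed counts per reason.
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  p <- cohort$patients
  keep <- p$exclusion == "none"
  removed <- table(factor(p$exclusion[!keep],
                          levels = c("data_quality", "alternative_diagnosis")))
  out <- cohort
  out$patients <- p[keep, , drop = FALSE]
  rownames(out$patients) <- NULL
  keep_ids <- out$patients$patient_id
  out$vasculature <- cohort$vasculature[cohort$vasculature$patient_id %in% keep_ids, , drop = FALSE]
  out$pial <- cohort$pial[cohort$pial$patient_id %in% keep_ids, , drop = FALSE]
  rownames(out$vasculature) <- rownames(out$pial) <- NULL
  if (!nrow(out$patients)) warning("no records remain after exclusions")
  attr(out, "exclusions") <- c(removed)
  out
}
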