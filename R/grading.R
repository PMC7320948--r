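# Whole-brain collateral vessel score.
#
# Aggregation rules:
#   * left and right grades of paired vessels are added -> one value per vessel
#   * cerebral artery segments are weighted proximal-to-distal:
#       ACA = 2*A1 + A2,  MCA = 4*M1 + 2*M2 + M3,  PCA = 4*P1 + 2*P2 + P3
#   * the ICA enters as one side-summed factor
#   * assessability-only vessels contribute 1 per assessable side
#   * pial collaterals contribute a cortical (0-2) and a cerebellar (0-2) score
#   * the whole-brain score is the unweighted sum of all components

#' Construct a patient vasculature sheet
#'
#' Bundles a complete set of vessel grades with the pial artery counts into a
#' validated `vasculature` object. The grade table must contain exactly one
#' row per slot defined by [vessel_slots()] (34 slots: 22 paired + 2 midline
#' graded vessels, 10 assessability slots).
#'
#' @param grades Data frame with columns `vessel`, `side`, `grade`.
#' @param pial_cortical Non-negative integer count of visible cortical pial
#'   arteries (whole brain).
#' @param pial_cerebellar Non-negative integer count of visible cerebellar
#'   pial arteries.
#' @return An object of class `vasculature`.
#' @examples
#' v <- normal_vasculature()
#' whole_brain_score(v)
#' @export
vasculature <- function(grades, pial_cortical, pial_cerebellar) {
  stopifnot(is.data.frame(grades))
  need <- c("vessel", "side", "grade")
  miss <- setdiff(need, names(grades))
  if (length(miss)) {
    stop("grades is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sch <- slot_schema()
  key <- paste(grades$vessel, grades$side, sep = ".")
  if (anyDuplicated(key)) {
    stop("duplicate (vessel, side) slots: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(sch$slot, key)
  if (length(absent)) {
    stop("incomplete grading sheet; missing slots: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(key, sch$slot)
  if (length(unknown)) {
    stop("unknown slots: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(grades))) {
    validate_grade(grades$vessel[i], grades$side[i], grades$grade[i])
  }
  pial <- pial_counts(pial_cortical, pial_cerebellar)
  grades <- grades[match(sch$slot, key), need]
  rownames(grades) <- NULL
  structure(list(grades = grades, pial = pial), class = "vasculature")
}

pial_counts <- function(cortical, cerebellar) {
  for (v in list(cortical = cortical, cerebellar = cerebellar)) {
    if (length(v) != 1L || is.na(v) || !is.finite(v) || v < 0 || v != round(v)) {
      stop("pial counts must be single finite non-negative integers", call. = FALSE)
    }
  }
  list(cortical = as.integer(cortical), cerebellar = as.integer(cerebellar))
}

#' All-normal reference sheet
#'
#' Convenience constructor: every graded vessel normal (1) on both sides,
#' every assessability vessel assessable, and pial counts at the top scoring
#' band (12 cortical, 3 cerebellar). Scores at the whole-brain maximum of 56.
#'
#' @return A `vasculature` object.
#' @export
normal_vasculature <- function() {
  sch <- slot_schema()
  vasculature(
    data.frame(vessel = sch$vessel, side = sch$side, grade = 1L),
    pial_cortical = 12L, pial_cerebellar = 3L
  )
}

#' Add left and right grades of a paired vessel
#'
#' One value per vessel: paired vessels get `left + right`; for the midline
#' vessels (BAS, Acom) the single grade is returned unchanged.
#'
#' @param left,right Integer grade codes.
#' @param vessel Optional vessel name; if given, both codes are validated
#'   against that vessel's allowed code set.
#' @return Integer side-summed grade.
#' @export
side_sum <- function(left, right = NULL, vessel = NULL) {
  if (!is.null(vessel)) {
    sch <- slot_schema()
    sides <- sch$side[sch$vessel == vessel]
    if (!length(sides)) stop("unknown vessel: ", vessel, call. = FALSE)
    if (identical(sides, "midline")) {
      validate_grade(vessel, "midline", left)
      return(as.integer(left))
    }
    validate_grade(vessel, "left", left)
    validate_grade(vessel, "right", right)
  }
  if (is.null(right)) return(as.integer(left))
  as.integer(left + right)
}

#' Weighted cerebral-artery segment score
#'
#' Proximal segments are up-weighted because proximal disease has the more
#' devastating downstream effect: `ACA = 2*A1 + A2`, `MCA = 4*M1 + 2*M2 + M3`,
#' `PCA = 4*P1 + 2*P2 + P3`. Inputs are side-summed segment values.
#'
#' @param vessel `"ACA"`, `"MCA"` or `"PCA"`.
#' @param segments Named or positional numeric vector of side-summed segment
#'   values, proximal first (`A1, A2` or `M1, M2, M3` / `P1, P2, P3`).
#' @return Integer weighted score.
#' @export
weighted_segment_score <- function(vessel, segments) {
  w <- switch(vessel,
    ACA = c(A1 = 2, A2 = 1),
    MCA = c(M1 = 4, M2 = 2, M3 = 1),
    PCA = c(P1 = 4, P2 = 2, P3 = 1),
    stop("unknown weighted vessel: ", vessel, call. = FALSE)
  )
  if (!is.null(names(segments)) && any(nzchar(names(segments)))) {
    miss <- setdiff(names(w), names(segments))
    if (length(miss)) {
      stop("missing segment(s) for ", vessel, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    segments <- segments[names(w)]
  } else if (length(segments) != length(w)) {
    stop(vessel, " needs ", length(w), " segment values, got ",
         length(segments), call. = FALSE)
  }
  as.integer(sum(w * segments))
}

#' Pial collateral scores
#'
#' Maps raw pial artery counts to ordinal scores. Cortical: 0 for 0-8 visible
#' pial arteries, 1 for 9-11, 2 for more than 11. Cerebellar: 0 if none
#' visible / not assessable, 1 for fewer than 3 visible, 2 for more than 2.
#'
#' @param cortical,cerebellar Non-negative integer counts.
#' @return Named integer vector `c(cortical = 0..2, cerebellar = 0..2)`.
#' @export
pial_scores <- function(cortical, cerebellar) {
  pial_counts(cortical, cerebellar)
  cort <- if (cortical <= 8) 0L else if (cortical <= 11) 1L else 2L
  cer <- if (cerebellar == 0) 0L else if (cerebellar < 3) 1L else 2L
  c(cortical = cort, cerebellar = cer)
}

#' Whole-brain collateral vessel score
#'
#' Aggregates a complete grading sheet into the comprehensive arterial
#' vasculature status score: side-summed VA, Pcom and ICA, the midline BAS
#' and Acom grades, the weighted ACA/MCA/PCA segment scores, one
#' assessability point per assessable cerebellar/ophthalmic/meningeal side,
#' and the two pial scores, all summed without further weighting.
#'
#' An all-normal sheet scores 56; all graded vessels occluded bilaterally
#' with nothing else assessable scores -168.
#'
#' @param v A `vasculature` object.
#' @return A `score_breakdown` object: list of named components plus
#'   `whole_brain_score` and `pial_only_score` totals.
#' @export
whole_brain_score <- function(v) {
  stopifnot(inherits(v, "vasculature"))
  g <- v$grades
  val <- function(vessel) {
    rows <- g$grade[g$vessel == vessel]
    as.integer(sum(rows)) # side-sum; midline vessels have a single row
  }
  vessels <- c("VA", "BAS", "Pcom", "ICA", "Acom")
  side_summed <- vapply(vessels, val, integer(1))
  aca <- weighted_segment_score("ACA", c(A1 = val("A1"), A2 = val("A2")))
  mca <- weighted_segment_score("MCA", c(M1 = val("M1"), M2 = val("M2"), M3 = val("M3")))
  pca <- weighted_segment_score("PCA", c(P1 = val("P1"), P2 = val("P2"), P3 = val("P3")))
  assess <- as.integer(sum(g$grade[g$vessel %in% c("PICA", "AICA", "SCA", "ophthalmic", "MMA")]))
  pial <- pial_scores(v$pial$cortical, v$pial$cerebellar)
  total <- sum(side_summed) + aca + mca + pca + assess + sum(pial)
  structure(list(
    side_summed = side_summed,
    ACA = aca, MCA = mca, PCA = pca,
    assessability = assess,
    pial_cortical = unname(pial["cortical"]),
    pial_cerebellar = unname(pial["cerebellar"]),
    pial_only_score = as.integer(sum(pial)),
    whole_brain_score = as.integer(total)
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("Whole-brain collateral vessel score:", x$whole_brain_score, "\n")
  cat("  side-summed:",
      paste(sprintf("%s=%d", names(x$side_summed), x$side_summed), collapse = " "), "\n")
  cat(sprintf("  weighted segments: ACA=%d MCA=%d PCA=%d\n", x$ACA, x$MCA, x$PCA))
  cat(sprintf("  assessability=%d pial cortical=%d pial cerebellar=%d (pial-only %d)\n",
              x$assessability, x$pial_cortical, x$pial_cerebellar, x$pial_only_score))
  invisible(x)
}

#' Pial-only collateral score
#'
#' The cortical plus cerebellar pial score, range 0-4. Reported alongside the
#' whole-brain score as a predictor in its own right.
#'
#' @param v A `vasculature` object.
#' @return Integer in 0-4.
#' @export
pial_only_score <- function(v) {
  stopifnot(inherits(v, "vasculature"))
  as.integer(sum(pial_scores(v$pial$cortical, v$pial$cerebellar)))
}

# ---- vectorised scoring over a cohort ---------------------------------------

# grades: n x 34 integer matrix, columns ordered as slot_schema()$slot;
# pial_cortical / pial_cerebellar: integer vectors of length n.
# Returns data.frame(whole_brain_score, pial_only_score).
score_grade_matrix <- function(grades, pial_cortical, pial_cerebellar) {
  sch <- slot_schema()
  stopifnot(ncol(grades) == nrow(sch))
  vess <- as.integer(grades %*% sch$weight)
  cort <- ifelse(pial_cortical <= 8, 0L, ifelse(pial_cortical <= 11, 1L, 2L))
  cer <- ifelse(pial_cerebellar == 0, 0L,
                ifelse(pial_cerebellar < 3, 1L, 2L))
  data.frame(
    whole_brain_score = vess + cort + cer,
    pial_only_score = cort + cer
  )
}

#' Score a long-format vasculature table
#'
#' Computes whole-brain and pial-only scores for every patient in a
#' long-format grade table (one row per patient x slot) with companion pial
#' counts, as written by [write_vasculature_csv()].
#'
#' @param grades Data frame with columns `patient_id`, `vessel`, `side`,
#'   `grade`.
#' @param pial Data frame with columns `patient_id`, `pial_cortical_count`,
#'   `pial_cerebellar_count`.
#' @return Data frame with `patient_id`, `whole_brain_score`,
#'   `pial_only_score`, one row per patient.
#' @export
score_cohort <- function(grades, pial) {
  stopifnot(all(c("patient_id", "vessel", "side", "grade") %in% names(grades)),
            all(c("patient_id", "pial_cortical_count", "pial_cerebellar_count") %in% names(pial)))
  sch <- slot_schema()
  ids <- unique(grades$patient_id)
  slot <- paste(grades$vessel, grades$side, sep = ".")
  j <- match(slot, sch$slot)
  if (anyNA(j)) {
    stop("unknown slots: ", paste(unique(slot[is.na(j)]), collapse = ", "), call. = FALSE)
  }
  i <- match(grades$patient_id, ids)
  m <- matrix(NA_integer_, length(ids), nrow(sch))
  m[cbind(i, j)] <- grades$grade
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    stop("incomplete grading sheet(s) for patient(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
  }
  k <- match(ids, pial$patient_id)
  if (anyNA(k)) stop("missing pial counts for some patients", call. = FALSE)
  out <- score_grade_matrix(m, pial$pial_cortical_count[k], pial$pial_cerebellar_count[k])
  cbind(data.frame(patient_id = ids), out)
}

# ---- sheet I/O --------------------------------------------------------------

#' Read / write long-format vasculature CSV
#'
#' The on-disk format is a long CSV with columns `patient_id`, `vessel`,
#' `side`, `grade` and a companion pial-count table with `patient_id`,
#' `pial_cortical_count`, `pial_cerebellar_count`; `write_vasculature_csv()`
#' writes the two as `<stem>.csv` and `<stem>_pial.csv`.
#'
#' @param grades,pial Data frames as in [score_cohort()].
#' @param stem Path stem (without `.csv`).
#' @return `read_vasculature_csv()` returns `list(grades, pial)`;
#'   the writer returns the two paths invisibly.
#' @export
write_vasculature_csv <- function(grades, pial, stem) {
  p1 <- paste0(stem, ".csv")
  p2 <- paste0(stem, "_pial.csv")
  utils::write.csv(grades, p1, row.names = FALSE)
  utils::write.csv(pial, p2, row.names = FALSE)
  invisible(c(grades = p1, pial = p2))
}

#' @rdname write_vasculature_csv
#' @export
read_vasculature_csv <- function(stem) {
  grades <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  pial <- utils::read.csv(paste0(stem, "_pial.csv"), stringsAsFactors = FALSE)
  need <- c("patient_id", "vessel", "side", "grade")
  miss <- setdiff(need, names(grades))
  if (length(miss)) stop("vasculature CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  list(grades = grades, pial = pial)
}

#' Convert a single-patient vasculature to/from JSON
#'
#' @param v A `vasculature` object.
#' @param txt JSON text produced by `vasculature_to_json()`.
#' @return JSON string / `vasculature` object.
#' @export
vasculature_to_json <- function(v) {
  stopifnot(inherits(v, "vasculature"))
  jsonlite::toJSON(list(
    grades = v$grades,
    pial = list(cortical = v$pial$cortical, cerebellar = v$pial$cerebellar)
  ), auto_unbox = TRUE, digits = NA)
}

#' @rdname vasculature_to_json
#' @export
vasculature_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  vasculature(x$grades, x$pial$cortical, x$pial$cerebellar)
}
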