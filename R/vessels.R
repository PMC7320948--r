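# Vessel/segment schema for the whole-brain collateral grading sheet.
#
# Two grading families:
#   * graded vessels  -- codes -4 (occluded), -3 (visible stenosis),
#                        -2 (hypoplastic), -1 (diameter variations),
#                         0 (not assessable), 1 (normal)
#   * assessability-only vessels -- 1 (assessable), 0 (not assessable)
# BAS and Acom are anatomically unpaired and carry a single midline grade.

GRADED_CODES <- c(-4L, -3L, -2L, -1L, 0L, 1L)
ASSESS_CODES <- c(0L, 1L)

#' Vessel slot schema
#'
#' Returns the complete set of vessel/segment slots that make up one
#' patient's collateral grading sheet: vessel identifier, side
#' (`left`/`right`, or `midline` for the unpaired basilar and anterior
#' communicating arteries), grading family (`graded` with codes -4..1 or
#' `assessability` with codes 0/1), and the weight the slot carries in the
#' whole-brain score (proximal cerebral-artery segments are up-weighted:
#' ACA = 2*A1 + A2, MCA = 4*M1 + 2*M2 + M3, PCA = 4*P1 + 2*P2 + P3).
#'
#' @return A data frame with one row per slot and columns `vessel`, `side`,
#'   `kind`, `weight`, and `slot` (the unique `vessel.side` label).
#' @export
vessel_slots <- function() {
  graded <- rbind(
    data.frame(vessel = "VA",   weight = 1),
    data.frame(vessel = "Pcom", weight = 1),
    data.frame(vessel = "ICA",  weight = 1),
    data.frame(vessel = "A1",   weight = 2),
    data.frame(vessel = "A2",   weight = 1),
    data.frame(vessel = "M1",   weight = 4),
    data.frame(vessel = "M2",   weight = 2),
    data.frame(vessel = "M3",   weight = 1),
    data.frame(vessel = "P1",   weight = 4),
    data.frame(vessel = "P2",   weight = 2),
    data.frame(vessel = "P3",   weight = 1)
  )
  paired_graded <- data.frame(
    vessel = rep(graded$vessel, each = 2L),
    side   = rep(c("left", "right"), nrow(graded)),
    kind   = "graded",
    weight = rep(graded$weight, each = 2L)
  )
  midline <- data.frame(
    vessel = c("BAS", "Acom"),
    side   = "midline",
    kind   = "graded",
    weight = 1
  )
  assess <- data.frame(
    vessel = rep(c("PICA", "AICA", "SCA", "ophthalmic", "MMA"), each = 2L),
    side   = rep(c("left", "right"), 5L),
    kind   = "assessability",
    weight = 1
  )
  out <- rbind(paired_graded, midline, assess)
  out$slot <- paste(out$vessel, out$side, sep = ".")
  rownames(out) <- NULL
  out
}

# cached schema (cheap, but called in tight loops)
.slots_cache <- new.env(parent = emptyenv())
slot_schema <- function() {
  if (is.null(.slots_cache$df)) .slots_cache$df <- vessel_slots()
  .slots_cache$df
}

allowed_codes <- function(kind) {
  if (kind == "graded") GRADED_CODES else ASSESS_CODES
}

#' Validate a single vessel grade code
#'
#' @param vessel Vessel/segment identifier (see [vessel_slots()]).
#' @param side One of `"left"`, `"right"`, `"midline"`.
#' @param grade Integer grade code.
#' @return Invisibly `TRUE`; otherwise an error naming the vessel and side.
#' @export
validate_grade <- function(vessel, side, grade) {
  sch <- slot_schema()
  hit <- sch[sch$vessel == vessel & sch$side == side, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop(sprintf("unknown vessel slot: %s (%s)", vessel, side), call. = FALSE)
  }
  ok <- allowed_codes(hit$kind)
  if (length(grade) != 1L || is.na(grade) || !(grade %in% ok)) {
    stop(sprintf(
      "invalid grade %s for vessel %s (%s); allowed codes: %s",
      deparse(grade), vessel, side, paste(ok, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
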