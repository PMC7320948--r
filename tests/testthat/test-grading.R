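test_that("side summation adds paired grades and passes midline grades through", {
  expect_identical(side_sum(1, 1), 2L)
  expect_identical(side_sum(-4, 1), -3L)
  expect_identical(side_sum(0, 0), 0L)
  expect_identical(side_sum(1, 1, vessel = "VA"), 2L)
  expect_identical(side_sum(-3, vessel = "BAS"), -3L)
  expect_error(side_sum(5, 1, vessel = "VA"), "invalid grade.*VA.*left")
  expect_error(side_sum(-1, 1, vessel = "PICA"), "invalid grade")
  expect_error(side_sum(1, 1, vessel = "XYZ"), "unknown vessel")
})

test_that("segment weighting up-weights proximal segments", {
  expect_identical(weighted_segment_score("MCA", c(2, 2, 2)), 14L)
  expect_identical(weighted_segment_score("MCA", c(-3, 2, 2)), -6L)
  expect_identical(weighted_segment_score("ACA", c(2, 2)), 6L)
  expect_identical(weighted_segment_score("PCA", c(P3 = 2, P1 = 2, P2 = 2)), 14L)
  expect_error(weighted_segment_score("ICA", c(1, 1)), "unknown weighted vessel")
  expect_error(weighted_segment_score("MCA", c(M1 = 2, M3 = 2)), "missing segment.*M2")
  expect_error(weighted_segment_score("ACA", 2), "needs 2 segment values")
})

test_that("pial counts map onto the 0-2 ordinal bands", {
  expect_identical(unname(pial_scores(12, 0)["cortical"]), 2L)
  expect_identical(unname(pial_scores(8, 0)["cortical"]), 0L)
  expect_identical(unname(pial_scores(9, 0)["cortical"]), 1L)
  expect_identical(unname(pial_scores(11, 0)["cortical"]), 1L)
  expect_identical(unname(pial_scores(0, 3)["cerebellar"]), 2L)
  expect_identical(unname(pial_scores(0, 0)["cerebellar"]), 0L)
  expect_identical(unname(pial_scores(0, 2)["cerebellar"]), 1L)
  expect_error(pial_scores(-1, 0), "non-negative")
  expect_error(pial_scores(2.5, 0), "non-negative integers")
})

test_that("whole-brain score matches the hand-derived aggregation", {
  v <- normal_vasculature()
  b <- whole_brain_score(v)
  expect_identical(b$whole_brain_score, 56L)
  # component bookkeeping: VA 2 + BAS 1 + Pcom 2 + ICA 2 + Acom 1 + ACA 6 +
  # MCA 14 + PCA 14 + assessability 10 + pial 4
  expect_identical(unname(b$side_summed), c(2L, 1L, 2L, 2L, 1L))
  expect_identical(c(b$ACA, b$MCA, b$PCA), c(6L, 14L, 14L))
  expect_identical(b$assessability, 10L)
  expect_identical(b$pial_only_score, 4L)

  g <- v$grades
  g$grade[g$vessel == "M1" & g$side == "left"] <- -4L
  expect_identical(whole_brain_score(vasculature(g, 12, 3))$whole_brain_score, 36L)

  # empty-information sheet: nothing assessable, nothing visible
  g0 <- v$grades; g0$grade <- 0L
  expect_identical(whole_brain_score(vasculature(g0, 0, 0))$whole_brain_score, 0L)

  # lower bound: all graded vessels occluded bilaterally
  gmin <- v$grades
  gmin$grade <- ifelse(vessel_slots()$kind == "graded", -4L, 0L)
  expect_identical(whole_brain_score(vasculature(gmin, 0, 0))$whole_brain_score, -168L)
})

test_that("pial-only score is the cortical plus cerebellar band sum", {
  expect_identical(pial_only_score(normal_vasculature()), 4L)
  v <- normal_vasculature()
  expect_identical(pial_only_score(vasculature(v$grades, 0, 0)), 0L)
  expect_identical(pial_only_score(vasculature(v$grades, 9, 1)), 2L)
})

test_that("sheet validation rejects incomplete, duplicated and invalid input", {
  v <- normal_vasculature()
  expect_error(vasculature(v$grades[-1, ], 1, 1), "missing slots: VA.left")
  dup <- rbind(v$grades, v$grades[1, ])
  expect_error(vasculature(dup, 1, 1), "duplicate")
  bad <- v$grades; bad$grade[bad$vessel == "PICA" & bad$side == "left"] <- -2L
  expect_error(vasculature(bad, 1, 1), "invalid grade -2.* PICA")
  bad2 <- v$grades; bad2$grade[1] <- 7L
  expect_error(vasculature(bad2, 1, 1), "invalid grade 7")
})

test_that("score is additive over its breakdown and symmetric under side swap", {
  set.seed(41)
  sch <- vessel_slots()
  for (i in 1:25) {
    v <- random_sheet()
    b <- whole_brain_score(v)
    expect_identical(
      b$whole_brain_score,
      as.integer(sum(b$side_summed) + b$ACA + b$MCA + b$PCA +
                   b$assessability + b$pial_cortical + b$pial_cerebellar))
    # swap all left/right grades
    g <- v$grades
    li <- g$side == "left"; ri <- g$side == "right"
    g$grade[li] <- v$grades$grade[ri][match(g$vessel[li], g$vessel[ri])]
    g$grade[ri] <- v$grades$grade[li][match(g$vessel[ri], v$grades$vessel[li])]
    sw <- vasculature(g, v$pial$cortical, v$pial$cerebellar)
    expect_identical(whole_brain_score(sw)$whole_brain_score, b$whole_brain_score)
  }
})

test_that("improving any single grade never decreases the score", {
  set.seed(42)
  sch <- vessel_slots()
  for (i in 1:20) {
    v <- random_sheet()
    base <- whole_brain_score(v)$whole_brain_score
    for (j in seq_len(nrow(sch))) {
      codes <- if (sch$kind[j] == "graded") c(-4L, -3L, -2L, -1L, 0L, 1L) else c(0L, 1L)
      cur <- v$grades$grade[j]
      pos <- match(cur, codes)
      if (pos == length(codes)) next
      g <- v$grades; g$grade[j] <- codes[pos + 1L]
      up <- whole_brain_score(vasculature(g, v$pial$cortical, v$pial$cerebellar))
      expect_gte(up$whole_brain_score, base)
    }
    # and improving pial visibility
    up <- whole_brain_score(vasculature(v$grades, v$pial$cortical + 4L,
                                        v$pial$cerebellar + 4L))
    expect_gte(up$whole_brain_score, base)
  }
})

test_that("vectorised cohort scoring agrees with per-patient scoring", {
  set.seed(7)
  sheets <- replicate(10, random_sheet(), simplify = FALSE)
  grades <- do.call(rbind, lapply(seq_along(sheets), function(i) {
    cbind(patient_id = sprintf("P%02d", i), sheets[[i]]$grades)
  }))
  pial <- data.frame(
    patient_id = sprintf("P%02d", seq_along(sheets)),
    pial_cortical_count = vapply(sheets, function(s) s$pial$cortical, integer(1)),
    pial_cerebellar_count = vapply(sheets, function(s) s$pial$cerebellar, integer(1)))
  sc <- score_cohort(grades, pial)
  expect_identical(sc$whole_brain_score,
                   vapply(sheets, function(s) whole_brain_score(s)$whole_brain_score, integer(1)))
  expect_identical(sc$pial_only_score,
                   vapply(sheets, function(s) pial_only_score(s), integer(1)))
})

test_that("vasculature sheets round-trip through CSV and JSON", {
  set.seed(11)
  v <- random_sheet()
  expect_identical(whole_brain_score(vasculature_from_json(vasculature_to_json(v))),
                   whole_brain_score(v))
  grades <- cbind(patient_id = "P01", v$grades)
  pial <- data.frame(patient_id = "P01",
                     pial_cortical_count = v$pial$cortical,
                     pial_cerebellar_count = v$pial$cerebellar)
  stem <- file.path(withr::local_tempdir(), "vasc")
  write_vasculature_csv(grades, pial, stem)
  back <- read_vasculature_csv(stem)
  expect_equal(back$grades, grades)
  expect_equal(back$pial, pial)
})
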