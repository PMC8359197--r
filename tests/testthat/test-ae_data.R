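test_that("event files parse, validate, and cross-check against the design", {
  events <- data.frame(
    patient_id = c("P1", "P1", "P2"), period_id = "p1",
    ae_name = c("NAUSEA", "VOMIT", "NAUSEA"), severity = c(1, 2, 2),
    count = c(3, 1, 2))
  design <- data.frame(period_id = "p1", study_id = 1,
                       treatment_id = "AC", mechanism_id = "NAS",
                       n_cycles = 4, is_baseline = FALSE)
  enrollment <- data.frame(period_id = "p1", patient_id = c("P1", "P2"))
  paths <- writeCSVTriple(events, design, enrollment)

  parsed <- readAEEvents(paths$events, paths$design, paths$enrollment)
  expect_equal(nrow(parsed$events), 3)
  expect_equal(parsed$events$count, c(3, 1, 2))

  bad <- events
  bad$severity[2] <- 5
  paths2 <- writeCSVTriple(bad, design, enrollment)
  expect_error(readAEEvents(paths2$events, paths2$design, paths2$enrollment),
               "row 2")

  noCol <- events[, -3]
  paths3 <- writeCSVTriple(noCol, design, enrollment)
  expect_error(readAEEvents(paths3$events, paths3$design, paths3$enrollment),
               "missing column")

  stranger <- rbind(events,
                    data.frame(patient_id = "P9", period_id = "p1",
                               ae_name = "FEVER", severity = 1, count = 1))
  paths4 <- writeCSVTriple(stranger, design, enrollment)
  expect_error(readAEEvents(paths4$events, paths4$design, paths4$enrollment),
               "absent from enrollment")
})

test_that("the pooled three-study design parses with 10 periods and the known arm sizes", {
  tb <- threeStudyTables()
  events <- data.frame(patient_id = "A1-0001", period_id = "p02",
                       ae_name = "NAUSEA", severity = 1, count = 1)
  paths <- writeCSVTriple(events, tb$design, tb$enrollment)
  parsed <- readAEEvents(paths$events, paths$design, paths$enrollment)
  expect_equal(nrow(parsed$design), 10)
  expect_equal(sum(parsed$design$is_baseline), 3)
  expect_setequal(stats::na.omit(parsed$design$treatment_id),
                  c("AC", "FAC", "A", "CMF", "T"))
  map <- unique(stats::na.omit(parsed$design[c("treatment_id", "mechanism_id")]))
  expect_equal(map$mechanism_id[map$treatment_id == "T"], "MIT")
  expect_true(all(map$mechanism_id[map$treatment_id != "T"] == "NAS"))
  idx <- buildAETypeIndex(parsed$events)
  cd <- assembleCounts(parsed$events, parsed$design, parsed$enrollment, idx)
  expect_equal(vapply(aeCounts(cd), nrow, integer(1)),
               setNames(as.integer(tb$n_per_period), tb$design$period_id))
  expect_true(all(aeExposure(cd)$p02 == 4))
  # a patient enrolled in p02 but dropped before p03
  dropped <- setdiff(rownames(aeCounts(cd)$p02), rownames(aeCounts(cd)$p03))
  expect_length(dropped, 42)
})

test_that("stopword and zero-AE-patient filters behave and are idempotent", {
  events <- data.frame(
    patient_id = c("P1", "P1", "P2", "P3"), period_id = "p1",
    ae_name = c("ALOPECIA", "NAUSEA", "ALOPECIA", "FEVER"),
    severity = c(2, 1, 3, 1), count = c(1, 2, 1, 1))
  enrollment <- data.frame(period_id = "p1",
                           patient_id = c("P1", "P2", "P3"))
  f <- applyAEFilters(events, enrollment, stopwords = "ALOPECIA")
  # all ALOPECIA rows removed regardless of severity
  expect_false("ALOPECIA" %in% f$events$ae_name)
  expect_equal(f$report$removed_names$name, "ALOPECIA")
  expect_equal(f$report$removed_names$events_removed, 2)
  # P2 only had a stopword AE: removed from enrollment entirely
  expect_equal(f$report$removed_patients, "P2")
  expect_false("P2" %in% f$enrollment$patient_id)
  # idempotent
  f2 <- applyAEFilters(f$events, f$enrollment, stopwords = "ALOPECIA")
  expect_identical(f$events, f2$events)
  expect_identical(f$enrollment, f2$enrollment)
  # identity case
  ev <- events[events$ae_name != "ALOPECIA", ]
  id <- applyAEFilters(ev, enrollment[enrollment$patient_id != "P2", ])
  expect_equal(id$events$ae_name, ev$ae_name)
  expect_equal(nrow(id$report$removed_names), 0)
})

test_that("the frequency rule removes names occurring in more than the threshold", {
  events <- data.frame(
    patient_id = c("P1", "P2", "P3", "P1"), period_id = "p1",
    ae_name = c("COMMON", "COMMON", "COMMON", "RARE"),
    severity = 1, count = 1)
  enrollment <- data.frame(period_id = "p1",
                           patient_id = c("P1", "P2", "P3", "P4"))
  f <- applyAEFilters(events, enrollment, freqThreshold = 0.7)
  expect_false("COMMON" %in% f$events$ae_name)  # 3/4 = 75% > 70%
  expect_true("RARE" %in% f$events$ae_name)
})

test_that("AE-type index is deterministic, labelled NAME_severity", {
  events <- data.frame(
    patient_id = "P1", period_id = "p1",
    ae_name = c("VOMIT", "NAUSEA", "NAUSEA", "VOMIT", "NAUSEA"),
    severity = c(2, 3, 1, 1, 2), count = 1)
  idx <- buildAETypeIndex(events)
  expect_equal(idx$label,
               c("NAUSEA_1", "NAUSEA_2", "NAUSEA_3", "VOMIT_1", "VOMIT_2"))
  expect_equal(idx$column, 1:5)
  one <- buildAETypeIndex(events[1, ])
  expect_equal(one$label, "VOMIT_2")
  expect_warning(empty <- buildAETypeIndex(events[0, ]), "no events")
  expect_equal(nrow(empty), 0)
})

test_that("severity adjacency chains observed grades and anchors the lowest", {
  events <- data.frame(
    patient_id = "P1", period_id = "p1",
    ae_name = c("NAUSEA", "NAUSEA", "SOLO", "GAP", "GAP"),
    severity = c(2, 3, 2, 1, 3), count = 1)
  idx <- buildAETypeIndex(events)
  adj <- buildAdjacency(idx)
  lab <- function(j) idx$label[j]
  # NAUSEA {2,3}: one pair, anchored at 2
  expect_true(any(lab(adj$pairs[, "j"]) == "NAUSEA_2" &
                  lab(adj$pairs[, "jprime"]) == "NAUSEA_3"))
  expect_equal(lab(adj$anchors[["NAUSEA"]]), "NAUSEA_2")
  # unobserved grade 2 of GAP: observed {1,3} chained directly
  expect_true(any(lab(adj$pairs[, "j"]) == "GAP_1" &
                  lab(adj$pairs[, "jprime"]) == "GAP_3"))
  expect_equal(lab(adj$anchors[["SOLO"]]), "SOLO_2")
  # chain property: k observed grades -> k-1 pairs, 1 anchor per name
  expect_equal(nrow(adj$pairs), (2 - 1) + (2 - 1) + 0)
  expect_length(adj$anchors, 3)
  expect_true(all(adj$pairs[, "j"] < adj$pairs[, "jprime"]))
})

test_that("adjacency chain property holds on random severity grids", {
  set.seed(42)
  for (rep in 1:5) {
    names <- sprintf("N%02d", 1:8)
    grids <- lapply(names, function(x) sort(sample(1:4, sample(1:4, 1))))
    events <- do.call(rbind, Map(function(nm, g)
      data.frame(patient_id = "P", period_id = "p", ae_name = nm,
                 severity = g, count = 1), names, grids))
    idx <- buildAETypeIndex(events)
    adj <- buildAdjacency(idx)
    expect_equal(nrow(adj$pairs), sum(lengths(grids) - 1))
    expect_length(adj$anchors, length(names))
    # each column participates in at most 2 pairs
    expect_true(all(table(c(adj$pairs)) <= 2))
  }
})

test_that("count assembly maps events to cells, respects enrollment, and round-trips totals", {
  events <- data.frame(
    patient_id = c("A", "A", "B"), period_id = c("p2", "p2", "p2"),
    ae_name = c("NAUSEA", "NAUSEA", "VOMIT"), severity = c(1, 1, 2),
    count = c(3, 2, 1))
  design <- data.frame(period_id = c("p1", "p2", "p3"), study_id = 1,
                       treatment_id = c(NA, "AC", "AC"),
                       mechanism_id = c(NA, "NAS", "NAS"),
                       n_cycles = c(NA, 4, 4),
                       is_baseline = c(TRUE, FALSE, FALSE))
  enrollment <- data.frame(
    period_id = c("p1", "p1", "p2", "p2", "p3"),
    patient_id = c("A", "B", "A", "B", "A"))  # B drops out before p3
  idx <- buildAETypeIndex(events)
  cd <- assembleCounts(events, design, enrollment, idx)
  Y2 <- aeCounts(cd)$p2
  expect_equal(Y2["A", "NAUSEA_1"], 5)  # two rows aggregated
  expect_equal(Y2["B", "VOMIT_2"], 1)
  expect_equal(sum(Y2), 6)
  expect_equal(sum(vapply(aeCounts(cd), sum, numeric(1))), sum(events$count))
  expect_true("B" %in% rownames(aeCounts(cd)$p2))
  expect_false("B" %in% rownames(aeCounts(cd)$p3))
  # baseline exposure default 1, treatment periods use cycles
  expect_equal(unname(aeExposure(cd)$p1), c(1, 1))
  expect_equal(unname(aeExposure(cd)$p2), c(4, 4))
  # permuting input row order changes nothing
  cd2 <- assembleCounts(events[c(3, 1, 2), ], design, enrollment, idx)
  expect_identical(aeCounts(cd2), aeCounts(cd))
  # event for a non-enrolled patient errors
  bad <- rbind(events, data.frame(patient_id = "B", period_id = "p3",
                                  ae_name = "VOMIT", severity = 2, count = 1))
  expect_error(assembleCounts(bad, design, enrollment, idx), "non-enrolled")
})

test_that("per-patient exposure overrides are honoured", {
  events <- data.frame(patient_id = "A", period_id = "p1",
                       ae_name = "FEVER", severity = 1, count = 1)
  design <- data.frame(period_id = "p1", study_id = 1, treatment_id = "AC",
                       mechanism_id = "NAS", n_cycles = 4,
                       is_baseline = FALSE)
  enrollment <- data.frame(period_id = "p1", patient_id = c("A", "B"),
                           exposure = c(NA, 2.5))
  cd <- assembleCounts(events, design, enrollment, buildAETypeIndex(events))
  expect_equal(aeExposure(cd)$p1, c(A = 4, B = 2.5))
})
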