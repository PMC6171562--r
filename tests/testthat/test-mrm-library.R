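lib <- load_mrm_library()

test_that("the packaged library preserves the printed acquisition values", {
  expect_gte(sum(lengths(lib$q3)), 45)
  expect_setequal(unique(lib$method_tag),
                  c("pos_underivatized", "neg_underivatized",
                    "obha_gradient1", "obha_gradient2"))
  lys <- library_entry("K.pos", lib)
  expect_equal(lys$q1, 147.0)
  expect_equal(lys$q3[[1]], 84.1)
  expect_equal(lys$rt, 2.72)
  tre <- library_entry("Tre.neg", lib)
  expect_equal(tre$polarity, "negative")
  expect_equal(c(tre$q1, tre$q3[[1]]), c(341.3, 179.3))
  expect_identical(load_mrm_library(), lib)  # pure
  expect_false(anyDuplicated(lib[c("abbreviation", "method_tag")]) > 0)
})

test_that("formula-based prediction reproduces printed Q1/Q3", {
  amp <- predict_transition(library_entry("AMP.pos", lib))
  expect_equal(unname(c(amp$q1, amp$q3)), c(348, 136))
  ump <- predict_transition(library_entry("UMP.pos", lib))
  expect_equal(unname(c(ump$q1, ump$q3)), c(325, 113))
  suc <- predict_transition(library_entry("Suc.obha", lib))
  expect_equal(suc$q1, 329)
  expect_equal(unname(suc$q3), c(206, 91))  # neutral loss, benzyl reporter
  # entries without a curated fragment predict Q1 only
  sam <- predict_transition(library_entry("SAM.pos", lib))
  expect_equal(sam$q1, 399)
  expect_true(all(is.na(sam$q3)))
})

test_that("every nucleotide Q1 and Q3 is reproduced exactly", {
  for (id in c("AMP.pos", "GMP.pos", "CMP.pos", "UMP.pos")) {
    entry <- library_entry(id, lib)
    pred <- predict_transition(entry)
    expect_equal(pred$q1, entry$q1, info = id)
    expect_equal(unname(pred$q3), entry$q3[[1]], info = id)
  }
})

test_that("validation classifies the library as printed", {
  rep <- validate_library(lib)
  expect_equal(nrow(rep), nrow(lib))
  expect_equal(rep$status[rep$entry_id == "E.obha"], "exact-match")
  expect_equal(rep$q1_predicted[rep$entry_id == "E.obha"], 253)
  expect_equal(rep$q1_predicted[rep$entry_id == "2-HG.obha"], 359)
  # the curated glutamine-OBHA anomaly is flagged, never absorbed
  gln <- rep[rep$entry_id == "Q.obha", ]
  expect_equal(gln$status, "off-by-k")
  expect_equal(gln$max_abs_deviation, 1)
  expect_match(gln$anomaly, "251")
  expect_true(all(rep$status[rep$entry_id != "Q.obha"] == "exact-match"))
})

test_that("OBHA Q1 predictions match printed values except glutamine", {
  obha <- lib[lib$derivatization == "OBHA", ]
  for (i in seq_len(nrow(obha))) {
    pred <- predict_transition(obha[i, ])$q1
    want <- round(obha$q1[i]) + if (obha$abbreviation[i] == "Q") 1 else 0
    expect_equal(pred, want, info = obha$entry_id[i])
  }
})

test_that("negative-mode sugar phosphates share the phosphate reporter", {
  sp <- lib[grepl("product:H3PO4", vapply(lib$fragment, paste,
                                          collapse = ";", "")), ]
  expect_gte(nrow(sp), 5)
  for (i in seq_len(nrow(sp))) {
    expect_equal(unname(predict_transition(sp[i, ])$q3), 97,
                 info = sp$entry_id[i])
    expect_equal(sp$q3[[i]], 97)
  }
})

test_that("isobars resolve chromatographically, with explicit tie errors", {
  expect_equal(resolve_isobars(132.0, 86.0, rt = 6.5, lib = lib)$name,
               "Isoleucine")
  expect_equal(resolve_isobars(147.0, 84.1, rt = 3.3, lib = lib)$entry_id,
               "Q.pos")
  expect_equal(resolve_isobars(147.0, 84.1, rt = 2.8, lib = lib)$entry_id,
               "K.pos")
  expect_error(resolve_isobars(132.0, 86.0, rt = 20.0, tolerance = 0.5,
                               lib = lib), "within")
  expect_error(resolve_isobars(500, 100, rt = 5, lib = lib), "no library")
  # exact RT tie between two candidates is an error, not a silent pick
  tie <- rbind(synthetic_entry(abbreviation = "A1", q1 = 100, q3 = 50, rt = 5),
               synthetic_entry(abbreviation = "A2", q1 = 100, q3 = 50, rt = 7))
  expect_error(resolve_isobars(100, 50, rt = 6, tolerance = 2, lib = tie),
               "tie")
})

test_that("gradient programs load with valid timetables", {
  gr <- load_gradients()
  expect_setequal(names(gr),
                  c("positive_underivatized", "negative_underivatized",
                    "obha_gradient1", "obha_gradient2"))
  g1 <- gr$obha_gradient1
  expect_equal(g1$timetable$percent_b[1:2], c(50, 75))
  for (g in gr) {
    expect_true(all(diff(g$timetable$time_min) > 0))
    expect_true(all(g$timetable$percent_b >= 0 & g$timetable$percent_b <= 100))
  }
})
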