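rules <- hebridean_rules()

test_that("criteria scoring matches the published two-of-three logic", {
  # small gracile track, narrow divarication: l/w > 1.50 and div < 50
  # satisfied, mesaxony criterion not
  rec <- track_record("SB02-4", metrics = track_metrics(
    L = 6.92, W = 4.54, te = 2.43, alpha = 21.50, beta = 23.71),
    flags = morphology_flags(digit_shape = "gracile",
                             digits_well_separated = FALSE),
    preservation_grade = 1.5)
  sc <- evaluate_criteria(rec, rules)
  b31 <- sc[sc$subgroup == "HBR_B3.1", ]
  expect_true(b31$eligible)
  expect_true(b31$full_match)
  expect_match(b31$matched[[1]], "lw_ratio", all = FALSE)
  expect_match(b31$matched[[1]], "total_div", all = FALSE)

  # wide-divarication low l/w spindle track satisfies every HBR_B2.2
  # metric predicate
  rec2 <- track_record("2006.011-1", metrics = track_metrics(
    L = 15.27, W = 12.71, te = 6.08, alpha = 47.52, beta = 26.86),
    flags = morphology_flags(digit_shape = "spindle"),
    preservation_grade = 2)
  sc2 <- evaluate_criteria(rec2, rules)
  b22 <- sc2[sc2$subgroup == "HBR_B2.2", ]
  expect_true(b22$eligible && b22$full_match)
  expect_identical(b22$n_satisfied, 3L)

  # all metrics missing -> every score zero
  sc3 <- evaluate_criteria(track_record("void"), rules)
  expect_true(all(sc3$score == 0))
})

test_that("published anchor tracks classify to their subgroups", {
  b11 <- track_record("2002.004", metrics = track_metrics(
    L = 43.88, W = 33.37, te = 13.81, alpha = 29.03, beta = 23.46),
    flags = morphology_flags(digit_shape = "parallel_sided",
                             hallux = "absent"),
    preservation_grade = 1.5)
  cl <- classify_track(b11, rules)
  expect_identical(cl$subgroup, "HBR_B1.1")
  expect_identical(cl$status, "characterized")
  expect_match(cl$suggested_ichnotaxon, "Megalosauripus")

  b32 <- track_record("2018.001-1", metrics = track_metrics(
    L = 7.59, W = 7.24, te = 3.30, alpha = 25.16, beta = 31.97),
    flags = morphology_flags(digit_shape = "gracile",
                             digits_well_separated = TRUE),
    preservation_grade = 2)
  expect_identical(classify_track(b32, rules)$subgroup, "HBR_B3.2")

  # a reversed (posterior) hallux forces the tiny bird-like morphotype
  b4 <- track_record("2009.002", metrics = track_metrics(
    L = 6.44, W = 5.80, te = 3.16, alpha = 49.87, beta = 40.25),
    flags = morphology_flags(digit_shape = "gracile", hallux = "posterior"),
    preservation_grade = 2)
  cl4 <- classify_track(b4, rules)
  expect_identical(cl4$subgroup, "HBR_B4")
  expect_match(cl4$suggested_ichnotaxon, "Trisauropodiscus")

  # contradictory size + shape: a 5 cm track cannot carry large
  # parallel-sided digits
  contra <- track_record("tiny-large", metrics = track_metrics(L = 5, W = 4),
                         flags = morphology_flags(digit_shape = "parallel_sided"),
                         preservation_grade = 2)
  clc <- classify_track(contra, rules)
  expect_identical(clc$status, "unclassified")
  expect_true(is.na(clc$subgroup))
  expect_match(clc$notes, "gates", all = FALSE)
})

test_that("status follows preservation grade and the wear judgement", {
  m <- sample_metrics("HBR_B2.1", strict = TRUE, rules = rules, seed = 5)
  fl <- profile_flags("HBR_B2.1")
  g15 <- classify_track(track_record("a", metrics = m, flags = fl,
                                     preservation_grade = 1.5), rules)
  expect_identical(g15$status, "characterized")
  g1r <- classify_track(track_record("b", metrics = m, flags = fl,
                                     preservation_grade = 1), rules)
  expect_identical(g1r$status, "referred")
  g1c <- classify_track(track_record("c", metrics = m, flags = fl,
                                     preservation_grade = 1,
                                     wear_acceptable = TRUE), rules)
  expect_identical(g1c$status, "characterized")
  g05 <- classify_track(track_record("d", metrics = m, flags = fl,
                                     preservation_grade = 0.5), rules)
  expect_identical(g05$status, "referred")
})

test_that("classification is deterministic and order-independent", {
  fx <- fixture_records()
  ct1 <- classify_table(fx, rules)
  set.seed(3)
  perm <- sample(seq_along(fx))
  ct2 <- classify_table(fx[perm], rules)
  ct2 <- ct2[match(ct1$specimen, ct2$specimen), ]
  expect_identical(ct1$assigned, ct2$assigned)
  expect_identical(ct1$status, ct2$status)
  ct3 <- classify_table(fx, rules)
  expect_identical(ct1$assigned, ct3$assigned)
})

test_that("size gates are sound: no large track enters the small morphotypes", {
  set.seed(11)
  for (i in 1:40) {
    L <- runif(1, 15, 45)
    rec <- track_record("big", metrics = track_metrics(
      L = L, W = L / runif(1, 1.0, 2.2), te = runif(1, 0.3, 0.9) * L / 2,
      alpha = runif(1, 10, 50), beta = runif(1, 10, 50)),
      flags = morphology_flags(digit_shape = "gracile"),
      preservation_grade = 2)
    cl <- classify_track(rec, rules)
    expect_false(isTRUE(cl$series == "HBR_B3"))
    expect_false(isTRUE(cl$subgroup == "HBR_B4"))
  }
  for (rec in fixture_records()) {
    if (!is.na(rec$metrics$L) && rec$metrics$L >= 15) {
      cl <- classify_track(rec, rules)
      expect_false(isTRUE(cl$series == "HBR_B3"))
    }
  }
})

test_that("the fixture audit meets the agreement floor with no silent misassignment", {
  ct <- classify_table(fixture_records(), rules)
  audit <- attr(ct, "audit")
  expect_identical(audit$n_published, 85L)
  expect_gte(audit$n_agree, 80L)
  if (nrow(audit$disagreements))
    expect_true(all(audit$disagreements$kind == "ambiguous"))
})

test_that("withholding flags strictly increases ambiguity", {
  fx <- fixture_records()
  stripped <- lapply(fx, function(r) {
    r$flags <- morphology_flags()
    r
  })
  amb_full <- sum(classify_table(fx, rules)$ambiguous)
  amb_bare <- sum(classify_table(stripped, rules)$ambiguous)
  expect_gt(amb_bare, amb_full)
})

test_that("empty input classifies to an empty table", {
  ct <- classify_table(list(), rules)
  expect_identical(nrow(ct), 0L)
  expect_identical(attr(ct, "audit")$n, 0L)
})
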