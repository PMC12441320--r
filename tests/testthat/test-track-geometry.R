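test_that("axis-aligned tip triangle gives te = height and W = base", {
  m <- measure_track(triangle_landmarks())
  expect_equal(m$te, 5.0)
  expect_equal(m$W, 8.0)
  expect_equal(m$total_div, m$alpha + m$beta)
})

test_that("mirror-symmetric landmark sets give alpha == beta and L_II == L_IV", {
  for (a in c(15, 25, 40)) {
    mc <- consistent_metrics(L = 12, W = 8, te = 4, alpha = a, beta = a)
    lm <- construct_landmarks(mc)
    m <- measure_track(lm)
    expect_equal(m$alpha, m$beta, tolerance = 1e-8)
    expect_equal(m$L_II, m$L_IV, tolerance = 1e-8)
    # mirroring the set leaves all metrics unchanged
    pts <- lm$points
    pts[, 1] <- -pts[, 1]
    m2 <- measure_track(landmark_set("mir", pts))
    expect_equal(unclass(m2), unclass(m), tolerance = 1e-9)
  }
})

test_that("measure_track inverts construct_landmarks on fixed metrics", {
  mc <- consistent_metrics(L = 10, W = 8, te = 4, alpha = 25, beta = 25)
  m <- measure_track(construct_landmarks(mc))
  need <- c("L", "W", "L_II", "L_III", "L_IV", "te", "alpha", "beta")
  expect_equal(unlist(m[need]), unlist(mc[need]), tolerance = 1e-6)
})

test_that("metrics are invariant under rigid motion; te under rotation", {
  mc <- consistent_metrics(L = 20, W = 12, te = 6, alpha = 20, beta = 30,
                           asym = 1.05)
  lm <- construct_landmarks(mc)
  m0 <- measure_track(lm)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- sweep(lm$points %*% t(R), 2, c(-13.2, 7.9), "+")
  m1 <- measure_track(landmark_set("rigid", pts))
  expect_equal(unclass(m1), unclass(m0), tolerance = 1e-9)
})

test_that("hallux landmarks never contribute to track length", {
  mc <- consistent_metrics(L = 6, W = 5, te = 2.5, alpha = 40, beta = 45)
  lm <- construct_landmarks(mc)
  m0 <- measure_track(lm)
  pts <- rbind(lm$points,
               hallux_tip = lm$points["heel", ] + c(0.5, -1.5),
               hallux_base = lm$points["heel", ] + c(0.2, -0.5))
  m1 <- measure_track(landmark_set("hx", pts))
  expect_equal(m1$L, m0$L)
  expect_equal(unclass(m1), unclass(m0))
})

test_that("incomplete and degenerate landmark sets are rejected", {
  lm <- triangle_landmarks()
  pts <- lm$points[setdiff(rownames(lm$points), c("heel", "tip_IV")), ]
  err <- tryCatch(measure_track(landmark_set("part", pts)),
                  error = function(e) e)
  expect_s3_class(err, "hebtracks_incomplete_landmarks")
  expect_setequal(err$missing, c("tip_IV", "heel"))

  pts2 <- lm$points
  pts2["tip_II", ] <- pts2["tip_IV", ]
  expect_error(measure_track(landmark_set("dup", pts2)), "degenerate")
})

test_that("collinear digit tips give te = 0 with a warning", {
  lm <- landmark_set("flat", list(
    tip_II = c(-4, 0), tip_III = c(0, 0), tip_IV = c(4, 0),
    hypex_II_III = c(-1, -2), hypex_III_IV = c(1, -2), heel = c(0, -6)))
  expect_warning(m <- measure_track(lm), "collinear")
  expect_identical(m$te, 0)
})

test_that("derived ratios reproduce printed anchor values", {
  d <- derive_metrics(track_metrics(L = 43.88, W = 33.37, te = 13.81,
                                    L_III = 27.56))
  expect_equal(round(d$lw_ratio, 2), 1.31)
  expect_equal(round(d$mesaxony, 2), 0.41)
  expect_equal(round(d$iii_over_L, 2), 62.81)

  d2 <- derive_metrics(track_metrics(L = 21.00, L_III = 14.15))
  expect_equal(round(d2$iii_over_L, 2), 67.38)

  d3 <- derive_metrics(track_metrics(L = 12, W = 12))
  expect_equal(d3$lw_ratio, 1.00)
})

test_that("derived ratios propagate missingness and zero denominators", {
  d <- derive_metrics(track_metrics(L = 10))
  expect_true(is.na(d$lw_ratio))
  expect_true(is.na(d$mesaxony))
  d0 <- derive_metrics(track_metrics(L = 10, W = 0, te = 1))
  expect_true(is.na(d0$lw_ratio))
  expect_true(is.na(d0$mesaxony))
})

test_that("length categories follow the size-class bins", {
  expect_identical(length_category(c(3, 9.99, 10, 19.9, 20, 29.9, 30, 49.9, 50)),
                   c("tiny", "tiny", "small", "small", "medium", "medium",
                     "large", "large", "giant"))
  expect_true(is.na(length_category(NA)))
})

test_that("positive-relief siding is mirrored, negative passes through", {
  r1 <- apply_relief_siding(track_record("a", side_observed = "right",
                                         relief = "positive"))
  expect_identical(r1$side_catalogued, "left")
  expect_true(r1$mirrored_for_relief)

  r2 <- apply_relief_siding(track_record("b", side_observed = "left",
                                         relief = "negative"))
  expect_identical(r2$side_catalogued, "left")
  expect_false(r2$mirrored_for_relief)

  expect_warning(
    r3 <- apply_relief_siding(track_record("c", side_observed = "indeterminate",
                                           relief = "positive")),
    "indeterminate")
  expect_identical(r3$side_catalogued, "indeterminate")
})

test_that("validate_record flags forced inconsistencies and none on clean rows", {
  clean <- track_record("t2", metrics = track_metrics(
    L = 43.88, W = 33.37, L_II = 23.68, L_III = 27.56, L_IV = 30.38,
    te = 13.81, alpha = 29.03, beta = 23.46, total_div = 52.49))
  expect_length(validate_record(clean), 0)

  bad <- track_record("bad", metrics = track_metrics(
    alpha = 30, beta = 30, total_div = 70))
  expect_match(validate_record(bad), "divarication mismatch", all = FALSE)

  mis <- track_record("cat", metrics = track_metrics(L = 9.9))
  mis$length_category <- "small"
  expect_match(validate_record(mis), "category mismatch, expected tiny",
               all = FALSE)
})

test_that("every fixture row passes validate_record at table tolerances", {
  findings <- unlist(lapply(fixture_records(), validate_record))
  expect_length(findings, 0)
})
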