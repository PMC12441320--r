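rules <- hebridean_rules()

test_that("sampling is deterministic under seed and varies across seeds", {
  m1 <- sample_metrics("HBR_B2.1", strict = TRUE, rules = rules, seed = 42)
  m2 <- sample_metrics("HBR_B2.1", strict = TRUE, rules = rules, seed = 42)
  m3 <- sample_metrics("HBR_B2.1", strict = TRUE, rules = rules, seed = 43)
  expect_identical(unclass(m1), unclass(m2))
  expect_false(identical(unclass(m1), unclass(m3)))
})

test_that("strict draws satisfy their subgroup's diagnostic bounds", {
  set.seed(9)
  for (i in 1:30) {
    m <- sample_metrics("HBR_B3.1", strict = TRUE, rules = rules)
    d <- derive_metrics(m)
    expect_gt(d$lw_ratio, 1.50)
    expect_gt(d$mesaxony, 0.7)
    expect_lt(m$total_div, 50)
    expect_lt(m$L, 15)
  }
  for (i in 1:30) {
    m4 <- sample_metrics("HBR_B4", strict = TRUE, rules = rules)
    expect_lt(m4$L, 10)
  }
})

test_that("measure o construct is the identity over random draws", {
  set.seed(31)
  ids <- names(rules$subgroups)
  need <- c("L", "W", "L_II", "L_III", "L_IV", "te", "alpha", "beta")
  worst <- 0
  for (i in 1:150) {
    sg <- sample(ids, 1)
    m <- sample_metrics(sg, strict = (i %% 2 == 0), rules = rules)
    lm <- construct_landmarks(m, side = sample(c("left", "right"), 1))
    m2 <- measure_track(lm)
    worst <- max(worst, max(abs(unlist(m2[need]) - unlist(m[need]))))
  }
  expect_lt(worst, 1e-6)
})

test_that("constructed sets have heel at origin and digit III along +y", {
  m <- sample_metrics("HBR_B2.2", strict = TRUE, rules = rules, seed = 4)
  lm <- construct_landmarks(m)
  expect_equal(unname(lm$points["heel", ]), c(0, 0))
  P <- (lm$points["hypex_II_III", ] + lm$points["hypex_III_IV", ]) / 2
  u3 <- lm$points["tip_III", ] - P
  expect_equal(unname(u3[1] / sqrt(sum(u3^2))), 0, tolerance = 1e-9)
  expect_gt(lm$points["tip_III", "y"], 0)  # tip III anterior of the heel
})

test_that("te = 0 requests give collinear digit tips", {
  mc <- consistent_metrics(L = 10, W = 7, te = 0, alpha = 30, beta = 30)
  lm <- construct_landmarks(mc)
  tips <- lm$points[c("tip_II", "tip_III", "tip_IV"), ]
  v1 <- tips[2, ] - tips[1, ]; v2 <- tips[3, ] - tips[1, ]
  expect_lt(unname(abs(v1[1] * v2[2] - v1[2] * v2[1])), 1e-8)
})

test_that("infeasible metric combinations are rejected with the constraint named", {
  bad_te <- track_metrics(L = 5, W = 4, L_II = 3, L_III = 4, L_IV = 3,
                          te = 6, alpha = 20, beta = 20)
  expect_error(construct_landmarks(bad_te), "te >= L")
  # lateral digits far too short to reach the required hypex depth
  deep <- track_metrics(L = 20, W = 10, L_II = 0.5, L_III = 16, L_IV = 0.5,
                        te = 2, alpha = 10, beta = 10)
  expect_error(construct_landmarks(deep), "infeasible")
  incomplete <- track_metrics(L = 10, W = 5)
  expect_error(construct_landmarks(incomplete), "incomplete")
})

test_that("wear severity 0 is the identity at grade 3; severity 1 bottoms out", {
  m <- sample_metrics("HBR_B3.2", strict = TRUE, rules = rules, seed = 12)
  lm <- construct_landmarks(m)
  w0 <- apply_wear(lm, wear_model(0), seed = 1)
  expect_identical(w0$points, lm$points)
  expect_identical(attr(w0, "preservation_grade"), 3)
  w1 <- apply_wear(lm, wear_model(1), seed = 1)
  expect_lte(attr(w1, "preservation_grade"), 0.5)
  expect_false(identical(w1$points, lm$points))
})

test_that("classification accuracy is monotone non-increasing in wear severity", {
  sev <- c(0, 0.25, 0.5, 0.75)
  acc <- vapply(seq_along(sev), function(k) {
    set.seed(500 + k)
    n <- 60
    ok <- 0
    for (i in 1:n) {
      m <- sample_metrics("HBR_B3.1", strict = TRUE, rules = rules)
      wl <- apply_wear(construct_landmarks(m), wear_model(sev[k]))
      rec <- track_record("w", metrics = measure_track(wl),
                          flags = profile_flags("HBR_B3.1"),
                          preservation_grade = attr(wl, "preservation_grade"))
      ok <- ok + isTRUE(classify_track(rec, rules)$subgroup == "HBR_B3.1")
    }
    ok / n
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("generated trackways recover the requested gait ratio", {
  for (seed in 1:10) {
    tw <- generate_trackway("HBR_B1.4", n_steps = 5, gait_ratio = 1.54,
                            step_width = 12, seed = seed, rules = rules)
    k <- estimate_trackway(tw)
    expect_equal(k$gait_ratio, 1.54, tolerance = 0.01 * 1.54)
  }
  straight <- generate_trackway("HBR_B2.1", n_steps = 4, gait_ratio = 1.2,
                                step_width = 0, seed = 3, rules = rules)
  g <- trackway_geometry(straight)
  expect_equal(g$pace_angulations, rep(180, 2))
  expect_equal(g$wap, rep(0, 2))
})

test_that("a forced mean track length of 34.16 cm at gait 1.54 gives a 2.10 m stride", {
  h <- hip_height(34.16)
  expect_equal(round(1.54 * h, 2), 2.10)
})

test_that("assemblages separate aligned from milling bearing models", {
  vm <- generate_assemblage(list(mixture = c(HBR_B2.1 = 1), n = 36,
                                 bearing_model = list(type = "vonmises",
                                                      mu = 220, kappa = 8)),
                            seed = 11, rules = rules)
  un <- generate_assemblage(list(mixture = c(HBR_B2.1 = 1), n = 36,
                                 bearing_model = list(type = "uniform")),
                            seed = 12, rules = rules)
  r_vm <- bearing_rose(vm$bearings)$rbar
  r_un <- bearing_rose(un$bearings)$rbar
  expect_gt(r_vm, 0.8)
  # null distribution of R-bar for uniform bearings at n = 36
  set.seed(99)
  null_rbar <- replicate(300, bearing_rose(runif(36, 0, 360))$rbar)
  expect_lt(r_un, quantile(null_rbar, 0.95))
  expect_gt(r_vm, quantile(null_rbar, 0.999))
})

test_that("generated assemblages are internally consistent and reproducible", {
  cfg <- list(mixture = c(HBR_B3.1 = 0.5, HBR_B2.2 = 0.5), n = 12,
              wear_severity = 0, bearing_model = list(type = "uniform"))
  a1 <- generate_assemblage(cfg, seed = 77, rules = rules)
  a2 <- generate_assemblage(cfg, seed = 77, rules = rules)
  expect_identical(a1$bearings$bearing_deg, a2$bearings$bearing_deg)
  expect_identical(length(a1$records), 12L)
  # zero-wear records carry no consistency findings
  findings <- unlist(lapply(a1$records, validate_record))
  expect_length(findings, 0)
  expect_identical(a1$manifest$seed, 77)
  # n = 0 still yields valid (empty) outputs
  dir0 <- withr::local_tempdir()
  a0 <- generate_assemblage(list(mixture = c(HBR_B4 = 1), n = 0,
                                 bearing_model = list(type = "uniform")),
                            seed = 1, dir = dir0, rules = rules)
  expect_identical(length(a0$records), 0L)
  expect_true(file.exists(file.path(dir0, "manifest.json")))
  expect_identical(nrow(utils::read.csv(file.path(dir0, "measurements.csv"))), 0L)
})
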