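# shared test fixtures, built in code

# a geometry-consistent metric set: digit lengths derived from the hypex
# depth so that the configuration is realizable (asym = 1 gives equal
# hypex depths; with alpha == beta that makes a mirror-symmetric track)
consistent_metrics <- function(L, W, te, alpha, beta, iii_frac = 0.65,
                               asym = 1) {
  L_III <- iii_frac * L
  stopifnot(L_III > te)
  depth <- L_III - te
  track_metrics(L = L, W = W,
                L_II = asym * depth / cos(alpha * pi / 180),
                L_III = L_III,
                L_IV = (2 - asym) * depth / cos(beta * pi / 180),
                te = te, alpha = alpha, beta = beta)
}

# hand-built landmark set with tips on an axis-aligned triangle
triangle_landmarks <- function() {
  landmark_set("tri", list(
    tip_II = c(-4, 0), tip_III = c(0, 5), tip_IV = c(4, 0),
    hypex_II_III = c(-1, -1), hypex_III_IV = c(1, -1),
    heel = c(0, -4)))
}

# the flag profile helper is internal; expose it for tests
profile_flags <- function(subgroup) hebtracks:::.subgroup_flag_profile(subgroup)

# record from sampled metrics with the subgroup's canonical flags
synthetic_record <- function(subgroup, strict = TRUE, grade = 2,
                             rules = hebridean_rules(), id = "syn") {
  m <- sample_metrics(subgroup, strict = strict, rules = rules)
  track_record(id, metrics = m, flags = profile_flags(subgroup),
               preservation_grade = grade, published_subgroup = subgroup)
}

fixture_records <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- hebtracks::hebridean_fixture()
    val
  }
})

fixture_table <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- hebtracks::hebridean_fixture("table")
    val
  }
})
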