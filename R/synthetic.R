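#' Sample track metrics for a morphotype subgroup
#'
#' Draws a complete, internally consistent set of track measurements
#' uniformly within the subgroup's diagnosed ranges (`strict = TRUE`
#' restricts to ranges nested inside them that are exclusive to the
#' subgroup given its flag profile). Consistency is enforced by
#' construction: W = L / (l/w), te = mesaxony x W, digit III length from
#' the III/L ratio, and the total divarication split into alpha and beta
#' by a uniform 0.42-0.58 fraction. The lateral (hypex-referenced) digit
#' lengths are placed geometrically: the hypex midpoint must sit at
#' depth L_III along the digit III axis, which fixes the combined hypex
#' depth, and a uniform 0.92-1.08 asymmetry factor splits it between
#' digits II and IV. The digit II/III and III/IV ratios are therefore
#' emergent, not sampled (hypex-referenced digit lengths are not
#' commensurate with published pad-inclusive digit lengths). By default
#' draws are rejected (and redrawn) until [construct_landmarks()]
#' succeeds on them, so every sampled metric set is geometrically
#' realizable.
#'
#' @param subgroup subgroup id (e.g. `"HBR_B3.1"`).
#' @param strict draw from the exclusive (strict) ranges.
#' @param rules a [hebridean_rules()] rule set.
#' @param seed optional integer seed (local RNG stream; the caller's
#'   stream is untouched).
#' @param ensure_feasible reject geometrically infeasible draws.
#' @return A [track_metrics()] object.
#' @export
sample_metrics <- function(subgroup, strict = FALSE,
                           rules = hebridean_rules(), seed = NULL,
                           ensure_feasible = TRUE) {
  sg <- rules$subgroups[[subgroup]]
  if (is.null(sg)) stop("unknown subgroup: ", subgroup)
  rng <- if (strict) sg$strict else sg$sample
  if (is.null(rng) || !length(rng)) stop("no sampling ranges for ", subgroup)
  draw1 <- function() {
    u <- function(nm) stats::runif(1, rng[[nm]][1], rng[[nm]][2])
    L <- u("L"); lw <- u("lw_ratio"); M <- u("mesaxony")
    div <- u("total_div"); iiiL <- u("iii_over_L")
    W <- L / lw
    te <- M * W
    L_III <- iiiL * L / 100
    frac <- stats::runif(1, 0.42, 0.58)
    alpha <- div * frac; beta <- div * (1 - frac)
    if (L_III <= te) return(NULL)  # central digit cannot be shallower than te
    # hypex depths: combined projection along the track axis must equal
    # L_III - te; an asymmetry factor splits it between digits II and IV
    a <- stats::runif(1, 0.92, 1.08)
    L_II <- a * (L_III - te) / cos(deg2rad(alpha))
    L_IV <- (2 - a) * (L_III - te) / cos(deg2rad(beta))
    track_metrics(L = L, W = W,
                  L_II = L_II, L_III = L_III, L_IV = L_IV,
                  te = te, alpha = alpha, beta = beta)
  }
  with_seed(seed, {
    for (i in 1:100) {
      m <- draw1()
      if (is.null(m)) next
      if (!ensure_feasible) return(m)
      ok <- tryCatch({ construct_landmarks(m); TRUE },
                     error = function(e) FALSE)
      if (ok) return(m)
    }
    stop("could not draw feasible metrics for ", subgroup,
         " after 100 attempts")
  })
}

# Closed-form solve for the landmark configuration realizing a metric
# set. Frame during solving: tip_III at the origin, the width line
# horizontal at y = -te, digit II on the +x side.
#
# With u3 the digit III axis direction at tilt phi from vertical, the
# interdigital angles force u2 = R(-alpha) u3 and u4 = R(+beta) u3, so
# the hypex midpoint is P = c - s(phi) where c is the width-line centre
# and s(phi) = (L2 u2 + L4 u4)/2. Requiring |tip_III - P| = L3 along u3
# reduces to one sinusoidal equation in phi:
#   (s_y0 - L3) cos(phi) - s_x0 sin(phi) + te = 0,
# solvable iff sqrt(s_x0^2 + (s_y0 - L3)^2) >= te. Both roots are tried
# and the one that reproduces the metrics is kept.
.solve_landmarks <- function(m) {
  W <- m$W; te <- m$te; L2 <- m$L_II; L3 <- m$L_III; L4 <- m$L_IV
  a_r <- deg2rad(m$alpha); b_r <- deg2rad(m$beta)
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s_x0 <- (L2 * sin(a_r) - L4 * sin(b_r)) / 2
  s_y0 <- (L2 * cos(a_r) + L4 * cos(b_r)) / 2
  R0 <- sqrt(s_x0^2 + (s_y0 - L3)^2)
  if (R0 < 1e-9) {
    phis <- if (te <= 1e-9) 0 else numeric(0)
  } else {
    if (R0 < te - 1e-9) return(NULL)
    delta <- atan2(s_x0, s_y0 - L3)
    base <- acos(max(-1, min(1, -te / R0)))
    phis <- c(base - delta, -base - delta)
    phis <- wrap180(rad2deg(phis)) * pi / 180
    # reject non-anatomical solutions: the digit III axis must stay
    # within 60 degrees of the anterior normal of the width line
    phis <- phis[abs(phis) <= pi / 3]
  }
  for (phi in phis) {
    u3 <- c(sin(phi), cos(phi))
    u2 <- drop(rot(-a_r) %*% u3)
    u4 <- drop(rot(b_r) %*% u3)
    s <- (L2 * u2 + L4 * u4) / 2
    t_ <- s[1L] - L3 * sin(phi)
    cy <- s[2L] - L3 * cos(phi)
    if (abs(cy + te) > 1e-8) next
    tip2 <- c(t_ + W / 2, -te); tip4 <- c(t_ - W / 2, -te)
    h23 <- tip2 - L2 * u2; h34 <- tip4 - L4 * u4
    P <- (h23 + h34) / 2
    if (abs(vnorm(P) - L3) > 1e-8) next
    # orientation check: digit II must sit on the tip_II side of the axis
    if (cross2(u3, u2) > 1e-12 || cross2(u4, u3) > 1e-12) next
    return(list(tip_II = tip2, tip_III = c(0, 0), tip_IV = tip4,
                hypex_II_III = h23, hypex_III_IV = h34,
                u2 = u2, u4 = u4))
  }
  NULL
}

#' Construct a landmark set realizing given metrics
#'
#' The geometric inverse of [measure_track()]: builds a labelled landmark
#' configuration whose measurements equal the input metrics to within
#' 1e-6 (cm / degrees). The construction places the heel at the origin
#' with digit III pointing along +y; the digit II side realizes the
#' requested footedness (digit II is the inner digit: on the left of the
#' axis for a right foot). The heel is placed on the divarication
#' bisector at the distance that realizes L exactly.
#'
#' @param metrics a complete [track_metrics()] object (all of L, W,
#'   L_II, L_III, L_IV, te, alpha, beta non-missing).
#' @param side `"right"` (default) or `"left"`.
#' @param track_id id for the resulting landmark set.
#' @return A [landmark_set()].
#' @export
construct_landmarks <- function(metrics, side = c("right", "left"),
                                track_id = "synthetic") {
  stopifnot(inherits(metrics, "track_metrics"))
  side <- match.arg(side)
  need <- c("L", "W", "L_II", "L_III", "L_IV", "te", "alpha", "beta")
  vals <- unlist(metrics[need])
  if (any(is.na(vals)))
    stop("metrics incomplete: missing ",
         paste(need[is.na(vals)], collapse = ", "))
  if (metrics$te >= metrics$L)
    stop("infeasible metrics: te >= L (toe extension exceeds track length)")
  if (any(vals[c("L", "W", "L_II", "L_III", "L_IV")] <= 0))
    stop("infeasible metrics: non-positive length")
  sol <- .solve_landmarks(metrics)
  if (is.null(sol))
    stop("geometrically infeasible metric combination: ",
         "no landmark configuration realizes W, te, digit lengths and ",
         "interdigital angles simultaneously")
  bis <- unitv(unitv(sol$u2) + unitv(sol$u4))
  heel <- sol$tip_III - metrics$L * bis
  pts <- rbind(tip_II = sol$tip_II, tip_III = sol$tip_III,
               tip_IV = sol$tip_IV,
               hypex_II_III = sol$hypex_II_III,
               hypex_III_IV = sol$hypex_III_IV,
               heel = heel)
  # rotate so the digit III axis points along +y, then shift heel to origin
  P <- (pts["hypex_II_III", ] + pts["hypex_III_IV", ]) / 2
  u3 <- unitv(pts["tip_III", ] - P)
  ang <- atan2(u3[1L], u3[2L])   # rotation taking u3 to (0, 1)
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  pts <- pts %*% t(Rm)
  pts <- sweep(pts, 2L, pts["heel", ])
  if (side == "right") pts[, 1L] <- -pts[, 1L]  # digit II medial
  colnames(pts) <- c("x", "y")
  lm <- landmark_set(track_id, pts, side_observed = side,
                     relief = "negative")
  chk <- suppressWarnings(measure_track(lm))
  dev <- max(abs(unlist(chk[need]) - vals))
  if (dev > 1e-6)
    stop("geometrically infeasible metric combination ",
         sprintf("(residual %.2e after construction)", dev))
  lm
}

#' Wear models
#'
#' Parametric model of preservation loss used to degrade synthetic
#' landmark sets: Gaussian landmark jitter, inward erosion of the digit
#' tips, random dropout of optional landmarks, and a monotone map from
#' wear severity to preservation grade. Severity 0 is the identity
#' (grade 3); severity 1 collapses to grade 0.5, the grade at which
#' morphology is in practice too effaced to characterize - the default
#' magnitudes (about 1 cm of margin loss and 0.4 cm of landmark
#' uncertainty at full severity) are chosen to match that meaning on the
#' tiny-to-small tracks where wear matters most.
#'
#' @param severity wear severity in 0-1.
#' @param landmark_jitter_sd jitter standard deviation, cm.
#' @param margin_erosion inward displacement of digit tips, cm.
#' @param dropout_prob per-optional-landmark dropout probability.
#' @return An object of class `wear_model`.
#' @export
wear_model <- function(severity,
                       landmark_jitter_sd = 0.4 * severity,
                       margin_erosion = 1.0 * severity,
                       dropout_prob = 0.5 * severity) {
  stopifnot(severity >= 0, severity <= 1)
  structure(list(severity = severity,
                 landmark_jitter_sd = landmark_jitter_sd,
                 margin_erosion = margin_erosion,
                 dropout_prob = dropout_prob),
            class = "wear_model")
}

# monotone non-increasing severity -> grade map, 0.5 steps
.wear_grade <- function(severity) {
  g <- 3 - 2.5 * severity
  max(0.5, round(g * 2) / 2)
}

#' Apply wear to a landmark set
#'
#' @param lm a [landmark_set()].
#' @param model a [wear_model()].
#' @param seed optional integer seed.
#' @return The worn [landmark_set()] with attribute
#'   `"preservation_grade"`.
#' @export
apply_wear <- function(lm, model, seed = NULL) {
  stopifnot(inherits(lm, "landmark_set"), inherits(model, "wear_model"))
  if (model$severity == 0) {
    attr(lm, "preservation_grade") <- 3
    return(lm)
  }
  with_seed(seed, {
    pts <- lm$points
    centroid <- colMeans(pts[intersect(.lm_required, rownames(pts)), ,
                             drop = FALSE])
    tips <- intersect(c("tip_II", "tip_III", "tip_IV"), rownames(pts))
    for (tp in tips) {
      v <- centroid - pts[tp, ]
      d <- vnorm(v)
      if (d > 1e-9)
        pts[tp, ] <- pts[tp, ] + v / d * min(model$margin_erosion, 0.5 * d)
    }
    pts <- pts + matrix(stats::rnorm(length(pts), 0,
                                     model$landmark_jitter_sd),
                        nrow(pts), 2L)
    keep_opt <- rownames(pts) %in% .lm_required |
      stats::runif(nrow(pts)) >= model$dropout_prob
    pts <- pts[keep_opt, , drop = FALSE]
    out <- landmark_set(lm$track_id, pts, side_observed = lm$side_observed,
                        relief = lm$relief)
    attr(out, "preservation_grade") <- .wear_grade(model$severity)
    out
  })
}

#' Generate a synthetic trackway
#'
#' Builds an ordered trackway for a trackmaker of a given subgroup moving
#' at a target gait ratio: per-track lengths are drawn from the subgroup
#' range (with a few percent step-to-step variation), hip height follows
#' h = 4L, the stride is gait x h, and alternating feet are offset
#' laterally by `step_width`. At zero step width the trackway is
#' perfectly straight (pace angulation 180 degrees) and
#' [estimate_trackway()] recovers the gait ratio exactly.
#'
#' @param subgroup subgroup id.
#' @param n_steps number of tracks (>= 2).
#' @param gait_ratio target stride / hip-height ratio.
#' @param step_width lateral offset between left and right feet, cm.
#' @param seed optional integer seed.
#' @param rules a [hebridean_rules()] rule set.
#' @return A [trackway_sequence()].
#' @export
generate_trackway <- function(subgroup, n_steps, gait_ratio,
                              step_width = 0, seed = NULL,
                              rules = hebridean_rules()) {
  stopifnot(n_steps >= 2, gait_ratio > 0)
  sg <- rules$subgroups[[subgroup]]
  if (is.null(sg)) stop("unknown subgroup: ", subgroup)
  with_seed(seed, {
    Lbase <- stats::runif(1, sg$sample$L[1], sg$sample$L[2])
    Ls <- Lbase * (1 + stats::runif(n_steps, -0.03, 0.03))
    lambda_m <- gait_ratio * 4 * mean(Ls) / 100
    y <- (seq_len(n_steps) - 1L) * lambda_m * 100 / 2
    x <- ifelse(seq_len(n_steps) %% 2L == 1L, -step_width / 2, step_width / 2)
    feet <- ifelse(seq_len(n_steps) %% 2L == 1L, "left", "right")
    trackway_sequence(
      paste0("sim-", subgroup),
      data.frame(track_id = sprintf("sim-%02d", seq_len(n_steps)),
                 foot = feet, x_cm = x, y_cm = y,
                 axis_bearing_deg = 0, L_cm = Ls),
      surface_frame_note = "simulated, +y = travel direction")
  })
}

# sample from a von Mises distribution (Best & Fisher 1979 rejection)
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        theta <- sign(u3 - 0.5) * acos(f)
        out[i] <- wrap360(mu_deg + rad2deg(theta))
        break
      }
    }
  }
  out
}

#' Generate a synthetic track assemblage
#'
#' End-to-end fixture factory: draws tracks from a mixture of morphotype
#' subgroups, constructs their landmark sets, applies a wear model, and
#' assigns surface bearings from either a von Mises model (aligned,
#' "gregarious" movement) or a uniform model (disorganized "milling").
#' Optionally serializes everything (landmark file, measurement table,
#' bearings file, manifest) to a directory in the package interchange
#' formats.
#'
#' @param config list with elements `mixture` (named weights over
#'   subgroup ids, summing to 1), `n` (number of tracks), `wear_severity`
#'   (0-1, default 0), `strict` (draw from exclusive ranges, default
#'   TRUE), and `bearing_model` (list with `type` = "vonmises" or
#'   "uniform", and for vonmises `mu` and `kappa`).
#' @param seed integer seed (required for a reproducible manifest).
#' @param dir optional output directory; created if needed.
#' @param rules a [hebridean_rules()] rule set.
#' @return list with `records` (track records, flags taken from each
#'   subgroup's profile), `landmarks`, `bearings` (data.frame), and
#'   `manifest` (all parameters + seed). When `dir` is given, files
#'   `landmarks.csv`, `measurements.csv`, `bearings.csv` and
#'   `manifest.json` are written there.
#' @export
generate_assemblage <- function(config, seed = NULL, dir = NULL,
                                rules = hebridean_rules()) {
  mix <- config$mixture
  if (is.null(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("config$mixture must be non-negative weights summing to 1")
  n <- config$n %||% 0L
  sev <- config$wear_severity %||% 0
  strict <- config$strict %||% TRUE
  bm <- config$bearing_model %||% list(type = "uniform")
  wm <- wear_model(sev)
  with_seed(seed, {
    subgroups <- if (n > 0)
      sample(names(mix), n, replace = TRUE, prob = mix) else character(0)
    bearings <- if (n == 0) numeric(0)
      else if (identical(bm$type, "vonmises"))
        rvonmises(n, bm$mu %||% 0, bm$kappa %||% 4)
      else stats::runif(n, 0, 360)
    records <- vector("list", n)
    landmarks <- vector("list", n)
    for (i in seq_len(n)) {
      sgid <- subgroups[i]
      m <- sample_metrics(sgid, strict = strict, rules = rules)
      side <- sample(c("left", "right"), 1L)
      lm0 <- construct_landmarks(m, side = side,
                                 track_id = sprintf("sim-%04d", i))
      lm <- apply_wear(lm0, wm)
      grade <- attr(lm, "preservation_grade") %||% 3
      mm <- if (is_complete_landmarks(lm)) measure_track(lm) else m
      records[[i]] <- track_record(
        specimen_id = lm$track_id,
        metrics = mm,
        flags = .subgroup_flag_profile(sgid),
        preservation_grade = grade,
        side_observed = side,
        locality = "simulated",
        bearing = bearings[i],
        published_subgroup = sgid)
      landmarks[[i]] <- lm
    }
    manifest <- list(generator = "generate_assemblage",
                     package_version = as.character(
                       utils::packageVersion("hebtracks")),
                     rules_version = rules$version,
                     seed = seed, n = n, mixture = as.list(mix),
                     wear_severity = sev, strict = strict,
                     bearing_model = bm)
    out <- list(records = records, landmarks = landmarks,
                bearings = data.frame(
                  surface_id = rep("simulated", n),
                  track_id = vapply(landmarks, function(l) l$track_id,
                                    character(1)),
                  bearing_deg = bearings),
                manifest = manifest)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      if (n > 0) write_landmark_file(landmarks, file.path(dir, "landmarks.csv"))
      write_measurement_table(records, file.path(dir, "measurements.csv"))
      utils::write.csv(out$bearings, file.path(dir, "bearings.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    out
  })
}

# canonical flag profile per subgroup (used for synthetic records)
.subgroup_flag_profile <- function(subgroup) {
  switch(subgroup,
    "HBR_B1.1" = morphology_flags(digit_shape = "parallel_sided",
                                  hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B1.2" = morphology_flags(digit_shape = "sub_parallel",
                                  hallux = "anterolateral",
                                  heel_impressed = TRUE),
    "HBR_B1.3" = morphology_flags(digit_shape = "sub_parallel",
                                  hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B1.4" = morphology_flags(digit_shape = "parallel_sided",
                                  hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B2.1" = morphology_flags(digit_shape = "spindle", hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B2.2" = morphology_flags(digit_shape = "spindle", hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B2.3" = morphology_flags(digit_shape = "broad_round",
                                  hallux = "absent",
                                  inner_margins_present = TRUE),
    "HBR_B3.1" = morphology_flags(digit_shape = "gracile", hallux = "absent",
                                  digits_well_separated = FALSE),
    "HBR_B3.2" = morphology_flags(digit_shape = "gracile", hallux = "absent",
                                  digits_well_separated = TRUE),
    "HBR_B4" = morphology_flags(digit_shape = "gracile", hallux = "absent",
                                digits_well_separated = FALSE),
    morphology_flags())
}
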