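#' Trackway sequences
#'
#' An ordered sequence of track reference points (the intersection point,
#' IP, of each track's length and width lines) in a common planar surface
#' frame, with the foot (left/right), total track length and optionally
#' the long-axis bearing of each track. Two-track sequences are accepted
#' as track associations (pace or stride only); kinematic estimation
#' needs at least three tracks.
#'
#' @param trackway_id character identifier.
#' @param steps data.frame with columns `track_id`, `foot` ("left" /
#'   "right"), `x_cm`, `y_cm`, and optionally `axis_bearing_deg` (track
#'   long-axis bearing in the surface frame, degrees) and `L_cm` (total
#'   track length).
#' @param surface_frame_note free-text note on the frame (e.g.
#'   "hypothetical north").
#' @return An object of class `trackway_sequence`.
#' @export
trackway_sequence <- function(trackway_id, steps, surface_frame_note = NA) {
  steps <- as.data.frame(steps)
  need <- c("track_id", "foot", "x_cm", "y_cm")
  if (!all(need %in% names(steps)))
    stop("steps must have columns: ", paste(need, collapse = ", "))
  if (nrow(steps) < 2L)
    stop("sequence too short: need at least 2 steps")
  if (!all(steps$foot %in% c("left", "right")))
    stop("foot must be 'left' or 'right'")
  if (!all(is.finite(steps$x_cm)) || !all(is.finite(steps$y_cm)))
    stop("step coordinates must be finite")
  if (is.null(steps$axis_bearing_deg)) steps$axis_bearing_deg <- NA_real_
  if (is.null(steps$L_cm)) steps$L_cm <- NA_real_
  alternating <- all(steps$foot[-1L] != steps$foot[-nrow(steps)])
  structure(list(trackway_id = as.character(trackway_id),
                 steps = steps,
                 feet_alternate = alternating,
                 surface_frame_note = surface_frame_note),
            class = "trackway_sequence")
}

#' Read a trackway file
#'
#' Delimited text, one step per row:
#' `trackway_id, track_id, foot, x_cm, y_cm, axis_bearing_deg, L_cm`
#' ("n/a" marks missing bearings/lengths).
#'
#' @param path file path.
#' @return a named list of [trackway_sequence()] objects.
#' @export
read_trackway_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "n/a")
  need <- c("trackway_id", "track_id", "foot", "x_cm", "y_cm",
            "axis_bearing_deg", "L_cm")
  if (!all(need %in% names(df)))
    stop("trackway file header must contain: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$trackway_id), function(d)
    trackway_sequence(d$trackway_id[1L], d[, -1L]))
  out[unique(df$trackway_id)]
}

#' Trackway geometry
#'
#' From n ordered reference points computes the n-1 paces (distance
#' between consecutive tracks, alternate feet), n-2 strides (distance
#' between successive same-foot tracks), n-2 widths of the pes angulation
#' pattern (WAP: the perpendicular distance from a middle track's
#' reference point to the stride line through its neighbours), n-2 pace
#' angulations (the interior angle between consecutive pace segments,
#' 180 degrees for a perfectly straight zero-width trackway), and - when
#' axis bearings are supplied - the rotation angle of each track relative
#' to the trackway midline (drawn through the midpoints of the pace
#' lines), signed positive outward (toes away from the midline).
#'
#' Distances follow the reporting convention of trackway tables: paces
#' and strides in metres, WAP in cm.
#'
#' @param seq a [trackway_sequence()].
#' @return An object of class `trackway_metrics`: list with `paces` (m),
#'   `strides` (m), `wap` (cm), `pace_angulations` (deg),
#'   `rotation_angles` (deg, positive outward, NA where no bearing),
#'   `mean_L` (cm), `feet_alternate`.
#' @export
trackway_geometry <- function(seq) {
  stopifnot(inherits(seq, "trackway_sequence"))
  st <- seq$steps
  n <- nrow(st)
  if (n < 2L) stop("sequence too short")
  if (!seq$feet_alternate)
    warning("feet do not strictly alternate; paces computed but flagged")
  P <- cbind(st$x_cm, st$y_cm)

  paces_cm <- sqrt(rowSums((P[-1L, , drop = FALSE] -
                            P[-n, , drop = FALSE])^2))
  strides_cm <- if (n >= 3L)
    sqrt(rowSums((P[-(1:2), , drop = FALSE] -
                  P[seq_len(n - 2L), , drop = FALSE])^2)) else numeric(0)

  wap_cm <- numeric(0)
  gamma <- numeric(0)
  if (n >= 3L) {
    wap_cm <- gamma <- numeric(n - 2L)
    for (i in seq_len(n - 2L)) {
      a <- P[i, ]; b <- P[i + 1L, ]; c <- P[i + 2L, ]
      stride_v <- c - a
      wap_cm[i] <- abs(cross2(stride_v, b - a)) / vnorm(stride_v)
      gamma[i] <- angle_between(a - b, c - b)
    }
  }

  # trackway midline: polyline through pace-line midpoints
  rot <- rep(NA_real_, n)
  if (n >= 3L && any(!is.na(st$axis_bearing_deg))) {
    mids <- (P[-1L, , drop = FALSE] + P[-n, , drop = FALSE]) / 2
    for (i in seq_len(n)) {
      if (is.na(st$axis_bearing_deg[i])) next
      # nearest midline segment to step i
      j <- min(max(i - 1L, 1L), nrow(mids) - 1L)
      d <- mids[j + 1L, ] - mids[j, ]
      if (vnorm(d) < 1e-12) next
      tml_bearing <- rad2deg(atan2(d[1L], d[2L]))
      delta <- wrap180(st$axis_bearing_deg[i] - tml_bearing)
      side <- sign(cross2(d, P[i, ] - mids[j, ]))  # >0: left of midline
      # positive outward: deviation toward the track's own side
      rot[i] <- if (side == 0) abs(delta) else delta * (-side)
    }
  }

  structure(list(trackway_id = seq$trackway_id,
                 paces = paces_cm / 100,
                 strides = strides_cm / 100,
                 wap = wap_cm,
                 pace_angulations = gamma,
                 rotation_angles = rot,
                 mean_L = if (all(is.na(st$L_cm))) NA_real_
                          else mean(st$L_cm, na.rm = TRUE),
                 feet_alternate = seq$feet_alternate),
            class = "trackway_metrics")
}

#' @export
print.trackway_metrics <- function(x, ...) {
  cat("<trackway_metrics> ", x$trackway_id, "\n", sep = "")
  cat("  paces (m):          ", paste(round(x$paces, 3), collapse = ", "), "\n")
  cat("  strides (m):        ", paste(round(x$strides, 3), collapse = ", "), "\n")
  cat("  WAP (cm):           ", paste(round(x$wap, 2), collapse = ", "), "\n")
  cat("  pace angulation:    ", paste(round(x$pace_angulations, 2),
                                      collapse = ", "), "\n")
  cat("  rotation (deg, +out):", paste(round(x$rotation_angles, 2),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Trackmaker hip height from track length
#'
#' The standard morphometric estimate: hip height h = 4 x track length.
#'
#' @param FL track length (for a trackway, the mean track length), cm.
#' @return hip height in metres.
#' @export
hip_height <- function(FL) {
  if (any(is.na(FL)) || any(FL <= 0)) stop("FL must be positive")
  4 * FL / 100
}

#' Trackmaker velocity from stride and hip height
#'
#' Dimensional-analysis speed estimate
#' V = c * g^0.5 * lambda^1.67 * h^-1.17 with g = 9.81 m s^-2 and
#' c = 0.25 (the classical Alexander coefficient) or c = 0.226 (the
#' Ruiz & Torices recalibration). The two variants differ by the exact
#' factor 0.226/0.25 = 0.904 for all inputs.
#'
#' @param lambda stride length, m (>= 0).
#' @param h hip height, m (> 0).
#' @param variant `"alexander"` or `"ruiz_torices"`.
#' @return velocity in m s^-1.
#' @export
track_velocity <- function(lambda, h, variant = c("alexander", "ruiz_torices")) {
  variant <- match.arg(variant)
  if (any(is.na(h)) || any(h <= 0)) stop("hip height must be positive")
  if (any(is.na(lambda)) || any(lambda < 0)) stop("stride must be non-negative")
  cc <- if (variant == "alexander") 0.25 else 0.226
  g <- 9.81
  cc * sqrt(g) * lambda^1.67 * h^-1.17
}

#' Gait ratio and category
#'
#' Relative stride lambda / h. Below 2.0 is interpreted as walking,
#' above 2.0 as running; exactly 2.0 is reported as the boundary.
#'
#' @param lambda stride length, m.
#' @param h hip height, m (> 0).
#' @return list with `gait_ratio` and `gait_category`
#'   ("walking" / "running" / "boundary").
#' @export
gait <- function(lambda, h) {
  if (any(is.na(h)) || any(h <= 0)) stop("hip height must be positive")
  r <- lambda / h
  cat_ <- ifelse(r < 2, "walking", ifelse(r > 2, "running", "boundary"))
  list(gait_ratio = r, gait_category = cat_)
}

#' Kinematic estimates for a trackway
#'
#' Combines the trackway geometry with the trackmaker equations: hip
#' height from the mean track length, velocity (both coefficient
#' variants) and gait ratio from the mean stride. All estimates are
#' computed from unrounded intermediates; rounding is a display concern
#' only.
#'
#' @param seq a [trackway_sequence()] with >= 3 steps and track lengths.
#' @return An object of class `kinematic_estimates`: `hip_height` (m),
#'   `velocity_alexander`, `velocity_rt` (m s^-1), `gait_ratio`,
#'   `gait_category`, plus `mean_L` (cm) and `mean_stride` (m).
#' @export
estimate_trackway <- function(seq) {
  stopifnot(inherits(seq, "trackway_sequence"))
  if (nrow(seq$steps) < 3L)
    stop("no stride measurable: need at least 3 steps")
  tm <- trackway_geometry(seq)
  if (!length(tm$strides))
    stop("no stride measurable")
  if (is.na(tm$mean_L))
    stop("track lengths missing: cannot estimate hip height")
  FL <- tm$mean_L
  h <- hip_height(FL)
  lambda <- mean(tm$strides)
  g <- gait(lambda, h)
  structure(list(trackway_id = seq$trackway_id,
                 mean_L = FL,
                 mean_stride = lambda,
                 hip_height = h,
                 velocity_alexander = track_velocity(lambda, h, "alexander"),
                 velocity_rt = track_velocity(lambda, h, "ruiz_torices"),
                 gait_ratio = g$gait_ratio,
                 gait_category = g$gait_category,
                 geometry = tm),
            class = "kinematic_estimates")
}

#' @export
print.kinematic_estimates <- function(x, ...) {
  cat("<kinematic_estimates> ", x$trackway_id, "\n", sep = "")
  cat(sprintf("  mean track length: %.2f cm -> hip height %.2f m\n",
              x$mean_L, x$hip_height))
  cat(sprintf("  mean stride: %.2f m\n", x$mean_stride))
  cat(sprintf("  velocity: %.2f m/s (Alexander), %.2f m/s (Ruiz-Torices)\n",
              x$velocity_alexander, x$velocity_rt))
  cat(sprintf("  gait: %.2f (%s)\n", x$gait_ratio, x$gait_category))
  invisible(x)
}
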