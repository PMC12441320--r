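#' Landmark sets for tridactyl tracks
#'
#' A landmark set is the raw observational unit of the package: a small
#' labelled 2D point configuration (in cm, arbitrary planar origin)
#' digitized from a footprint outline or orthophoto. The required labels
#' describe a tridactyl (three-toed) pes track: the three digit tips
#' (`tip_II`, `tip_III`, `tip_IV`, with digit III central), the two
#' hypexes (interdigital notches `hypex_II_III`, `hypex_III_IV`) and the
#' `heel`. Optional labels record a hallux (digit I) impression
#' (`hallux_tip`, `hallux_base`) and lateral margin points (`lat_II`,
#' `lat_IV`). Digit tips are digitized at the digit pad terminus: claw
#' (ungual) marks are excluded from length measurements by convention,
#' so no ungual landmark exists.
#'
#' @param track_id character identifier.
#' @param points a two-column numeric matrix (or data.frame) of x/y
#'   coordinates in cm with rownames giving the labels, or a named list of
#'   length-2 numeric vectors.
#' @param side_observed `"left"`, `"right"` or `"indeterminate"`: the
#'   apparent footedness as seen on the surface.
#' @param relief `"negative"` (concave impression) or `"positive"`
#'   (convex infill cast).
#' @return An object of class `landmark_set`.
#' @seealso [measure_track()], [construct_landmarks()], [read_landmark_file()]
#' @export
landmark_set <- function(track_id, points,
                         side_observed = c("indeterminate", "left", "right"),
                         relief = c("negative", "positive")) {
  side_observed <- match.arg(side_observed)
  relief <- match.arg(relief)
  if (is.list(points) && !is.data.frame(points)) {
    labs <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- labs
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("landmark points must have two columns (x, y)")
  if (is.null(rownames(points))) stop("landmark points must be labelled")
  colnames(points) <- c("x", "y")
  bad <- setdiff(rownames(points),
                 c(.lm_required, .lm_optional,
                   grep("^ext_", rownames(points), value = TRUE)))
  if (length(bad))
    stop("unknown landmark label(s): ", paste(bad, collapse = ", "),
         " (use an 'ext_' prefix for extensions)")
  if (anyDuplicated(rownames(points)))
    stop("duplicated landmark labels")
  if (!all(is.finite(points)))
    stop("landmark coordinates must be finite")
  structure(list(track_id = as.character(track_id),
                 side_observed = side_observed,
                 relief = relief,
                 points = points),
            class = "landmark_set")
}

.lm_required <- c("tip_II", "tip_III", "tip_IV",
                  "hypex_II_III", "hypex_III_IV", "heel")
.lm_optional <- c("hallux_tip", "hallux_base", "lat_II", "lat_IV")

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$track_id,
      "  (", x$side_observed, ", ", x$relief, " relief, ",
      nrow(x$points), " points)\n", sep = "")
  print(round(x$points, 3))
  invisible(x)
}

#' Is a landmark set complete?
#'
#' Complete means all six required tridactyl labels are present.
#' @param lm a [landmark_set()].
#' @return logical.
#' @export
is_complete_landmarks <- function(lm) {
  all(.lm_required %in% rownames(lm$points))
}

#' Measure a tridactyl track from its landmarks
#'
#' Converts a labelled landmark set into the standard track measurements:
#'
#' * `L` - total track length, measured from the heel to digit tip III
#'   along the track axis (the bisector of the total divarication);
#' * `W` - track width, the straight-line distance between the tips of
#'   digits II and IV (the anterior-triangle base);
#' * `L_II`, `L_III`, `L_IV` - digit lengths along each digit axis. The
#'   digit axis runs from the digit's proximal reference point to its tip:
#'   for digit II the II-III hypex, for digit IV the III-IV hypex, and for
#'   digit III the midpoint of the two hypexes;
#' * `te` - toe extension of digit III: the perpendicular distance from
#'   tip III to the line through tips II and IV (the anterior-triangle
#'   height, numerator of the mesaxony ratio te/W);
#' * `alpha`, `beta` - interdigital (divarication) angles between the
#'   digit II and III axes, and the digit III and IV axes;
#' * `total_div` - total divarication II-IV, `alpha + beta` by
#'   construction.
#'
#' Hallux landmarks, if present, never contribute to `L`. Claw marks are
#' excluded by the landmarking convention (tips are digitized at the pad
#' terminus).
#'
#' @param lm a [landmark_set()].
#' @param collinear_tol tolerance (cm) below which the three digit tips
#'   are treated as collinear, giving `te = 0` with a warning.
#' @return A [track_metrics()] object.
#' @export
measure_track <- function(lm, collinear_tol = 1e-8) {
  stopifnot(inherits(lm, "landmark_set"))
  missing_labs <- setdiff(.lm_required, rownames(lm$points))
  if (length(missing_labs))
    stop(structure(class = c("hebtracks_incomplete_landmarks",
                             "error", "condition"),
                   list(message = paste0("incomplete landmark set: missing ",
                                         paste(missing_labs, collapse = ", ")),
                        call = sys.call(-1),
                        missing = missing_labs)))
  p <- lm$points
  req <- p[.lm_required, , drop = FALSE]
  dd <- as.matrix(stats::dist(req))
  if (any(dd[upper.tri(dd)] < 1e-9))
    stop("degenerate landmark set: coincident required points")

  tip2 <- p["tip_II", ]; tip3 <- p["tip_III", ]; tip4 <- p["tip_IV", ]
  h23 <- p["hypex_II_III", ]; h34 <- p["hypex_III_IV", ]
  heel <- p["heel", ]

  u2 <- tip2 - h23
  u4 <- tip4 - h34
  prox3 <- (h23 + h34) / 2
  u3 <- tip3 - prox3

  L_II <- vnorm(u2); L_III <- vnorm(u3); L_IV <- vnorm(u4)
  alpha <- angle_between(u2, u3)
  beta <- angle_between(u3, u4)
  W <- vnorm(tip2 - tip4)

  base <- tip4 - tip2
  if (vnorm(base) < 1e-12) stop("degenerate width line: tips II and IV coincide")
  te <- abs(cross2(base, tip3 - tip2)) / vnorm(base)
  if (te < collinear_tol) {
    warning("digit tips are collinear within tolerance; te set to 0")
    te <- 0
  }

  bisector <- unitv(unitv(u2) + unitv(u4))
  L <- sum((tip3 - heel) * bisector)

  track_metrics(L = L, W = W, L_II = L_II, L_III = L_III, L_IV = L_IV,
                te = te, alpha = alpha, beta = beta)
}

#' Read / write landmark files
#'
#' The landmark interchange format is a flat delimited text file in long
#' form, one landmark per row, with columns
#' `track_id, side_observed, relief, label, x_cm, y_cm`. A single file may
#' hold many tracks. Unknown labels are rejected unless prefixed `ext_`.
#'
#' @param path file path.
#' @return `read_landmark_file()`: a named list of [landmark_set()]
#'   objects, keyed by `track_id`.
#' @export
read_landmark_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "side_observed", "relief", "label", "x_cm", "y_cm")
  if (!identical(names(df)[seq_along(need)], need))
    stop("landmark file header must be: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$track_id), function(d) {
    pts <- as.matrix(d[, c("x_cm", "y_cm")])
    rownames(pts) <- d$label
    landmark_set(d$track_id[1L], pts,
                 side_observed = d$side_observed[1L],
                 relief = d$relief[1L])
  })
  out[unique(df$track_id)]
}

#' @rdname read_landmark_file
#' @param landmarks a list of [landmark_set()] objects (or a single one).
#' @export
write_landmark_file <- function(landmarks, path) {
  if (inherits(landmarks, "landmark_set")) landmarks <- list(landmarks)
  rows <- lapply(landmarks, function(lm) {
    data.frame(track_id = lm$track_id,
               side_observed = lm$side_observed,
               relief = lm$relief,
               label = rownames(lm$points),
               x_cm = lm$points[, "x"],
               y_cm = lm$points[, "y"],
               row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
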