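#' Track measurements
#'
#' Container for the primary measurements of a single tridactyl track.
#' All lengths are in cm and angles in degrees; any field may be `NA`
#' (explicitly missing - operations propagate missingness, never
#' zero-fill). `total_div` is always `alpha + beta` when both are
#' defined.
#'
#' @param L total track length (heel to digit III tip, claw marks
#'   excluded), cm.
#' @param W track width (tip II to tip IV), cm.
#' @param L_II,L_III,L_IV digit lengths, cm.
#' @param te digit III toe extension (anterior-triangle height), cm.
#' @param alpha interdigital angle digits II-III, degrees.
#' @param beta interdigital angle digits III-IV, degrees.
#' @param total_div total divarication II-IV, degrees. Defaults to
#'   `alpha + beta`; can be supplied independently (e.g. when transcribing
#'   a table that reports it with the component angles missing), in which
#'   case [validate_record()] cross-checks the sum.
#' @return An object of class `track_metrics`.
#' @export
track_metrics <- function(L = NA, W = NA, L_II = NA, L_III = NA, L_IV = NA,
                          te = NA, alpha = NA, beta = NA, total_div = NA) {
  m <- list(L = num_or_na(L), W = num_or_na(W),
            L_II = num_or_na(L_II), L_III = num_or_na(L_III),
            L_IV = num_or_na(L_IV), te = num_or_na(te),
            alpha = num_or_na(alpha), beta = num_or_na(beta),
            total_div = num_or_na(total_div))
  for (f in names(m))
    if (!is.na(m[[f]]) && m[[f]] < 0)
      stop("track metric '", f, "' must be non-negative")
  if (is.na(m$total_div) && !is.na(m$alpha) && !is.na(m$beta))
    m$total_div <- m$alpha + m$beta
  structure(m, class = "track_metrics")
}

#' @export
print.track_metrics <- function(x, ...) {
  v <- unlist(x)
  cat("<track_metrics>\n")
  print(round(v, 3))
  invisible(x)
}

#' Derived track ratios
#'
#' Computes the dimensionless descriptors used throughout the morphotype
#' scheme from raw measurements: length-to-width ratio `L/W`; digit
#' length ratios III/II and III/IV; digit III as a percentage of total
#' track length (`iii_over_L`); and mesaxony `te/W`, the anterior-triangle
#' ratio quantifying how far the central digit projects beyond the
#' lateral digit tips. Each value is `NA` whenever a constituent
#' measurement is missing or a denominator is zero (no error is thrown).
#'
#' @param m a [track_metrics()] object.
#' @return A list of class `derived_metrics` with fields `lw_ratio`,
#'   `r_iii_ii`, `r_iii_iv`, `iii_over_L` (percent), `mesaxony`.
#' @export
derive_metrics <- function(m) {
  stopifnot(inherits(m, "track_metrics"))
  sdiv <- function(a, b) {
    if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
  }
  structure(list(
    lw_ratio = sdiv(m$L, m$W),
    r_iii_ii = sdiv(m$L_III, m$L_II),
    r_iii_iv = sdiv(m$L_III, m$L_IV),
    iii_over_L = 100 * sdiv(m$L_III, m$L),
    mesaxony = sdiv(m$te, m$W)
  ), class = "derived_metrics")
}

#' Track length categories
#'
#' Bins a total track length into the conventional theropod size classes:
#' tiny (< 10 cm), small (10-20 cm), medium (20-30 cm), large (30-50 cm),
#' giant (>= 50 cm). Left-closed bins.
#'
#' @param L total track length(s), cm.
#' @return character vector of categories (`NA` in, `NA` out).
#' @export
length_category <- function(L) {
  out <- rep(NA_character_, length(L))
  ok <- !is.na(L)
  out[ok & L < 10] <- "tiny"
  out[ok & L >= 10 & L < 20] <- "small"
  out[ok & L >= 20 & L < 30] <- "medium"
  out[ok & L >= 30 & L < 50] <- "large"
  out[ok & L >= 50] <- "giant"
  out
}

.digit_shapes <- c("parallel_sided", "sub_parallel", "spindle",
                   "gracile", "broad_round")
.hallux_states <- c("absent", "anterolateral", "posterior", "uncertain")
.ungual_states <- c("absent", "short", "elongate")

#' Morphology flags
#'
#' Categorical morphological observations used by the classifier
#' alongside the metrics. Unknown states are explicit `NA`s, never
#' silently defaulted.
#'
#' @param digit_shape one of `r paste(.digit_shapes, collapse=", ")`, or NA.
#' @param hallux digit I state: absent, anterolateral, posterior, uncertain.
#' @param ungual_marks absent, short or elongate.
#' @param pad_formula phalangeal pad formula string (e.g. `"2:3:4"`,
#'   `"X"` marking unobserved positions) or NA.
#' @param digits_well_separated,inner_margins_present,heel_impressed
#'   logical or NA.
#' @return An object of class `morphology_flags`.
#' @export
morphology_flags <- function(digit_shape = NA, hallux = NA,
                             ungual_marks = NA, pad_formula = NA,
                             digits_well_separated = NA,
                             inner_margins_present = NA,
                             heel_impressed = NA) {
  chk <- function(x, allowed, what) {
    if (is.null(x) || length(x) == 0L || is.na(x)) return(NA_character_)
    x <- as.character(x)
    if (!x %in% allowed)
      stop("invalid ", what, ": '", x, "' (allowed: ",
           paste(allowed, collapse = ", "), ")")
    x
  }
  lgl <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) NA else as.logical(x)
  structure(list(
    digit_shape = chk(digit_shape, .digit_shapes, "digit_shape"),
    hallux = chk(hallux, .hallux_states, "hallux"),
    ungual_marks = chk(ungual_marks, .ungual_states, "ungual_marks"),
    pad_formula = if (is.null(pad_formula) || length(pad_formula) == 0L ||
                      is.na(pad_formula)) NA_character_ else as.character(pad_formula),
    digits_well_separated = lgl(digits_well_separated),
    inner_margins_present = lgl(inner_margins_present),
    heel_impressed = lgl(heel_impressed)
  ), class = "morphology_flags")
}

#' Track records
#'
#' The catalogued unit: one footprint with provenance, preservation
#' grade, siding, morphology flags, measurements and derived ratios.
#'
#' @param specimen_id specimen / track identifier.
#' @param metrics a [track_metrics()] object.
#' @param flags a [morphology_flags()] object.
#' @param preservation_grade ordinal anatomical-fidelity grade on 0-3 in
#'   0.5 steps (3 = sharpest morphology). Grade >= 1.5 tracks anchor
#'   morphotype definitions ("characterized"); grade-1 tracks may
#'   characterize only when surface wear is judged acceptable; lower
#'   grades are at best "referred".
#' @param side_observed,side_catalogued `"left"`, `"right"` or
#'   `"indeterminate"`. The catalogued side differs from the observed side
#'   for positive-relief casts (see [apply_relief_siding()]).
#' @param relief `"negative"` or `"positive"`.
#' @param locality,sublocality,formation,bed provenance strings (optional).
#' @param bearing track bearing in degrees within its surface frame, or NA.
#' @param wear_acceptable operator judgement used only for grade-1 tracks:
#'   if TRUE such tracks may characterize rather than be referred.
#' @param published_subgroup optional published morphotype assignment
#'   (used by the classification audit).
#' @param derived optional precomputed [derive_metrics()] result; computed
#'   from `metrics` when NULL. Transcribed tables may carry independently
#'   rounded derived values, which [validate_record()] cross-checks.
#' @param mirrored_for_relief logical: set by [apply_relief_siding()].
#' @return An object of class `track_record`.
#' @export
track_record <- function(specimen_id, metrics = track_metrics(),
                         flags = morphology_flags(),
                         preservation_grade = NA,
                         side_observed = "indeterminate",
                         side_catalogued = NA,
                         relief = "negative",
                         locality = NA, sublocality = NA,
                         formation = NA, bed = NA,
                         bearing = NA,
                         wear_acceptable = FALSE,
                         published_subgroup = NA,
                         derived = NULL,
                         mirrored_for_relief = FALSE) {
  stopifnot(inherits(metrics, "track_metrics"),
            inherits(flags, "morphology_flags"))
  pg <- num_or_na(preservation_grade)
  if (!is.na(pg) && !(pg %in% seq(0, 3, by = 0.5)))
    stop("preservation_grade must lie in {0, 0.5, ..., 3}")
  side_observed <- match.arg(side_observed, c("indeterminate", "left", "right"))
  if (is.null(derived)) derived <- derive_metrics(metrics)
  structure(list(
    specimen_id = as.character(specimen_id),
    locality = locality, sublocality = sublocality,
    formation = formation, bed = bed,
    side_observed = side_observed,
    side_catalogued = if (is.na(side_catalogued)) side_observed
                      else match.arg(side_catalogued,
                                     c("indeterminate", "left", "right")),
    relief = match.arg(relief, c("negative", "positive")),
    mirrored_for_relief = isTRUE(mirrored_for_relief),
    preservation_grade = pg,
    flags = flags,
    metrics = metrics,
    derived = derived,
    length_category = length_category(metrics$L),
    bearing = num_or_na(bearing),
    wear_acceptable = isTRUE(wear_acceptable),
    published_subgroup = published_subgroup
  ), class = "track_record")
}

#' @export
print.track_record <- function(x, ...) {
  cat("<track_record> ", x$specimen_id,
      "  [", x$length_category %||% NA, "]",
      "  grade ", x$preservation_grade, "\n", sep = "")
  m <- x$metrics; d <- x$derived
  cat(sprintf("  L %.2f  W %.2f  L/W %.2f  te %.2f  M %.2f  div %.2f\n",
              m$L, m$W, d$lw_ratio, m$te, d$mesaxony, m$total_div))
  invisible(x)
}

#' Apply the positive-relief siding convention
#'
#' Positive-relief tracks are infill casts: on the base of a bed the cast
#' is a mirror image of the foot that made it, so a track that appears
#' right-footed is catalogued as a left track. This function sets
#' `side_catalogued` to the mirror of `side_observed` for positive-relief
#' tracks (flagging `mirrored_for_relief`), and passes negative-relief
#' tracks through unchanged. Indeterminate sides pass through with a
#' warning.
#'
#' @param record a [track_record()].
#' @return The updated record.
#' @export
apply_relief_siding <- function(record) {
  stopifnot(inherits(record, "track_record"))
  if (record$relief == "positive") {
    if (record$side_observed == "indeterminate") {
      warning("positive-relief track with indeterminate side: ",
              "catalogued side left indeterminate")
      record$side_catalogued <- "indeterminate"
    } else {
      record$side_catalogued <-
        if (record$side_observed == "right") "left" else "right"
      record$mirrored_for_relief <- TRUE
    }
  } else {
    record$side_catalogued <- record$side_observed
  }
  record
}

#' Consistency checks on a track record
#'
#' Verifies the arithmetic identities that link raw measurements to the
#' derived columns of a measurement table: total divarication =
#' alpha + beta; L/W, mesaxony and III/L recomputed from the raw values
#' agree with any stored derived values; and the length category is
#' consistent with L. Returns findings, never throws: transcribed tables
#' round inputs to 2 d.p., so small tolerances absorb printing error.
#'
#' @param record a [track_record()].
#' @param tol_ratio tolerance on L/W, mesaxony and divarication sum.
#' @param tol_pct tolerance on the III/L percentage.
#' @return A character vector of findings (length 0 when consistent).
#' @export
validate_record <- function(record, tol_ratio = 0.02, tol_pct = 0.05) {
  stopifnot(inherits(record, "track_record"))
  m <- record$metrics; d <- record$derived
  f <- character(0)
  chk <- function(stored, computed, tol, label) {
    if (!is.na(stored) && !is.na(computed) && abs(stored - computed) > tol)
      sprintf("%s mismatch: stored %.4f vs recomputed %.4f", label,
              stored, computed) else NULL
  }
  if (!is.na(m$alpha) && !is.na(m$beta) && !is.na(m$total_div) &&
      abs(m$total_div - (m$alpha + m$beta)) > tol_ratio)
    f <- c(f, sprintf("divarication mismatch: total %.2f vs alpha+beta %.2f",
                      m$total_div, m$alpha + m$beta))
  fresh <- derive_metrics(m)
  f <- c(f,
         chk(d$lw_ratio, fresh$lw_ratio, tol_ratio, "l/w ratio"),
         chk(d$mesaxony, fresh$mesaxony, tol_ratio, "mesaxony"),
         chk(d$iii_over_L, fresh$iii_over_L, tol_pct, "III/L"))
  if (!is.na(m$L)) {
    expect_cat <- length_category(m$L)
    if (!is.na(record$length_category) &&
        !identical(record$length_category, expect_cat))
      f <- c(f, sprintf("category mismatch, expected %s", expect_cat))
  }
  f
}
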