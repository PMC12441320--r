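# measurement-table IO, the packaged reference fixture and result writers

.table_cols <- c("specimen", "PG", "LR", "L", "W", "LW",
                 "LII", "LIII", "LIV", "III_II", "III_IV", "III_L",
                 "div_II_III", "div_III_IV", "div_II_IV", "te", "M")
.meta_cols <- c("published_subgroup", "source_table", "locality",
                "formation", "digit_shape", "hallux",
                "digits_well_separated", "inner_margins", "heel_impressed",
                "pad_formula", "status", "avg_row", "bearing_deg",
                "wear_acceptable")

.parse_lr <- function(lr) {
  lr <- trimws(as.character(lr))
  side <- ifelse(grepl("^L", lr), "left",
                 ifelse(grepl("^R", lr), "right", "indeterminate"))
  mirrored <- grepl("\\*", lr)
  list(side = side, mirrored = mirrored)
}

.parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
         ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
}

#' Read a track measurement table
#'
#' Reads a delimited measurement table in the printed column order
#' (`specimen, PG, LR, L, W, LW, LII, LIII, LIV, III_II, III_IV, III_L,
#' div_II_III, div_III_IV, div_II_IV, te, M`), where lengths are cm,
#' III_L is a percentage, angles are degrees and `"n/a"` denotes missing.
#' Additional metadata columns (published subgroup, locality, morphology
#' flags, status, ...) are honoured when present; unknown columns are a
#' hard error. Rows flagged `avg_row` (published per-table average rows)
#' are skipped.
#'
#' The stored derived columns (LW, III_II, III_IV, III_L, M) are kept as
#' the records' derived metrics - they are the printed, independently
#' rounded values; [validate_record()] cross-checks them against the raw
#' measurements.
#'
#' An `LR` entry carries the observed side plus the positive-relief
#' mirror marker `*` (e.g. `R*` = appears right, catalogued left) and an
#' optional trailing `?` for uncertain siding.
#'
#' @param path file path.
#' @return list of [track_record()] objects; attribute `"table"` holds
#'   the raw data.frame.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("n/a", "NA", ""),
                        check.names = FALSE)
  unknown <- setdiff(names(df), c(.table_cols, .meta_cols))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         "\nexpected header: ", paste(.table_cols, collapse = ", "),
         " [+ optional metadata columns]")
  missing_core <- setdiff(.table_cols, names(df))
  if (length(missing_core))
    stop("missing column(s): ", paste(missing_core, collapse = ", "))
  if (!is.null(df$avg_row)) {
    av <- .parse_logical(df$avg_row)
    df <- df[!(av %in% TRUE), , drop = FALSE]
  }
  numcols <- setdiff(.table_cols, c("specimen", "LR"))
  for (cn in numcols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad))
        stop("unparseable numeric in column '", cn, "' at data row ",
             bad[1L], ": '", v[bad[1L]], "'")
      df[[cn]] <- suppress
    }
  }
  getc <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
  records <- lapply(seq_len(nrow(df)), function(i) {
    lr <- .parse_lr(df$LR[i])
    relief <- if (lr$mirrored) "positive" else "negative"
    m <- track_metrics(L = df$L[i], W = df$W[i],
                       L_II = df$LII[i], L_III = df$LIII[i],
                       L_IV = df$LIV[i], te = df$te[i],
                       alpha = df$div_II_III[i], beta = df$div_III_IV[i],
                       total_div = df$div_II_IV[i])
    d <- structure(list(lw_ratio = num_or_na(df$LW[i]),
                        r_iii_ii = num_or_na(df$III_II[i]),
                        r_iii_iv = num_or_na(df$III_IV[i]),
                        iii_over_L = num_or_na(df$III_L[i]),
                        mesaxony = num_or_na(df$M[i])),
                   class = "derived_metrics")
    fl <- morphology_flags(
      digit_shape = getc("digit_shape")[i],
      hallux = getc("hallux")[i],
      pad_formula = getc("pad_formula")[i],
      digits_well_separated = .parse_logical(getc("digits_well_separated")[i]),
      inner_margins_present = .parse_logical(getc("inner_margins")[i]),
      heel_impressed = .parse_logical(getc("heel_impressed")[i]))
    rec <- track_record(
      specimen_id = df$specimen[i],
      metrics = m, flags = fl, derived = d,
      preservation_grade = df$PG[i],
      side_observed = lr$side,
      relief = relief,
      locality = getc("locality")[i],
      formation = getc("formation")[i],
      bearing = num_or_na(getc("bearing_deg")[i]),
      wear_acceptable = isTRUE(.parse_logical(getc("wear_acceptable")[i])),
      published_subgroup = getc("published_subgroup")[i])
    rec <- apply_relief_siding(rec)
    st <- getc("status")[i]
    attr(rec, "status") <- if (is.na(st)) NA_character_ else as.character(st)
    rec
  })
  message(length(records), " track record(s) read from ", basename(path))
  attr(records, "table") <- df
  records
}

#' Write a collection of records as a measurement table
#'
#' Full-precision serialization in the canonical column order (round-trip
#' safe). See [write_results()] for the display-rounded twin.
#'
#' @param records list of [track_record()] objects.
#' @param path output path.
#' @param digits when non-NULL, round numeric columns (display twin).
#' @return the path, invisibly.
#' @export
write_measurement_table <- function(records, path, digits = NULL) {
  if (!length(records)) {
    writeLines(paste(c(.table_cols, "published_subgroup", "locality"),
                     collapse = ","), path)
    return(invisible(path))
  }
  rows <- lapply(records, function(r) {
    m <- r$metrics; d <- r$derived
    lr <- switch(r$side_observed, left = "L", right = "R", "?")
    if (r$relief == "positive") lr <- paste0(lr, "*")
    data.frame(specimen = r$specimen_id, PG = r$preservation_grade,
               LR = lr, L = m$L, W = m$W, LW = d$lw_ratio,
               LII = m$L_II, LIII = m$L_III, LIV = m$L_IV,
               III_II = d$r_iii_ii, III_IV = d$r_iii_iv,
               III_L = d$iii_over_L,
               div_II_III = m$alpha, div_III_IV = m$beta,
               div_II_IV = m$total_div, te = m$te, M = d$mesaxony,
               published_subgroup = as.character(r$published_subgroup %||% NA),
               locality = as.character(r$locality %||% NA),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(digits))
    for (cn in names(df))
      if (is.numeric(df[[cn]])) df[[cn]] <- round_half_up(df[[cn]], digits)
  out <- df
  for (cn in names(out)) out[[cn]][is.na(out[[cn]])] <- "n/a"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The packaged 85-track reference table
#'
#' The characterized tracks of the Valtos and Lub Score assemblages
#' (Isle of Skye, Middle Jurassic), transcribed from the published
#' per-subgroup measurement tables, with the published subgroup, the
#' table of origin, best-effort locality/formation, and curated
#' morphology flags taken from the subgroup descriptions. Lengths cm,
#' angles degrees, III_L percent; all values printed at 2 d.p. in the
#' source.
#'
#' @param as `"records"` (default) for a list of [track_record()]s, or
#'   `"table"` for the raw data.frame.
#' @return see `as`.
#' @export
hebridean_fixture <- function(as = c("records", "table")) {
  as <- match.arg(as)
  path <- system.file("extdata", "hebridean_tracks.csv",
                      package = "hebtracks", mustWork = TRUE)
  if (as == "table")
    return(utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("n/a", "NA", ""),
                           check.names = FALSE))
  suppressMessages(read_measurement_table(path))
}

#' Write analysis results with a manifest
#'
#' Writes the classified measurement table at full precision plus a
#' display-rounded twin (2 d.p., half-up - the printing convention of the
#' source tables), the classification table, optional trackway metrics,
#' and a JSON manifest recording the package version, rule-set version
#' and seed so the run is reproducible from the manifest alone.
#'
#' @param records list of [track_record()] objects.
#' @param classifications optional [classify_table()] result.
#' @param metrics optional list of [kinematic_estimates()].
#' @param dir output directory (created if needed).
#' @param seed the seed used upstream, echoed into the manifest.
#' @param rules the rule set used (for its version string).
#' @return dir, invisibly.
#' @export
write_results <- function(records, classifications = NULL, metrics = NULL,
                          dir, seed = NULL, rules = hebridean_rules()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tryCatch({
    write_measurement_table(records, file.path(dir, "measurements_full.csv"))
    write_measurement_table(records, file.path(dir, "measurements_rounded.csv"),
                            digits = 2)
    if (!is.null(classifications))
      utils::write.csv(classifications,
                       file.path(dir, "classifications.csv"),
                       row.names = FALSE)
    if (!is.null(metrics)) {
      km <- do.call(rbind, lapply(metrics, function(k)
        data.frame(trackway_id = k$trackway_id, mean_L_cm = k$mean_L,
                   hip_height_m = k$hip_height,
                   mean_stride_m = k$mean_stride,
                   velocity_alexander = k$velocity_alexander,
                   velocity_rt = k$velocity_rt,
                   gait_ratio = k$gait_ratio,
                   gait_category = k$gait_category)))
      utils::write.csv(km, file.path(dir, "trackway_estimates.csv"),
                       row.names = FALSE)
    }
    manifest <- list(package_version = as.character(
                       utils::packageVersion("hebtracks")),
                     rules_version = rules$version,
                     seed = seed,
                     n_records = length(records),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }, error = function(e) stop("cannot write results to '", dir, "': ",
                              conditionMessage(e)))
  invisible(dir)
}
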