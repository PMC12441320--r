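# assemblage-level aggregation: subgroup summary tables, abundances,
# metric correlations, allometry pairs and bearing roses

# flatten a list of track_records to a data.frame of the table columns
records_to_table <- function(records) {
  if (!length(records)) {
    cols <- c("specimen", "subgroup", "locality", "status", "PG", "L", "W",
              "LW", "LII", "LIII", "LIV", "III_II", "III_IV", "III_L",
              "div_II_III", "div_III_IV", "div_II_IV", "te", "M")
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    for (cn in c("specimen", "subgroup", "locality", "status"))
      out[[cn]] <- character(0)
    return(out)
  }
  rows <- lapply(records, function(r) {
    m <- r$metrics; d <- r$derived
    data.frame(specimen = r$specimen_id,
               subgroup = as.character(r$published_subgroup %||% NA),
               locality = as.character(r$locality %||% NA),
               status = NA_character_,
               PG = r$preservation_grade,
               L = m$L, W = m$W, LW = d$lw_ratio,
               LII = m$L_II, LIII = m$L_III, LIV = m$L_IV,
               III_II = d$r_iii_ii, III_IV = d$r_iii_iv,
               III_L = d$iii_over_L,
               div_II_III = m$alpha, div_III_IV = m$beta,
               div_II_IV = m$total_div,
               te = m$te, M = d$mesaxony,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemblage summary
#'
#' Per-subgroup means of every numeric measurement column (computed over
#' rows where the value is present, matching the convention of published
#' "average" rows, which average the characterized tracks only), plus
#' counts by locality, subgroup and status.
#'
#' @param records list of [track_record()] objects.
#' @param classifications optional result of [classify_table()]; when
#'   given, its `assigned`/`status` columns are used for grouping,
#'   otherwise each record's `published_subgroup` and a status of
#'   "characterized" for grade >= 1 records is assumed.
#' @param use_derived when TRUE (default) derived ratios stored on the
#'   records are used as-is (i.e. the table's own printed derived columns
#'   when records were read from a transcription).
#' @return An object of class `assemblage_summary`: list with
#'   `per_subgroup_means` (data.frame, one row per subgroup),
#'   `counts` (locality x subgroup x status), `n_characterized`,
#'   `n_referred`.
#' @export
summarize_assemblage <- function(records, classifications = NULL,
                                 use_derived = TRUE) {
  tab <- records_to_table(records)
  if (!is.null(classifications)) {
    tab$subgroup <- classifications$assigned[match(tab$specimen,
                                                   classifications$specimen)]
    tab$status <- classifications$status[match(tab$specimen,
                                               classifications$specimen)]
  } else {
    st <- vapply(records, function(r) {
      s <- attr(r, "status") %||% NULL
      if (!is.null(s)) return(as.character(s))
      if (!is.na(r$preservation_grade) && r$preservation_grade >= 1)
        "characterized" else "referred"
    }, character(1))
    tab$status <- st
  }
  num_cols <- c("PG", "L", "W", "LW", "LII", "LIII", "LIV",
                "III_II", "III_IV", "III_L",
                "div_II_III", "div_III_IV", "div_II_IV", "te", "M")
  char <- tab[tab$status == "characterized" & !is.na(tab$subgroup), ,
              drop = FALSE]
  means <- do.call(rbind, lapply(split(char, char$subgroup), function(d) {
    v <- vapply(num_cols, function(cn) {
      x <- d[[cn]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(subgroup = d$subgroup[1L], n = nrow(d)),
          as.data.frame(as.list(v)))
  }))
  rownames(means) <- NULL
  counts <- as.data.frame(table(locality = tab$locality,
                                subgroup = tab$subgroup,
                                status = tab$status))
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  names(counts)[4L] <- "n"
  structure(list(per_subgroup_means = means,
                 counts = counts,
                 n_characterized = sum(tab$status == "characterized",
                                       na.rm = TRUE),
                 n_referred = sum(tab$status == "referred", na.rm = TRUE)),
            class = "assemblage_summary")
}

#' @export
print.assemblage_summary <- function(x, ...) {
  cat("<assemblage_summary> ", x$n_characterized, " characterized, ",
      x$n_referred, " referred\n\n", sep = "")
  print(cbind(x$per_subgroup_means[, 1:2],
              round(x$per_subgroup_means[, -(1:2)], 2)))
  invisible(x)
}

#' Pearson correlation between two track metrics
#'
#' Computes the sample Pearson correlation over the records selected by
#' an explicit, named inclusion rule. The rule is recorded on the result
#' so the exact selection is auditable.
#'
#' @param records list of [track_record()] objects.
#' @param x,y metric names (one of `L`, `W`, `lw_ratio`, `mesaxony`,
#'   `total_div`, `iii_over_L`, `r_iii_ii`, `r_iii_iv`, `te`,
#'   `L_minus_te`).
#' @param inclusion `"both-present"` (default) or a list
#'   `list(exclude_subgroups = c(...))` which additionally drops records
#'   whose published subgroup is listed.
#' @return An object of class `metric_relation`: `x_name`, `y_name`,
#'   `inclusion_rule`, `n`, `pearson_r` (NA with an explanation when
#'   n < 3 or a variance is zero).
#' @export
metric_correlation <- function(records, x, y, inclusion = "both-present") {
  get1 <- function(r, name) {
    if (name == "L_minus_te") {
      v <- r$metrics$L - r$metrics$te
      return(if (length(v)) v else NA_real_)
    }
    if (name == "te") return(r$metrics$te)
    .record_metric(r, name)
  }
  keep <- rep(TRUE, length(records))
  label <- "both-present"
  if (is.list(inclusion)) {
    ex <- inclusion$exclude_subgroups %||% character(0)
    pub <- vapply(records, function(r)
      as.character(r$published_subgroup %||% NA), character(1))
    keep <- keep & !(pub %in% ex)
    label <- paste0("both-present; exclude-subgroups [",
                    paste(ex, collapse = ", "), "]")
  }
  xs <- vapply(records, get1, numeric(1), name = x)
  ys <- vapply(records, get1, numeric(1), name = y)
  keep <- keep & !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  r <- NA_real_
  note <- NULL
  if (n < 3) {
    note <- "fewer than 3 complete pairs; r undefined"
  } else if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    note <- "zero variance in a variable; r undefined"
  } else {
    r <- stats::cor(xs, ys)
  }
  structure(list(x_name = x, y_name = y, inclusion_rule = label,
                 n = n, pearson_r = r, note = note),
            class = "metric_relation")
}

#' @export
print.metric_relation <- function(x, ...) {
  cat("<metric_relation> r(", x$x_name, ", ", x$y_name, ") = ",
      if (is.na(x$pearson_r)) "undefined" else sprintf("%.4f", x$pearson_r),
      "  (n = ", x$n, "; ", x$inclusion_rule, ")\n", sep = "")
  if (!is.null(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}

#' Triangle-elongation allometry pairs
#'
#' Emits, for every record with both L and te present, the pair
#' (L - te, te): the digit III toe extension against the remaining track
#' length. Plotted across subgroups this shows whether central-digit
#' pronouncement scales with track size. A descriptive ordinary
#' least-squares slope is attached (no inferential statistics).
#'
#' @param records list of [track_record()] objects.
#' @return data.frame with columns `specimen`, `subgroup`, `L_minus_te`,
#'   `te`; attribute `"slope"` holds the OLS slope of te on L - te (NA
#'   when fewer than 2 distinct points).
#' @export
allometry_panel <- function(records) {
  tab <- records_to_table(records)
  ok <- !is.na(tab$L) & !is.na(tab$te)
  out <- data.frame(specimen = tab$specimen[ok],
                    subgroup = tab$subgroup[ok],
                    L_minus_te = tab$L[ok] - tab$te[ok],
                    te = tab$te[ok],
                    stringsAsFactors = FALSE)
  slope <- NA_real_
  if (nrow(out) >= 2L && stats::sd(out$L_minus_te) > 0)
    slope <- unname(stats::coef(stats::lsfit(out$L_minus_te, out$te))[2L])
  attr(out, "slope") <- slope
  out
}

#' Bearing rose (windrose) and circular summary
#'
#' Bins track bearings into sectors of `bin_width` degrees and computes
#' the circular mean direction and the mean resultant length R-bar
#' (1 = all bearings identical, 0 = perfect cancellation). A near-zero
#' R-bar is reported as no preferred direction: disorganized, multi-
#' directional ("milling") surfaces contrast with aligned ("gregarious")
#' ones.
#'
#' @param bearings numeric vector of bearings in degrees (wrapped to
#'   0-360), or a data.frame with a `bearing_deg` column.
#' @param bin_width sector width in degrees; must divide 360. Default 15
#'   (24 sectors), the conventional rose resolution.
#' @return An object of class `bearing_rose`: `counts` (named integer
#'   vector per sector), `mean_direction` (deg, NA when R-bar ~ 0),
#'   `rbar`, `n`, `preferred` (logical).
#' @export
bearing_rose <- function(bearings, bin_width = 15) {
  if (is.data.frame(bearings)) bearings <- bearings$bearing_deg
  bearings <- bearings[!is.na(bearings)]
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  b <- wrap360(bearings)
  breaks <- seq(0, 360, by = bin_width)
  idx <- findInterval(b, breaks, rightmost.closed = FALSE)
  idx[idx > length(breaks) - 1L] <- length(breaks) - 1L
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  names(counts) <- sprintf("[%d,%d)", breaks[-length(breaks)], breaks[-1L])
  n <- length(b)
  if (n == 0) {
    return(structure(list(counts = counts, mean_direction = NA_real_,
                          rbar = NA_real_, n = 0L, preferred = NA),
                     class = "bearing_rose"))
  }
  s <- mean(sin(deg2rad(b))); c_ <- mean(cos(deg2rad(b)))
  rbar <- sqrt(s^2 + c_^2)
  mu <- if (rbar < 1e-8) NA_real_ else wrap360(rad2deg(atan2(s, c_)))
  structure(list(counts = counts, mean_direction = mu, rbar = rbar,
                 n = n, preferred = rbar >= 1e-8),
            class = "bearing_rose")
}

#' @export
print.bearing_rose <- function(x, ...) {
  cat("<bearing_rose> n = ", x$n, ", R-bar = ",
      ifelse(is.na(x$rbar), "NA", sprintf("%.3f", x$rbar)), sep = "")
  if (isTRUE(!x$preferred) || (!is.na(x$rbar) && x$rbar < 1e-8))
    cat("  (no preferred direction)")
  else if (!is.na(x$mean_direction))
    cat(sprintf(", mean direction %.1f deg", x$mean_direction))
  cat("\n")
  occ <- x$counts[x$counts > 0]
  if (length(occ)) print(occ)
  invisible(x)
}

#' Status and abundance count report
#'
#' Totals by status, by subgroup and by locality, for an assemblage of
#' records. When the records carry a transcription status column (via
#' `attr(record, "status")`) that is used; otherwise status follows the
#' classifications argument.
#'
#' @param records list of [track_record()] objects.
#' @param classifications optional [classify_table()] result.
#' @return list with `total`, `by_status`, `by_subgroup`, `by_locality`,
#'   `n_characterized`, `n_referred`, `max_total_div` (the study-wide
#'   maximum divarication, a quick integrity anchor).
#' @export
count_report <- function(records, classifications = NULL) {
  tab <- records_to_table(records)
  status <- vapply(seq_along(records), function(i) {
    s <- attr(records[[i]], "status")
    if (!is.null(s) && !is.na(s)) return(as.character(s))
    if (!is.null(classifications))
      return(classifications$status[match(records[[i]]$specimen_id,
                                          classifications$specimen)])
    NA_character_
  }, character(1))
  tab$status <- status
  list(total = nrow(tab),
       by_status = table(tab$status, useNA = "ifany"),
       by_subgroup = table(tab$subgroup, useNA = "ifany"),
       by_locality = table(tab$locality, tab$status, useNA = "ifany"),
       n_characterized = sum(status == "characterized", na.rm = TRUE),
       n_referred = sum(status == "referred", na.rm = TRUE),
       max_total_div = if (all(is.na(tab$div_II_IV))) NA_real_
                       else max(tab$div_II_IV, na.rm = TRUE))
}
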