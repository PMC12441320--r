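#' Score a track record against every morphotype subgroup
#'
#' Evaluates, for each subgroup in the rule set, the eligibility gates
#' (size category, digit shape, hallux state, hard metric bounds, hard
#' flags) and the soft metric/flag predicates. A predicate on a missing
#' metric counts as unsatisfied, never satisfied; the score is the
#' satisfied fraction of all soft predicates. Gates that reference a
#' missing quantity cannot exclude (a track with unknown length passes
#' every size gate).
#'
#' @param record a [track_record()].
#' @param rules a [hebridean_rules()] rule set.
#' @return data.frame with one row per subgroup: `subgroup`, `eligible`,
#'   `score` (in 0-1), `n_satisfied`, `n_predicates`, `full_match`
#'   (combination rule satisfied), and a list-column `matched` of
#'   satisfied predicate labels.
#' @export
evaluate_criteria <- function(record, rules = hebridean_rules()) {
  stopifnot(inherits(record, "track_record"))
  ids <- names(rules$subgroups)
  rows <- lapply(ids, function(id) {
    sg <- rules$subgroups[[id]]
    fl <- record$flags

    eligible <- TRUE
    # size gate (Table-1 length category implied by the diagnosed range)
    cats <- unlist(sg$size_categories)
    if (length(cats) && !is.na(record$length_category))
      eligible <- eligible && record$length_category %in% cats
    # digit-shape gate
    shapes <- unlist(sg$digit_shapes)
    if (length(shapes) && !is.na(fl$digit_shape))
      eligible <- eligible && fl$digit_shape %in% shapes
    # hallux gate: NA treated as uncertain
    hal <- if (is.na(fl$hallux)) "uncertain" else fl$hallux
    eligible <- eligible && hal %in% unlist(sg$hallux_allowed)
    # hard metric bounds (missing metric cannot exclude)
    for (p in sg$metrics_hard) {
      v <- .record_metric(record, p$metric)
      if (!is.na(v)) eligible <- eligible && .pred_ok(p, v)
    }
    # hard flag requirements (NA flag fails a hard requirement)
    for (fp in sg$flags_hard) {
      v <- fl[[fp$flag]]
      eligible <- eligible && !is.na(v) && identical(as.logical(v), fp$value)
    }

    sat <- character(0)
    n_m <- length(sg$metrics_soft)
    n_sat_m <- 0L
    for (p in sg$metrics_soft) {
      if (.pred_ok(p, .record_metric(record, p$metric))) {
        n_sat_m <- n_sat_m + 1L
        sat <- c(sat, .pred_label(p))
      }
    }
    n_f <- length(sg$flags_soft)
    n_sat_f <- 0L
    for (fp in sg$flags_soft) {
      v <- fl[[fp$flag]]
      if (!is.na(v) && identical(as.logical(v), fp$value)) {
        n_sat_f <- n_sat_f + 1L
        sat <- c(sat, paste0(fp$flag, " == ", fp$value))
      }
    }
    n_tot <- n_m + n_f
    comb <- sg$combination %||% "all"
    full <- if (identical(comb, "all")) n_sat_m == n_m
            else n_sat_m >= as.integer(comb)
    data.frame(subgroup = id,
               eligible = eligible,
               score = if (n_tot) (n_sat_m + n_sat_f) / n_tot else 0,
               n_satisfied = n_sat_m + n_sat_f,
               n_predicates = n_tot,
               full_match = full,
               matched = I(list(sat)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a track into the Hebridean morphotype series
#'
#' Deterministic rule-based assignment. Candidates are first filtered by
#' the eligibility gates (size class, digit shape, hallux state, hard
#' bounds); among candidates satisfying their combination rule (falling
#' back to all candidates when none does), the highest normalized score
#' wins. Ties are broken by the number of satisfied predicates, then by
#' the rule set's preference order, and the co-maximal candidates are
#' recorded as `ambiguity`. Status follows preservation grade: >= 1.5
#' characterized; grade 1 characterized only when the record's
#' `wear_acceptable` flag is set, otherwise referred; grade < 1 referred
#' when any candidate matched at all; otherwise (or with no candidate)
#' unclassified.
#'
#' @param record a [track_record()].
#' @param rules a [hebridean_rules()] rule set.
#' @return An object of class `classification`: list with `subgroup`,
#'   `series`, `status`, `score`, `matched`, `ambiguity` (co-maximal
#'   candidates when tie-broken), `suggested_ichnotaxon`, `notes`, and
#'   the full `scores` table from [evaluate_criteria()].
#' @export
classify_track <- function(record, rules = hebridean_rules()) {
  sc <- evaluate_criteria(record, rules)
  cand <- sc[sc$eligible, , drop = FALSE]
  notes <- character(0)

  if (!nrow(cand)) {
    return(structure(list(subgroup = NA_character_, series = NA_character_,
                          status = "unclassified", score = NA_real_,
                          matched = character(0), ambiguity = character(0),
                          suggested_ichnotaxon = NA_character_,
                          notes = "no subgroup passes the eligibility gates",
                          scores = sc),
                     class = "classification"))
  }

  pool <- cand[cand$full_match, , drop = FALSE]
  if (!nrow(pool)) {
    pool <- cand
    notes <- c(notes, "no full diagnostic match; ranked by partial score")
  }

  pref <- match(pool$subgroup, unlist(rules$preference_order))
  ord <- order(-pool$score, -pool$n_satisfied, pref)
  pool <- pool[ord, , drop = FALSE]
  top_score <- pool$score[1L]
  co_max <- pool$subgroup[abs(pool$score - top_score) < 1e-9]
  winner <- pool[1L, ]
  ambiguity <- if (length(co_max) > 1L) co_max else character(0)

  sg <- rules$subgroups[[winner$subgroup]]
  g <- record$preservation_grade
  any_match <- any(cand$n_satisfied > 0L)
  status <-
    if (is.na(g)) "referred"
    else if (g >= 1.5) "characterized"
    else if (g >= 1) { if (record$wear_acceptable) "characterized" else "referred" }
    else if (any_match) "referred"
    else "unclassified"

  structure(list(subgroup = winner$subgroup,
                 series = sg$series,
                 status = status,
                 score = winner$score,
                 matched = winner$matched[[1L]],
                 ambiguity = ambiguity,
                 suggested_ichnotaxon = sg$suggested_ichnotaxon,
                 notes = notes,
                 scores = sc),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification> ", x$subgroup %||% NA, " (", x$status, ")",
      if (length(x$ambiguity)) paste0("  [ambiguous: ",
                                      paste(x$ambiguity, collapse = ", "), "]"),
      "\n", sep = "")
  if (!is.na(x$subgroup))
    cat("  suggested ichnotaxon: ", x$suggested_ichnotaxon, "\n",
        "  matched: ", paste(x$matched, collapse = "; "), "\n", sep = "")
  if (length(x$notes)) cat("  note: ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Classify a collection of records, with a published-assignment audit
#'
#' Applies [classify_track()] to every record (deterministically and
#' independently, so the result does not depend on input order). When
#' records carry a `published_subgroup`, the attached audit separates
#' disagreements into "ambiguous" (the assignment was tie-broken or only
#' a partial match, with the published subgroup among the candidates)
#' and "misassigned" (a confident disagreement).
#'
#' @param records a list of [track_record()] objects.
#' @param rules a [hebridean_rules()] rule set.
#' @return data.frame with one row per record (`specimen`, `published`,
#'   `assigned`, `series`, `status`, `score`, `ambiguous`, `agree`);
#'   attribute `"audit"` holds a summary list with `n`, `n_published`,
#'   `n_agree`, `disagreements` (data.frame with a `kind` column
#'   splitting "ambiguous" from "misassigned").
#' @export
classify_table <- function(records, rules = hebridean_rules()) {
  if (!length(records)) {
    out <- data.frame(specimen = character(0), published = character(0),
                      assigned = character(0), series = character(0),
                      status = character(0), score = numeric(0),
                      ambiguous = logical(0), agree = logical(0))
    attr(out, "audit") <- list(n = 0L, n_published = 0L, n_agree = 0L,
                               disagreements = out[0, ])
    return(out)
  }
  cls <- lapply(records, classify_track, rules = rules)
  pub <- vapply(records, function(r)
    as.character(r$published_subgroup %||% NA), character(1))
  out <- data.frame(
    specimen = vapply(records, function(r) r$specimen_id, character(1)),
    published = pub,
    assigned = vapply(cls, function(c) c$subgroup %||% NA_character_, character(1)),
    series = vapply(cls, function(c) c$series %||% NA_character_, character(1)),
    status = vapply(cls, function(c) c$status, character(1)),
    score = vapply(cls, function(c) c$score %||% NA_real_, numeric(1)),
    ambiguous = vapply(cls, function(c)
      length(c$ambiguity) > 0L || length(c$notes) > 0L, logical(1)),
    agree = NA,
    stringsAsFactors = FALSE)
  out$agree <- ifelse(is.na(out$published), NA,
                      out$published == out$assigned)
  dis <- out[!is.na(out$agree) & !out$agree, , drop = FALSE]
  if (nrow(dis)) {
    # ambiguous if the winner was tie-broken / partial, or the published
    # subgroup was itself an eligible candidate with a nonzero score
    kind <- vapply(seq_len(nrow(dis)), function(i) {
      idx <- match(dis$specimen[i], out$specimen)
      sc <- cls[[idx]]$scores
      pub_row <- sc[sc$subgroup == dis$published[i], , drop = FALSE]
      close <- nrow(pub_row) && pub_row$eligible &&
        pub_row$n_satisfied > 0L
      if (dis$ambiguous[i] || close) "ambiguous" else "misassigned"
    }, character(1))
    dis$kind <- kind
  } else dis$kind <- character(0)
  attr(out, "audit") <- list(
    n = nrow(out),
    n_published = sum(!is.na(out$published)),
    n_agree = sum(out$agree, na.rm = TRUE),
    disagreements = dis)
  attr(out, "classifications") <- cls
  out
}
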