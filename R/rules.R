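#' Load a morphotype rule set
#'
#' Diagnostic criteria for the Hebridean morphotype series are shipped as
#' a versioned, human-readable YAML file so the series can be extended or
#' amended without code changes. Each subgroup entry carries: gates
#' (length-size categories, admissible digit shapes, admissible hallux
#' states, hard metric bounds and hard flag requirements) which exclude a
#' candidate outright; soft metric/flag predicates which contribute to a
#' normalized score; a combination rule (`"all"` or an integer k = "at
#' least k of the soft metric predicates") defining a full diagnostic
#' match; a suggested ichnotaxon label (informational only); and sampling
#' ranges used by the synthetic generator.
#'
#' @param path path to a rules YAML file; defaults to the packaged
#'   Hebridean series.
#' @return An object of class `morphotype_rules`.
#' @export
hebridean_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hebridean_rules.yaml",
                        package = "hebtracks", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$subgroups) || !length(raw$subgroups))
    stop("rules file has no subgroups")
  for (id in names(raw$subgroups)) {
    sg <- raw$subgroups[[id]]
    for (blk in c("sample", "strict"))
      raw$subgroups[[id]][[blk]] <- lapply(sg[[blk]], function(x)
        as.numeric(unlist(x)))
    sg <- raw$subgroups[[id]]
    for (p in c(sg$metrics_hard, sg$metrics_soft)) {
      if (is.null(p$metric)) stop("predicate without metric name in ", id)
      if (!p$metric %in% c("L", "W", "lw_ratio", "mesaxony", "total_div",
                           "iii_over_L", "r_iii_ii", "r_iii_iv"))
        stop("unknown metric '", p$metric, "' in rules for ", id)
      lo <- p$min %||% p$gt; hi <- p$max %||% p$lt
      if (!is.null(lo) && !is.null(hi) && lo > hi)
        stop("unordered bounds for ", p$metric, " in ", id)
    }
    for (rng in c(sg$sample, sg$strict))
      if (length(rng) == 2L && rng[1] >= rng[2])
        stop("degenerate sampling range in ", id)
  }
  structure(raw, class = "morphotype_rules")
}

#' @export
print.morphotype_rules <- function(x, ...) {
  cat("<morphotype_rules> ", x$series_name, " series, version ", x$version,
      " (", length(x$subgroups), " subgroups)\n\n", sep = "")
  for (id in names(x$subgroups)) {
    sg <- x$subgroups[[id]]
    cat(id, ": ", sg$description, "\n", sep = "")
    cat("    suggested ichnotaxon: ", sg$suggested_ichnotaxon, "\n", sep = "")
  }
  invisible(x)
}

# evaluate one predicate against a value; NA value -> FALSE (a predicate
# on a missing metric is never satisfied)
.pred_ok <- function(p, value) {
  if (is.na(value)) return(FALSE)
  ok <- TRUE
  if (!is.null(p$min)) ok <- ok && value >= p$min
  if (!is.null(p$max)) ok <- ok && value <= p$max
  if (!is.null(p$gt))  ok <- ok && value > p$gt
  if (!is.null(p$lt))  ok <- ok && value < p$lt
  ok
}

.pred_label <- function(p) {
  parts <- c(if (!is.null(p$min)) paste0(">=", p$min),
             if (!is.null(p$gt)) paste0(">", p$gt),
             if (!is.null(p$max)) paste0("<=", p$max),
             if (!is.null(p$lt)) paste0("<", p$lt))
  paste0(p$metric, " ", paste(parts, collapse = " & "))
}

.record_metric <- function(record, name) {
  switch(name,
         L = record$metrics$L,
         W = record$metrics$W,
         lw_ratio = record$derived$lw_ratio,
         mesaxony = record$derived$mesaxony,
         total_div = record$metrics$total_div,
         iii_over_L = record$derived$iii_over_L,
         r_iii_ii = record$derived$r_iii_ii,
         r_iii_iv = record$derived$r_iii_iv,
         NA_real_)
}

#' Audit rule-set overlap zones
#'
#' Reports, for every pair of subgroups and every metric with sampling
#' ranges in both, the overlap interval of their diagnosed ranges.
#' Overlap zones (e.g. l/w around 1.4-1.5 between the two small gracile
#' subgroups) are where metric-only classification is inherently
#' ambiguous and flags carry the discrimination.
#'
#' @param rules a [hebridean_rules()] object.
#' @return data.frame with columns `subgroup_a`, `subgroup_b`, `metric`,
#'   `overlap_lo`, `overlap_hi`.
#' @export
rules_audit <- function(rules = hebridean_rules()) {
  ids <- names(rules$subgroups)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- rules$subgroups[[ids[i]]]$sample
    b <- rules$subgroups[[ids[j]]]$sample
    for (m in intersect(names(a), names(b))) {
      lo <- max(a[[m]][1], b[[m]][1]); hi <- min(a[[m]][2], b[[m]][2])
      if (lo < hi)
        out[[length(out) + 1L]] <- data.frame(
          subgroup_a = ids[i], subgroup_b = ids[j], metric = m,
          overlap_lo = lo, overlap_hi = hi)
    }
  }
  if (!length(out)) return(data.frame(subgroup_a = character(0),
                                      subgroup_b = character(0),
                                      metric = character(0),
                                      overlap_lo = numeric(0),
                                      overlap_hi = numeric(0)))
  do.call(rbind, out)
}
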