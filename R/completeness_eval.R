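# Survey-based evaluation: relevance banding of point-of-care survey
# percentages, explicit/implicit match accounting against the algorithm's
# parameter usage, per-decision-point data-completeness rates, and
# next-step concordance of the simulation against clinician responses.

#' Three-band relevance scale
#'
#' Clinician relevance percentages are banded as less relevant (0-33.3),
#' moderately relevant (33.4-66.6) and highly relevant (66.7-100). Band
#' membership is decided on values rounded half-up to one decimal, so the
#' printed closed ranges partition the scale with no gap at finer
#' precision.
#'
#' @param less,moderate,high closed `[lo, hi]` bounds in percent
#' @return a `relevance_scale`
#' @export
relevance_scale <- function(less = c(0, 33.3), moderate = c(33.4, 66.6),
                            high = c(66.7, 100)) {
  s <- structure(list(less = less, moderate = moderate, high = high),
                 class = "relevance_scale")
  b <- rbind(less, moderate, high)
  if (any(b[, 1] > b[, 2]) || b[1, 1] != 0 || b[3, 2] != 100 ||
      any(round_half_up(b[-1, 1] - b[-3, 2], 1) != 0.1))
    stop("bands must be closed one-decimal ranges partitioning [0, 100]",
         call. = FALSE)
  s
}

#' Classify a relevance percentage into a band
#'
#' @param pct numeric vector of percentages in `[0, 100]`
#' @param scale a [relevance_scale()]
#' @return character vector in `{"less", "moderate", "high"}`
#' @export
classify_relevance <- function(pct, scale = relevance_scale()) {
  if (any(is.na(pct)) || any(pct < 0) || any(pct > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  r <- round_half_up(pct, 1)
  out <- character(length(r))
  out[r <= scale$less[2]] <- "less"
  out[r >= scale$moderate[1] & r <= scale$moderate[2]] <- "moderate"
  out[r >= scale$high[1]] <- "high"
  out
}

survey_dp_rows <- function(survey, dp) {
  if (is.list(survey) && !is.data.frame(survey)) survey <- survey$relevance
  rows <- survey[survey$dp == dp, , drop = FALSE]
  if (nrow(rows) == 0) stop("no survey rows for decision point ", dp,
                            call. = FALSE)
  bad <- setdiff(rows$algorithm_usage,
                 c("explicit", "implicit", "unused", "additional"))
  if (length(bad)) stop("unknown usage mark(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rows
}

#' Per-decision-point data-completeness rate
#'
#' Of the parameters clinicians rated highly relevant at a decision point
#' (free-text "additional" mentions excluded), the share the clinical
#' algorithm actually uses: explicitly marked parameters only, or also the
#' implicitly used ones when `include_implicit = TRUE`. Rounded half-up to
#' one decimal. An empty highly-relevant set yields a vacuous 100.0 (with a
#' message).
#'
#' @param survey the relevance table from [make_survey_fixture()] (or its
#'   `relevance` component), or a pre-filtered data.frame
#' @param dp decision-point id (e.g. `"DP8"`, `"DP16"`)
#' @param include_implicit count implicitly used parameters in the numerator
#' @param scale a [relevance_scale()]
#' @return completeness percentage, one decimal
#' @export
completeness_rate <- function(survey, dp, include_implicit = FALSE,
                              scale = relevance_scale()) {
  rows <- survey_dp_rows(survey, dp)
  rows <- rows[rows$algorithm_usage != "additional", , drop = FALSE]
  high <- classify_relevance(rows$relevance_pct, scale) == "high"
  den <- sum(high)
  if (den == 0L) {
    message("no highly relevant parameters at ", dp,
            ": completeness vacuously 100.0")
    return(100.0)
  }
  used <- rows$algorithm_usage == "explicit"
  if (include_implicit) used <- used | rows$algorithm_usage == "implicit"
  round_half_up(100 * sum(high & used) / den, 1)
}

#' Highly relevant parameters unused by the algorithm
#'
#' The mismatch set at a decision point: parameters clinicians rated highly
#' relevant that the clinical algorithm does not use at that point (neither
#' explicitly nor implicitly). Order-stable in survey row order.
#'
#' @inheritParams completeness_rate
#' @return character vector of parameter names
#' @export
mismatch_set <- function(survey, dp, scale = relevance_scale()) {
  rows <- survey_dp_rows(survey, dp)
  rows <- rows[rows$algorithm_usage != "additional", , drop = FALSE]
  high <- classify_relevance(rows$relevance_pct, scale) == "high"
  rows$parameter[high & rows$algorithm_usage == "unused"]
}

#' Full completeness report over all surveyed decision points
#'
#' @param survey relevance table (see [completeness_rate()])
#' @param scale a [relevance_scale()]
#' @return a `completeness_report`: data.frame with one row per decision
#'   point (counts of highly relevant / explicit / implicit / mismatched
#'   parameters and both completeness rates) and a `details` attribute
#'   holding the per-decision-point parameter sets
#' @export
completeness_report <- function(survey, scale = relevance_scale()) {
  if (is.list(survey) && !is.data.frame(survey)) survey <- survey$relevance
  dps <- unique(survey$dp)
  details <- list()
  rows <- lapply(dps, function(dp) {
    r <- survey_dp_rows(survey, dp)
    r <- r[r$algorithm_usage != "additional", , drop = FALSE]
    high <- classify_relevance(r$relevance_pct, scale) == "high"
    details[[dp]] <<- list(
      highly_relevant = r$parameter[high],
      matched_explicit = r$parameter[high & r$algorithm_usage == "explicit"],
      matched_implicit = r$parameter[high & r$algorithm_usage == "implicit"],
      mismatched = r$parameter[high & r$algorithm_usage == "unused"])
    data.frame(dp = dp,
               n_highly_relevant = sum(high),
               n_explicit = sum(high & r$algorithm_usage == "explicit"),
               n_implicit = sum(high & r$algorithm_usage == "implicit"),
               n_mismatched = sum(high & r$algorithm_usage == "unused"),
               rate_excluding_implicit =
                 completeness_rate(survey, dp, FALSE, scale),
               rate_including_implicit =
                 completeness_rate(survey, dp, TRUE, scale),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  class(out) <- c("completeness_report", "data.frame")
  out
}

#' Concordance of simulated next steps with clinician survey choices
#'
#' Per response option, the survey percentage (count / respondents, rounded
#' half-up to one decimal) and a match flag. An option matches when the
#' simulation selected it and every respondent did too, or when the
#' simulation did not select it and no respondent did; any deviation is
#' flagged for discussion, reproducing the published match/mismatch
#' accounting (where a single deviating respondent flags the option).
#'
#' @param table concordance table from [make_survey_fixture()] (or its
#'   `concordance` component): columns `dp`, `option`,
#'   `simulation_selected`, `count`, `respondents`
#' @return the table with `survey_pct` and `match` columns added, class
#'   `concordance_table`
#' @export
concordance <- function(table) {
  if (is.list(table) && !is.data.frame(table)) table <- table$concordance
  if (any(table$count > table$respondents))
    stop("survey count exceeds respondent count for option(s): ",
         paste(table$option[table$count > table$respondents], collapse = ", "),
         call. = FALSE)
  if (any(table$count < 0)) stop("negative survey count", call. = FALSE)
  table$survey_pct <- round_half_up(100 * table$count / table$respondents, 1)
  table$match <- (table$simulation_selected & table$count == table$respondents) |
    (!table$simulation_selected & table$count == 0)
  class(table) <- c("concordance_table", "data.frame")
  table
}

#' Per-decision-point concordance summary
#'
#' @param conc a `concordance_table` from [concordance()]
#' @return data.frame with per-dp option counts and number of mismatches
#' @export
concordance_summary <- function(conc) {
  dps <- unique(conc$dp)
  do.call(rbind, lapply(dps, function(dp) {
    r <- conc[conc$dp == dp, , drop = FALSE]
    data.frame(dp = dp, n_options = nrow(r),
               n_mismatched = sum(!r$match),
               mismatched_options = paste(r$option[!r$match], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Write completeness and concordance reports
#'
#' Exports the completeness report and concordance table as JSON plus a
#' human-readable Markdown summary.
#'
#' @param report a `completeness_report`
#' @param conc a `concordance_table`
#' @param dir output directory
#' @return paths of written files, invisibly
#' @export
write_evaluation_report <- function(report, conc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "evaluation.json")
  jsonlite::write_json(
    list(completeness = as.data.frame(report),
         completeness_details = attr(report, "details"),
         concordance = as.data.frame(conc)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md_path <- file.path(dir, "evaluation.md")
  lines <- c("# Data-completeness and concordance evaluation", "",
             "## Completeness per decision point", "",
             "| DP | highly relevant | explicit | implicit | mismatched | rate (excl. implicit) | rate (incl. implicit) |",
             "|----|----------------:|---------:|---------:|-----------:|----------------------:|----------------------:|")
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d | %.1f%% | %.1f%% |",
                              r$dp, r$n_highly_relevant, r$n_explicit,
                              r$n_implicit, r$n_mismatched,
                              r$rate_excluding_implicit,
                              r$rate_including_implicit))
  }
  lines <- c(lines, "", "## Next-step concordance", "",
             "| DP | option | simulation | survey | match |",
             "|----|--------|-----------|-------:|:-----:|")
  for (i in seq_len(nrow(conc))) {
    r <- conc[i, ]
    lines <- c(lines, sprintf("| %s | %s | %s | %d/%d (%.1f%%) | %s |",
                              r$dp, r$option,
                              if (r$simulation_selected) "selected" else "-",
                              r$count, r$respondents, r$survey_pct,
                              if (r$match) "x" else "MISMATCH"))
  }
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}
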