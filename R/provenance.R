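#' Whole-year lag between a query's deposition and its evidence
#'
#' The lag is `floor(days / 365.25)` of the elapsed time from `query_date`
#' to `hit_date`: 13 August 2000 to 8 March 2011 is 10 years, 4 February
#' 2002 to 28 April 2011 is 9. Negative when the hit predates the query.
#'
#' @param query_date,hit_date `Date` vectors (or ISO 8601 strings);
#'   recycled to a common length.
#' @return Integer vector of whole years.
#' @export
#' @examples
#' lag_years("2000-08-13", "2011-03-08")  # 10
lag_years <- function(query_date, hit_date) {
  q <- if (inherits(query_date, "Date")) query_date else parse_iso_date(query_date)
  h <- if (inherits(hit_date, "Date")) hit_date else parse_iso_date(hit_date)
  as.integer(floor(as.numeric(h - q) / 365.25))
}

## does a name actually name a function? informative per blacklist AND at
## least one token matching the function vocabulary (default: "-ase" words)
names_a_function <- function(name, vocabulary = c("ase$"),
                             blacklist = name_blacklist()) {
  if (is_uninformative_name(name, blacklist)) return(FALSE)
  toks <- name_tokens(name)[[1]]
  any(vapply(vocabulary, function(p) any(grepl(p, toks)), logical(1)))
}

## discrepancy flags from the two PDB-side metadata strings only
discrepancy_flags <- function(classification_header, molecule_name,
                              vocabulary = c("ase$"),
                              blacklist = name_blacklist()) {
  flags <- character(0)
  cls_unknown <- tolower(trimws(classification_header)) == "unknown function"
  if (cls_unknown &&
      names_a_function(molecule_name, vocabulary, blacklist))
    flags <- c(flags, "NAME_VS_CLASS")
  if (!cls_unknown &&
      names_a_function(classification_header, vocabulary, blacklist) &&
      is_uninformative_name(molecule_name, blacklist))
    flags <- c(flags, "CLASS_VS_NAME")
  flags
}

#' Provenance record for one triaged entry
#'
#' Collects the dates at which the entry's retained evidence became
#' available and compares them with the entry's own deposition date. The
#' evidence dates are the integration dates of the supporting sequence hits
#' (for a sequence-significant query) and the deposition date of the
#' definite structural best hit (for a structure-definite query); the
#' earliest of these is the entry's `earliest_hit_date`. Evidence available
#' on the deposition day itself does not count as postdating. Two metadata
#' discrepancy flags are raised from the entry's own PDB-side strings:
#' `NAME_VS_CLASS` when the classification header says "unknown function"
#' but the molecule name names a function, and `CLASS_VS_NAME` when the
#' header names a function but the molecule name is uninformative.
#'
#' @param entry One entry (list or one-row data frame) with `pdb_id`,
#'   `deposition_date`, `classification_header`, `molecule_name`.
#' @param seq A `sequence_evidence` object for the entry, or `NULL`.
#' @param struct A `structure_evidence` object for the entry, or `NULL`.
#' @param control A [triage_control()] (function vocabulary and blacklist).
#' @return A list of class `provenance_record`: `query_id`, `query_date`,
#'   `seq_evidence_date`, `struct_evidence_date`, `earliest_hit_date`,
#'   `hit_postdates_query`, `lag_years`, `discrepancy_flags`. Date and lag
#'   fields are `NA` when the entry has no retained evidence.
#' @export
build_provenance <- function(entry, seq = NULL, struct = NULL,
                             control = triage_control()) {
  qdate <- entry$deposition_date[[1]]
  if (is.na(qdate)) fail("provenance", "entry has no valid deposition date")
  seq_date <- as.Date(NA)
  if (!is.null(seq) && !is.null(seq$supporting_hits) &&
      nrow(seq$supporting_hits) > 0L)
    seq_date <- min(seq$supporting_hits$subject_integration_date)
  struct_date <- as.Date(NA)
  if (!is.null(struct) && identical(struct$value, "DEFINITE") &&
      !is.null(struct$best_hit))
    struct_date <- struct$best_hit$subject_deposition_date[[1]]
  earliest <- suppressWarnings(min(c(seq_date, struct_date), na.rm = TRUE))
  if (is.infinite(as.numeric(earliest))) earliest <- as.Date(NA)
  structure(list(
    query_id = as.character(entry$pdb_id[[1]]),
    query_date = qdate,
    seq_evidence_date = seq_date,
    struct_evidence_date = struct_date,
    earliest_hit_date = earliest,
    hit_postdates_query = if (is.na(earliest)) NA else earliest > qdate,
    lag_years = if (is.na(earliest)) NA_integer_ else lag_years(qdate, earliest),
    discrepancy_flags = discrepancy_flags(
      entry$classification_header[[1]], entry$molecule_name[[1]],
      control$function_vocabulary, control$blacklist)),
    class = "provenance_record")
}

#' Date accounting over a set of provenance records
#'
#' For each evidence channel, the fraction (percent, 2 decimals) of
#' evidence whose availability date strictly postdates the query's
#' deposition date: the sequence channel over sequence-significant queries,
#' the structural channel over structure-definite queries. With
#' `denominator = "queries"` (default) each query contributes once through
#' its earliest evidence date; with `"alignments"` every retained supporting
#' alignment contributes individually. Queries whose evidence strictly
#' predates them -- the set for which one would have expected the alignment
#' to have been reported -- are listed in `predating_query_ids` (sorted).
#'
#' @param records List of [build_provenance()] records.
#' @param seq_outcomes Optional named list of `sequence_evidence` objects
#'   (required for the per-alignment denominator).
#' @param denominator `"queries"` or `"alignments"`.
#' @return A list of class `date_accounting`:
#'   `fraction_hits_postdate_blast`, `fraction_hits_postdate_dali`
#'   (percent, `NA` when the channel has no evidence), and
#'   `predating_query_ids`.
#' @export
summarize_dates <- function(records, seq_outcomes = NULL,
                            denominator = c("queries", "alignments")) {
  denominator <- match.arg(denominator)
  qid <- vapply(records, `[[`, character(1), "query_id")
  qdate <- as.Date(vapply(records, function(r) as.numeric(r$query_date),
                          numeric(1)))
  seq_date <- as.Date(vapply(records, function(r) as.numeric(r$seq_evidence_date),
                             numeric(1)))
  struct_date <- as.Date(vapply(records,
                                function(r) as.numeric(r$struct_evidence_date),
                                numeric(1)))
  pct <- function(hit_dates, q_dates) {
    keep <- !is.na(hit_dates)
    if (!any(keep)) return(NA_real_)
    round_half_away(100 * sum(hit_dates[keep] > q_dates[keep]) / sum(keep), 2)
  }
  if (denominator == "queries" || is.null(seq_outcomes)) {
    blast <- pct(seq_date, qdate)
  } else {
    # per-alignment: every supporting hit's integration date counts once
    hd <- qd <- numeric(0)
    for (i in seq_along(records)) {
      ev <- seq_outcomes[[qid[i]]]
      if (is.null(ev) || is.null(ev$supporting_hits)) next
      dates <- ev$supporting_hits$subject_integration_date
      hd <- c(hd, as.numeric(dates))
      qd <- c(qd, rep(as.numeric(qdate[i]), length(dates)))
    }
    blast <- pct(as.Date(hd), as.Date(qd))
  }
  dali <- pct(struct_date, qdate)
  earliest <- as.Date(vapply(records,
                             function(r) as.numeric(r$earliest_hit_date),
                             numeric(1)))
  predating <- !is.na(earliest) & earliest < qdate
  structure(list(fraction_hits_postdate_blast = blast,
                 fraction_hits_postdate_dali = dali,
                 predating_query_ids = sort(qid[predating])),
            class = "date_accounting")
}
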