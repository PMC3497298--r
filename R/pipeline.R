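#' Run the full triage on in-memory inputs
#'
#' Applies the four stages to a corpus: annotation sufficiency for every
#' entry, sequence evidence for entries without sufficient annotation,
#' structural evidence for entries without significant sequence evidence,
#' and provenance dating for every triaged entry. Deterministic: the same
#' inputs and control always produce the same result.
#'
#' The final label per entry is `CHARACTERIZED_IN_SEQUENCE_DB` for
#' sufficiently annotated entries, `REANNOTATION_CANDIDATE` for entries with
#' significant sequence evidence or a definite structural homolog, and
#' `TRUE_UNKNOWN` otherwise. Probable structural homologs (Z-score in the
#' 8-20 band) are counted in the report but do not remove an entry from the
#' true-unknown set.
#'
#' @param entries Entry data frame ([read_structure_entries()]).
#' @param annotations Named list ([read_annotations()]).
#' @param seq_hits Named list of enriched hit data frames
#'   ([read_sequence_hits()]).
#' @param struct_hits Named list of hit data frames
#'   ([read_structure_hits()]).
#' @param control A [triage_control()].
#' @param quiet Suppress per-stage count messages.
#' @return An object of class `pdb_triage`: a list with `verdicts` (one row
#'   per entry), `funnel` (a [build_funnel()] report), `provenance` (one row
#'   per triaged entry), `dates` (a [summarize_dates()] accounting) and
#'   `control`.
#' @export
#' @examples
#' spec <- corpus_spec(n_entries = 12, statuses = c(3, 3, 3, 3),
#'                     seq_classes = c(2, 1, 2, 2, 2),
#'                     struct_classes = c(2, 2, 1, 1), seed = 7)
#' corpus <- generate_corpus(spec)
#' fit <- triage_corpus(corpus$entries, corpus$annotations,
#'                      corpus$sequence_hits, corpus$structure_hits)
#' fit
triage_corpus <- function(entries, annotations, seq_hits, struct_hits,
                          control = triage_control(), quiet = TRUE) {
  validate_entries(entries, "triage")
  n <- nrow(entries)
  if (n == 0L) fail("triage", "empty corpus")
  initial_ids <- entries$pdb_id
  say <- function(...) if (!quiet) message(sprintf(...))

  ## stage 1: annotation sufficiency
  buckets <- partition_corpus(entries, annotations, control)
  status <- attr(buckets, "status")
  say("stage annotation: in=%d sufficient=%d insufficient=%d equivalent=%d no_mapping=%d",
      n, length(buckets$SUFFICIENT), length(buckets$INSUFFICIENT),
      length(buckets$UNCHARACTERIZED_EQUIVALENT), length(buckets$NO_MAPPING))

  ## stage 2: sequence evidence for forwarded entries
  forwarded <- which(status != "SUFFICIENT")
  seq_ev <- stats::setNames(vector("list", n), initial_ids)
  sequence_class <- rep(NA_character_, n)
  for (i in forwarded) {
    ev <- classify_sequence_evidence(seq_hits[[initial_ids[i]]],
                                     control$cutoffs, control$blacklist)
    seq_ev[[i]] <- ev
    sequence_class[i] <- ev$value
  }
  significant <- !is.na(sequence_class) &
    sequence_class %in% c("SIGNIFICANT_ALL_CHARACTERIZED", "SIGNIFICANT_MIXED")
  say("stage sequence: in=%d significant=%d forwarded=%d",
      length(forwarded), sum(significant), length(forwarded) - sum(significant))

  ## stage 3: structural evidence for sequence-non-significant entries
  to_struct <- which(status != "SUFFICIENT" & !significant)
  struct_ev <- stats::setNames(vector("list", n), initial_ids)
  structure_class <- rep(NA_character_, n)
  for (i in to_struct) {
    ev <- classify_structure_evidence(struct_hits[[initial_ids[i]]],
                                      control$bands, initial_ids,
                                      control$blacklist)
    struct_ev[[i]] <- ev
    structure_class[i] <- ev$value
  }
  say("stage structure: in=%d definite=%d", length(to_struct),
      sum(structure_class == "DEFINITE", na.rm = TRUE))

  ## final labels
  final_label <- ifelse(status == "SUFFICIENT", "CHARACTERIZED_IN_SEQUENCE_DB",
                 ifelse(significant |
                          (!is.na(structure_class) &
                             structure_class == "DEFINITE"),
                        "REANNOTATION_CANDIDATE", "TRUE_UNKNOWN"))

  verdicts <- data.frame(pdb_id = initial_ids,
                         annotation_status = status,
                         sequence_class = sequence_class,
                         structure_class = structure_class,
                         final_label = final_label,
                         stringsAsFactors = FALSE)

  ## stage 4: provenance for every triaged (non-sufficient) entry
  prov_records <- vector("list", length(forwarded))
  for (k in seq_along(forwarded)) {
    i <- forwarded[k]
    prov_records[[k]] <- build_provenance(entries[i, , drop = FALSE],
                                          seq_ev[[i]], struct_ev[[i]],
                                          control)
  }
  dates <- summarize_dates(prov_records,
                           seq_outcomes = seq_ev[!vapply(seq_ev, is.null,
                                                         logical(1))],
                           denominator = control$date_denominator)
  provenance <- data.frame(
    query_id = vapply(prov_records, `[[`, character(1), "query_id"),
    query_date = as.Date(vapply(prov_records,
                                function(r) as.numeric(r$query_date),
                                numeric(1))),
    earliest_hit_date = as.Date(vapply(prov_records,
                                       function(r) as.numeric(r$earliest_hit_date),
                                       numeric(1))),
    hit_postdates_query = vapply(prov_records, function(r)
      as.logical(r$hit_postdates_query), logical(1)),
    lag_years = vapply(prov_records, function(r) as.integer(r$lag_years),
                       integer(1)),
    discrepancy_flags = vapply(prov_records, function(r)
      paste(r$discrepancy_flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  funnel <- build_funnel(verdicts)
  structure(list(verdicts = verdicts, funnel = funnel,
                 provenance = provenance, dates = dates, control = control),
            class = "pdb_triage")
}

#' @export
print.pdb_triage <- function(x, ...) {
  cat(sprintf("PDB unknown-function triage: %d entries\n",
              x$funnel$counts[["initial"]]))
  print(x$funnel)
  invisible(x)
}

#' @export
summary.pdb_triage <- function(object, ...) {
  structure(list(funnel = object$funnel, dates = object$dates,
                 n_flagged = sum(nzchar(object$provenance$discrepancy_flags))),
            class = "summary.pdb_triage")
}

#' @export
print.summary.pdb_triage <- function(x, ...) {
  print(x$funnel)
  blast <- x$dates$fraction_hits_postdate_blast
  dali <- x$dates$fraction_hits_postdate_dali
  cat("Provenance dating\n")
  cat(sprintf("  sequence evidence postdating its query  %s\n",
              if (is.na(blast)) "n/a" else sprintf("%.2f%%", blast)))
  cat(sprintf("  structural evidence postdating its query %s\n",
              if (is.na(dali)) "n/a" else sprintf("%.2f%%", dali)))
  cat(sprintf("  queries predated by their evidence      %d\n",
              length(x$dates$predating_query_ids)))
  cat(sprintf("  entries with metadata discrepancy flags %d\n", x$n_flagged))
  invisible(x)
}

#' Run the triage pipeline file-to-file
#'
#' Reads the four fixture files, runs [triage_corpus()], and (when
#' `out_dir` is given) writes `report.json`, `report.tsv`, `verdicts.tsv`
#' and `provenance.tsv`. Any stage validation error aborts with a
#' stage-named message. Re-running on identical inputs produces
#' byte-identical outputs.
#'
#' @param entries_path,annotations_path,seq_hits_path,struct_hits_path
#'   Paths to the four input files.
#' @param control A [triage_control()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param quiet Suppress per-stage count messages.
#' @return The `pdb_triage` object, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(entries_path, annotations_path, seq_hits_path,
                         struct_hits_path, control = triage_control(),
                         out_dir = NULL, quiet = FALSE) {
  entries <- read_structure_entries(entries_path)
  annotations <- read_annotations(annotations_path)
  seq_hits <- read_sequence_hits(seq_hits_path, annotations,
                                 strict = control$strict_hits)
  struct_hits <- read_structure_hits(struct_hits_path)
  result <- triage_corpus(entries, annotations, seq_hits, struct_hits,
                          control, quiet = quiet)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(result$funnel, file.path(out_dir, "report.json"), "json")
    write_report(result$funnel, file.path(out_dir, "report.tsv"), "tsv")
    verd <- result$verdicts
    verd$sequence_class[is.na(verd$sequence_class)] <- ""
    verd$structure_class[is.na(verd$structure_class)] <- ""
    write_tsv(verd, file.path(out_dir, "verdicts.tsv"))
    prov <- result$provenance
    prov$query_date <- format(prov$query_date, "%Y-%m-%d")
    prov$earliest_hit_date <- ifelse(is.na(prov$earliest_hit_date), "",
                                     format(prov$earliest_hit_date, "%Y-%m-%d"))
    prov$hit_postdates_query <- ifelse(is.na(prov$hit_postdates_query), "",
                                       ifelse(prov$hit_postdates_query,
                                              "TRUE", "FALSE"))
    prov$lag_years <- ifelse(is.na(prov$lag_years), "",
                             as.character(prov$lag_years))
    write_tsv(prov, file.path(out_dir, "provenance.tsv"))
    return(invisible(result))
  }
  result
}
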