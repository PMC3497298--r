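#' Percentage with two decimals, half away from zero
#'
#' All percentages in the funnel report are recomputed from integer counts
#' with this function: `100 * numerator / denominator`, rounded to two
#' decimal places with halves away from zero (so 34.0525... prints as
#' 34.05 and 22.486... as 22.49).
#'
#' @param numerator Non-negative count.
#' @param denominator Positive count.
#' @return Numeric scalar (percent).
#' @export
#' @examples
#' percentage(1084, 2549)  # 42.53
percentage <- function(numerator, denominator) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
    fail("report", "percentage() needs a positive denominator")
  if (any(is.na(numerator)) || any(numerator < 0))
    fail("report", "percentage() needs non-negative numerators")
  round_half_away(100 * numerator / denominator, 2)
}

#' Assemble the funnel report from per-entry verdicts
#'
#' Tabulates a complete corpus run into the triage funnel: the four
#' annotation-status buckets, the sequence-stage and structure-stage class
#' counts, the re-annotation candidate and true-unknown sets, and every
#' derived percentage. Counts are validated against the stage-conservation
#' identities (initial = sum of status buckets; forwarded-to-sequence =
#' initial - sufficient; forwarded-to-structure = forwarded-to-sequence -
#' sequence-significant; true unknowns = forwarded-to-structure - definite)
#' and an inconsistent verdict table is an error.
#'
#' @param verdicts Data frame with columns `pdb_id`, `annotation_status`,
#'   `sequence_class` (`NA` for sufficient entries), `structure_class`
#'   (`NA` unless the entry reached stage 3) and `final_label`.
#' @return A list of class `funnel_report` with elements `counts` (named
#'   integer vector), `percent` (named numeric vector), `true_unknown_ids`
#'   and `reannotation_candidate_ids` (both sorted), and `table` (the
#'   stage/count/percent data frame written to `report.tsv`).
#' @export
build_funnel <- function(verdicts) {
  need <- c("pdb_id", "annotation_status", "sequence_class",
            "structure_class", "final_label")
  miss <- setdiff(need, names(verdicts))
  if (length(miss))
    fail("report", "verdict table lacks column(s): ",
         paste(miss, collapse = ", "))
  v <- verdicts
  seq_present <- !is.na(v$sequence_class)
  if (!identical(unname(seq_present), unname(v$annotation_status != "SUFFICIENT")))
    fail("report", "internal consistency error: sequence evidence must be ",
         "present exactly for non-sufficient entries")
  significant <- seq_present & v$sequence_class %in%
    c("SIGNIFICANT_ALL_CHARACTERIZED", "SIGNIFICANT_MIXED")
  struct_present <- !is.na(v$structure_class)
  if (!identical(unname(struct_present), unname(seq_present & !significant)))
    fail("report", "internal consistency error: structure evidence must be ",
         "present exactly for sequence-non-significant entries")

  status_counts <- vapply(ANNOTATION_STATUSES,
                          function(s) sum(v$annotation_status == s), integer(1))
  seq_counts <- summarize_sequence_stage(v$sequence_class[seq_present])
  struct_counts <- summarize_structure_stage(v$structure_class[struct_present])

  initial <- nrow(v)
  fwd_seq <- initial - status_counts[["SUFFICIENT"]]
  fwd_struct <- fwd_seq - seq_counts[["SIGNIFICANT"]]
  true_unknown <- fwd_struct - struct_counts[["DEFINITE"]]
  candidates <- seq_counts[["SIGNIFICANT"]] + struct_counts[["DEFINITE"]]

  label_counts <- vapply(FINAL_LABELS, function(l) sum(v$final_label == l),
                         integer(1))
  if (label_counts[["TRUE_UNKNOWN"]] != true_unknown ||
      label_counts[["REANNOTATION_CANDIDATE"]] != candidates ||
      label_counts[["CHARACTERIZED_IN_SEQUENCE_DB"]] !=
        status_counts[["SUFFICIENT"]])
    fail("report", "internal consistency error: final labels disagree with ",
         "stage counts")

  counts <- c(initial = initial,
              status_counts,
              ANNOTATED_IN_SEQUENCE_DB = unname(status_counts[["SUFFICIENT"]] +
                                                  status_counts[["INSUFFICIENT"]]),
              forwarded_to_sequence = unname(fwd_seq),
              stats::setNames(seq_counts, paste0("seq_", names(seq_counts))),
              forwarded_to_structure = unname(fwd_struct),
              stats::setNames(struct_counts,
                              paste0("struct_", names(struct_counts))),
              reannotation_candidates = unname(candidates),
              true_unknown = unname(true_unknown))

  percent <- c(
    sufficient_of_initial = percentage(status_counts[["SUFFICIENT"]], initial),
    annotated_of_initial = percentage(counts[["ANNOTATED_IN_SEQUENCE_DB"]],
                                      initial),
    true_unknown_of_initial = percentage(true_unknown, initial),
    candidates_of_initial = percentage(candidates, initial))
  if (fwd_seq > 0) {
    percent <- c(percent,
      seq_significant_of_queries = percentage(seq_counts[["SIGNIFICANT"]],
                                              fwd_seq),
      seq_discarded_only_of_queries = percentage(seq_counts[["DISCARDED_ONLY"]],
                                                 fwd_seq),
      seq_no_hits_of_queries = percentage(seq_counts[["NO_HITS"]], fwd_seq),
      seq_sub_threshold_of_queries = percentage(seq_counts[["SUB_THRESHOLD"]],
                                                fwd_seq))
  }
  if (fwd_struct > 0) {
    percent <- c(percent,
      struct_definite_of_queries = percentage(struct_counts[["DEFINITE"]],
                                              fwd_struct),
      struct_probable_of_queries = percentage(struct_counts[["PROBABLE"]],
                                              fwd_struct),
      struct_definite_or_probable_of_queries =
        percentage(struct_counts[["DEFINITE_OR_PROBABLE"]], fwd_struct))
  }

  tbl <- data.frame(
    stage = c("initial",
              paste0("status_", ANNOTATION_STATUSES),
              "annotated_in_sequence_db",
              "forwarded_to_sequence",
              paste0("seq_", names(seq_counts)),
              "forwarded_to_structure",
              paste0("struct_", names(struct_counts)),
              "reannotation_candidates",
              "true_unknown"),
    count = c(initial, unname(status_counts),
              counts[["ANNOTATED_IN_SEQUENCE_DB"]],
              fwd_seq, unname(seq_counts), fwd_struct, unname(struct_counts),
              candidates, true_unknown),
    stringsAsFactors = FALSE)
  denom <- c(initial, rep(initial, length(ANNOTATION_STATUSES)), initial,
             initial, rep(max(fwd_seq, 1L), length(seq_counts)),
             max(fwd_seq, 1L), rep(max(fwd_struct, 1L), length(struct_counts)),
             initial, initial)
  tbl$percent <- sprintf("%.2f", vapply(seq_len(nrow(tbl)), function(i)
    percentage(tbl$count[i], denom[i]), numeric(1)))

  structure(list(counts = counts,
                 percent = percent,
                 true_unknown_ids = sort(v$pdb_id[v$final_label ==
                                                    "TRUE_UNKNOWN"]),
                 reannotation_candidate_ids =
                   sort(v$pdb_id[v$final_label == "REANNOTATION_CANDIDATE"]),
                 table = tbl),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Triage funnel report\n")
  cat(sprintf("  initial entries          %6d\n", x$counts[["initial"]]))
  cat(sprintf("  sufficiently annotated   %6d (%.2f%%)\n",
              x$counts[["SUFFICIENT"]], x$percent[["sufficient_of_initial"]]))
  cat(sprintf("  forwarded to sequence    %6d\n",
              x$counts[["forwarded_to_sequence"]]))
  if ("seq_significant_of_queries" %in% names(x$percent))
    cat(sprintf("  sequence-significant     %6d (%.2f%% of queries)\n",
                x$counts[["seq_SIGNIFICANT"]],
                x$percent[["seq_significant_of_queries"]]))
  cat(sprintf("  forwarded to structure   %6d\n",
              x$counts[["forwarded_to_structure"]]))
  if ("struct_definite_of_queries" %in% names(x$percent))
    cat(sprintf("  definite homologs        %6d (%.2f%% of queries)\n",
                x$counts[["struct_DEFINITE"]],
                x$percent[["struct_definite_of_queries"]]))
  cat(sprintf("  re-annotation candidates %6d (%.2f%% of initial)\n",
              x$counts[["reannotation_candidates"]],
              x$percent[["candidates_of_initial"]]))
  cat(sprintf("  true unknowns            %6d (%.2f%% of initial)\n",
              x$counts[["true_unknown"]],
              x$percent[["true_unknown_of_initial"]]))
  invisible(x)
}

#' Write a funnel report to disk
#'
#' `format = "json"` serializes counts, percentages and the sorted ID lists;
#' `format = "tsv"` writes the stage/count/percent table (one row per funnel
#' node). Both round-trip through [read_report()].
#'
#' @param report A [build_funnel()] result.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  if (!inherits(report, "funnel_report"))
    fail("report", "write_report() needs a funnel_report object")
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(counts = as.list(report$counts),
                    percent = as.list(report$percent),
                    true_unknown_ids = report$true_unknown_ids,
                    reannotation_candidate_ids =
                      report$reannotation_candidate_ids)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write_tsv(report$table, path)
  }
  invisible(path)
}

#' Read back a funnel report
#'
#' @param path Path written by [write_report()].
#' @param format `"json"` or `"tsv"`.
#' @return For `"json"`, a list with `counts`, `percent` and the two ID
#'   lists; for `"tsv"`, the stage/count/percent data frame.
#' @export
read_report <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    out$counts <- unlist(out$counts)
    out$percent <- unlist(out$percent)
    out
  } else {
    df <- read_tsv(path, "report")
    df$count <- as.integer(df$count)
    df
  }
}
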