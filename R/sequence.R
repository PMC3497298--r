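#' Is a sequence hit's subject a characterized protein?
#'
#' A hit counts as characterized when its subject's record name is
#' informative, i.e. passes the same whole-word blacklist used in the
#' annotation stage. Hits to subjects named "Probable ...", "Putative ..."
#' and the like are discarded from the evidence.
#'
#' @param hit A hit row (list or one-row data frame) with a `subject_name`
#'   field.
#' @param blacklist A [name_blacklist()].
#' @return Single logical.
#' @export
hit_is_characterized <- function(hit, blacklist = name_blacklist()) {
  !is_uninformative_name(hit$subject_name[[1]], blacklist)
}

#' GO domains supported by one sequence hit
#'
#' A domain is supported when the subject carries at least one GO term in
#' it and the alignment's percent identity strictly exceeds the domain's
#' cutoff. For the molecular-function domain the "*-binding" exclusion
#' applies on top: at least one of the subject's MF term names must not end
#' in "binding", otherwise the MF domain is not supported.
#'
#' @param hit A hit row with `percent_identity` and a `subject_go` GO table
#'   (directly, or as the `subject_go` list-column element of an enriched
#'   hit data frame).
#' @param cutoffs An [identity_cutoffs()] vector.
#' @return Character vector of supported domain names (possibly empty).
#' @export
#' @examples
#' h <- list(percent_identity = 45,
#'           subject_go = go_terms("GO:0006096", "BIOLOGICAL_PROCESS",
#'                                 "glycolytic process"))
#' hit_supported_domains(h, identity_cutoffs())
hit_supported_domains <- function(hit, cutoffs = identity_cutoffs()) {
  pid <- as.numeric(hit$percent_identity[[1]])
  go <- hit$subject_go
  if (is.list(go) && !is.data.frame(go)) go <- go[[1]]
  if (is.null(go) || nrow(go) == 0L) return(character(0))
  supported <- character(0)
  for (d in GO_DOMAINS) {
    in_d <- go$domain == d
    if (!any(in_d)) next
    if (!(pid > cutoffs[[d]])) next
    if (d == "MOLECULAR_FUNCTION" &&
        all(ends_in_binding(go$term_name[in_d]))) next
    supported <- c(supported, d)
  }
  supported
}

#' Classify one query's sequence-evidence outcome
#'
#' Partitions the query's hits into: `S`, characterized hits supporting at
#' least one GO domain; `D`, hits discarded because the subject name is
#' uninformative; and `T`, characterized hits supporting no domain
#' (sub-threshold). The outcome is
#'
#' * `NO_HITS` -- no hits at all;
#' * `SIGNIFICANT_ALL_CHARACTERIZED` -- `S` non-empty, `D` empty;
#' * `SIGNIFICANT_MIXED` -- `S` and `D` both non-empty;
#' * `DISCARDED_ONLY` -- only discarded hits (`S`, `T` empty);
#' * `SUB_THRESHOLD` -- otherwise (`S` empty, `T` non-empty).
#'
#' @param hits Enriched hit data frame for one query (an element of
#'   [read_sequence_hits()]'s result), or `NULL` / zero rows.
#' @param cutoffs An [identity_cutoffs()] vector.
#' @param blacklist A [name_blacklist()].
#' @return A list of class `sequence_evidence` with elements `value` (the
#'   outcome string) and `supporting_hits` (the rows of `S`, possibly empty).
#' @export
classify_sequence_evidence <- function(hits, cutoffs = identity_cutoffs(),
                                       blacklist = name_blacklist()) {
  empty <- is.null(hits) || nrow(hits) == 0L
  if (empty) {
    return(structure(list(value = "NO_HITS", supporting_hits = NULL),
                     class = "sequence_evidence"))
  }
  n <- nrow(hits)
  characterized <- !is_uninformative_name(hits$subject_name, blacklist)
  supported <- logical(n)
  for (i in seq_len(n)) {
    supported[i] <- characterized[i] && length(hit_supported_domains(
      list(percent_identity = hits$percent_identity[i],
           subject_go = hits$subject_go[[i]]), cutoffs)) > 0L
  }
  s <- supported                      # significant, characterized
  d <- !characterized                 # name-discarded
  t <- characterized & !supported     # characterized but sub-threshold
  value <- if (any(s)) {
    if (any(d)) "SIGNIFICANT_MIXED" else "SIGNIFICANT_ALL_CHARACTERIZED"
  } else if (any(d) && !any(t)) {
    "DISCARDED_ONLY"
  } else {
    "SUB_THRESHOLD"
  }
  structure(list(value = value,
                 supporting_hits = if (any(s)) hits[s, , drop = FALSE] else NULL),
            class = "sequence_evidence")
}

#' Tabulate sequence-stage outcomes
#'
#' Counts queries per outcome class and adds the derived `SIGNIFICANT` row
#' (all-characterized plus mixed). Counts over the five primitive classes
#' sum to the number of queries.
#'
#' @param outcomes Named list of `sequence_evidence` objects (or a character
#'   vector of outcome values), one per query.
#' @return Named integer vector over the five outcome classes plus
#'   `SIGNIFICANT`.
#' @export
summarize_sequence_stage <- function(outcomes) {
  values <- if (is.character(outcomes)) outcomes
            else vapply(outcomes, `[[`, character(1), "value")
  counts <- vapply(SEQUENCE_CLASSES, function(cl) sum(values == cl), integer(1))
  c(counts, SIGNIFICANT = unname(counts[["SIGNIFICANT_ALL_CHARACTERIZED"]] +
                                   counts[["SIGNIFICANT_MIXED"]]))
}
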