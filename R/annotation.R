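#' Does a free-text name carry no functional information?
#'
#' A name is uninformative when any blacklist keyword occurs in it as a
#' whole word, case-insensitively, on alphanumeric token boundaries
#' ("Probable kinase" matches, "probability" does not), or when the name is
#' empty or whitespace.
#'
#' @param name Character vector of names (vectorized).
#' @param blacklist A [name_blacklist()].
#' @return Logical vector.
#' @export
#' @examples
#' is_uninformative_name(c("Hypothetical protein ybdK",
#'                         "Walker type ATP-ase", ""))
is_uninformative_name <- function(name, blacklist = name_blacklist()) {
  name <- as.character(name)
  toks <- name_tokens(name)
  out <- vapply(toks, function(t) any(t %in% blacklist), logical(1))
  out | is.na(name) | !nzchar(trimws(name))
}

## does a GO term name end in the token "binding" ("ATP binding",
## "metal ion binding", "Zinc-binding")? case-insensitive, token-based
ends_in_binding <- function(term_name) {
  vapply(name_tokens(term_name), function(t) {
    length(t) > 0L && t[length(t)] == "binding"
  }, logical(1))
}

#' Is a GO profile sufficient functional characterization?
#'
#' A profile qualifies when it has at least `min_terms` terms, unless every
#' term is from the cellular-component ontology (pure localization) or every
#' term name ends in "binding" (pure binding vocabulary) -- either exception
#' makes the profile insufficient regardless of its size.
#'
#' @param terms A [go_terms()] data frame (may have zero rows).
#' @param min_terms Minimum term count (default 3).
#' @return Single logical.
#' @export
#' @examples
#' go_profile_sufficient(go_terms(
#'   c("GO:0016301", "GO:0006096", "GO:0005737"),
#'   c("MOLECULAR_FUNCTION", "BIOLOGICAL_PROCESS", "CELLULAR_COMPONENT"),
#'   c("kinase activity", "glycolytic process", "cytoplasm")))
go_profile_sufficient <- function(terms, min_terms = 3) {
  n <- if (is.null(terms)) 0L else nrow(terms)
  if (n < min_terms) return(FALSE)
  if (all(terms$domain == "CELLULAR_COMPONENT")) return(FALSE)
  if (all(ends_in_binding(terms$term_name))) return(FALSE)
  TRUE
}

## sufficiency verdict for one resolved annotation record
record_status <- function(rec, blacklist, min_terms) {
  if (is_uninformative_name(rec$protein_name, blacklist))
    return("UNCHARACTERIZED_EQUIVALENT")
  annotated <- nzchar(trimws(rec$function_text)) ||
    nzchar(trimws(rec$catalytic_activity)) ||
    length(rec$ec_numbers) > 0L ||
    go_profile_sufficient(rec$go_terms, min_terms)
  if (annotated) "SUFFICIENT" else "INSUFFICIENT"
}

#' Annotation-sufficiency status of one structure entry
#'
#' Resolves the entry's accessions against the annotations mapping and
#' decides the stage-1 status:
#'
#' * `NO_MAPPING` -- no accession resolves to a record;
#' * `UNCHARACTERIZED_EQUIVALENT` -- the record's own name is uninformative
#'   (this dominates: no amount of GO annotation rescues such a record);
#' * `SUFFICIENT` -- the record has a function text, a catalytic activity,
#'   an EC number, or a sufficient GO profile ([go_profile_sufficient()]);
#' * `INSUFFICIENT` -- otherwise.
#'
#' With `accession_policy = "any-sufficient"` (the default) an entry mapping
#' to several records is `SUFFICIENT` if any resolvable record is, since the
#' evidence is disjunctive; otherwise the first resolvable record decides.
#' With `"first"` only the first resolvable record is consulted.
#'
#' @param entry One entry: a list or one-row data frame with an `accessions`
#'   field (character vector, possibly via list column).
#' @param annotations Named list from [read_annotations()].
#' @param blacklist A [name_blacklist()].
#' @param min_terms Minimum GO term count for sufficiency.
#' @param accession_policy `"any-sufficient"` or `"first"`.
#' @return One of the four `AnnotationStatus` strings.
#' @export
classify_annotation_status <- function(entry, annotations,
                                       blacklist = name_blacklist(),
                                       min_terms = 3,
                                       accession_policy = c("any-sufficient",
                                                            "first")) {
  accession_policy <- match.arg(accession_policy)
  acc <- entry$accessions
  if (is.list(acc)) acc <- acc[[1]]
  acc <- acc[!is.na(acc) & nzchar(acc)]
  acc <- acc[acc %in% names(annotations)]
  if (length(acc) == 0L) return("NO_MAPPING")
  if (accession_policy == "first") {
    return(record_status(annotations[[acc[[1]]]], blacklist, min_terms))
  }
  statuses <- vapply(acc, function(a)
    record_status(annotations[[a]], blacklist, min_terms), character(1))
  if (any(statuses == "SUFFICIENT")) "SUFFICIENT" else statuses[[1]]
}

#' Partition a corpus by annotation status
#'
#' Applies [classify_annotation_status()] to every entry and groups the
#' entry IDs by status. The buckets are disjoint and exhaustive and preserve
#' input order within each bucket; entries with status other than
#' `SUFFICIENT` proceed to the sequence-evidence stage.
#'
#' @param entries Entry data frame ([read_structure_entries()]).
#' @param annotations Named list from [read_annotations()].
#' @param control A [triage_control()].
#' @return Named list of character vectors, one per `AnnotationStatus`
#'   (empty vectors for empty buckets), with a `"status"` attribute giving
#'   the per-entry status vector in input order.
#' @export
partition_corpus <- function(entries, annotations,
                             control = triage_control()) {
  validate_entries(entries, "triage")
  n <- nrow(entries)
  status <- character(n)
  for (i in seq_len(n)) {
    status[i] <- classify_annotation_status(
      list(accessions = entries$accessions[[i]]), annotations,
      blacklist = control$blacklist, min_terms = control$min_go_terms,
      accession_policy = control$accession_policy)
  }
  out <- lapply(ANNOTATION_STATUSES,
                function(s) entries$pdb_id[status == s])
  names(out) <- ANNOTATION_STATUSES
  attr(out, "status") <- status
  out
}
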