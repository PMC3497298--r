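#' Is a structural hit admissible as functional evidence?
#'
#' A hit is admissible only when its subject (i) is not itself part of the
#' initial unknown-function dataset, (ii) is not classified "unknown
#' function" (case-insensitive), (iii) has a classification header that
#' does not ambiguously describe a function (the header passes the
#' uninformative-name blacklist), and (iv) has an informative subject name.
#'
#' @param hit A hit row (list or one-row data frame) with `subject_pdb_id`,
#'   `subject_classification` and `subject_name` fields.
#' @param initial_dataset Character vector (or set) of the corpus entry IDs.
#' @param blacklist A [name_blacklist()].
#' @return Single logical.
#' @export
hit_is_admissible <- function(hit, initial_dataset,
                              blacklist = name_blacklist()) {
  cls <- as.character(hit$subject_classification[[1]])
  !(hit$subject_pdb_id[[1]] %in% initial_dataset) &&
    tolower(trimws(cls)) != "unknown function" &&
    !is_uninformative_name(cls, blacklist) &&
    !is_uninformative_name(hit$subject_name[[1]], blacklist)
}

#' Band a structural-alignment Z-score into a homology class
#'
#' Strictly above `definite_above` is `DEFINITE`, strictly below
#' `probable_floor` is `UNRELATED`, and the closed interval between them --
#' including both boundary values -- is `PROBABLE`. A step function of `z`,
#' weakly monotone, with breakpoints exactly at the two band edges.
#'
#' @param z Numeric vector of Z-scores (any sign).
#' @param bands A [z_score_bands()] object.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_z(c(39.5, 20, 8, 7.9))
classify_z <- function(z, bands = z_score_bands()) {
  z <- as.numeric(z)
  ifelse(z > bands$definite_above, "DEFINITE",
         ifelse(z < bands$probable_floor, "UNRELATED", "PROBABLE"))
}

#' Classify one query's structural-evidence outcome
#'
#' Inadmissible hits ([hit_is_admissible()]) are removed first; with no
#' admissible hit left the outcome is `NO_HITS`. Otherwise the outcome is
#' the [classify_z()] class of the best admissible hit -- the maximum
#' Z-score, ties broken by lexicographically smallest subject ID.
#'
#' @param hits Hit data frame for one query (an element of
#'   [read_structure_hits()]'s result), or `NULL`.
#' @param bands A [z_score_bands()] object.
#' @param initial_dataset Character vector of corpus entry IDs.
#' @param blacklist A [name_blacklist()].
#' @return A list of class `structure_evidence` with elements `value` and
#'   `best_hit` (one-row data frame, or `NULL` for `NO_HITS`).
#' @export
classify_structure_evidence <- function(hits, bands = z_score_bands(),
                                        initial_dataset = character(0),
                                        blacklist = name_blacklist()) {
  no_hits <- structure(list(value = "NO_HITS", best_hit = NULL),
                       class = "structure_evidence")
  if (is.null(hits) || nrow(hits) == 0L) return(no_hits)
  adm <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    adm[i] <- hit_is_admissible(hits[i, , drop = FALSE], initial_dataset,
                                blacklist)
  }
  if (!any(adm)) return(no_hits)
  hits <- hits[adm, , drop = FALSE]
  ord <- order(-hits$z_score, hits$subject_pdb_id)
  best <- hits[ord[1], , drop = FALSE]
  structure(list(value = classify_z(best$z_score, bands), best_hit = best),
            class = "structure_evidence")
}

#' Tabulate structure-stage outcomes
#'
#' Counts queries per homology class and adds the derived
#' `DEFINITE_OR_PROBABLE` row. The four primitive classes sum to the number
#' of queries.
#'
#' @param outcomes Named list of `structure_evidence` objects (or a
#'   character vector of outcome values), one per query.
#' @return Named integer vector over the four classes plus
#'   `DEFINITE_OR_PROBABLE` and the combined `UNRELATED_OR_NO_HITS`.
#' @export
summarize_structure_stage <- function(outcomes) {
  values <- if (is.character(outcomes)) outcomes
            else vapply(outcomes, `[[`, character(1), "value")
  counts <- vapply(STRUCTURE_CLASSES, function(cl) sum(values == cl),
                   integer(1))
  c(counts,
    DEFINITE_OR_PROBABLE = unname(counts[["DEFINITE"]] + counts[["PROBABLE"]]),
    UNRELATED_OR_NO_HITS = unname(counts[["UNRELATED"]] + counts[["NO_HITS"]]))
}
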