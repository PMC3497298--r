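#' Default blacklist of uninformative name keywords
#'
#' Protein and header names containing any of these words (as whole words,
#' case-insensitively) are treated as carrying no functional information:
#' a record named "Putative uncharacterized protein" tells us nothing about
#' what the protein does.
#'
#' @param keywords Character vector of lowercase keywords.
#' @return A character vector of class `name_blacklist`.
#' @seealso [is_uninformative_name()]
#' @export
#' @examples
#' name_blacklist()
name_blacklist <- function(keywords = c("uncharacterized", "putative",
                                        "unknown", "predicted", "unnamed",
                                        "probable", "hypothetical")) {
  keywords <- as.character(keywords)
  if (length(keywords) == 0L) fail("control", "blacklist must be non-empty")
  if (any(keywords != tolower(keywords)))
    fail("control", "blacklist keywords must be lowercase")
  structure(unique(keywords), class = "name_blacklist")
}

#' Per-GO-domain percent identity cutoffs for sequence evidence
#'
#' A sequence alignment only supports transfer of a subject's GO terms in a
#' given ontology domain when the percent identity strictly exceeds the
#' domain's cutoff. The defaults (40 / 50 / 60 for biological process,
#' molecular function, cellular component) correspond to identity levels at
#' which a randomly selected protein pair shares roughly 70% of its GO terms.
#'
#' @param biological_process,molecular_function,cellular_component
#'   Percent thresholds, each in (0, 100].
#' @return Named numeric vector of class `identity_cutoffs`, with one element
#'   per GO domain.
#' @export
#' @examples
#' identity_cutoffs()
identity_cutoffs <- function(biological_process = 40,
                             molecular_function = 50,
                             cellular_component = 60) {
  v <- c(BIOLOGICAL_PROCESS = as.numeric(biological_process),
         MOLECULAR_FUNCTION = as.numeric(molecular_function),
         CELLULAR_COMPONENT = as.numeric(cellular_component))
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 100))
    fail("control", "identity cutoffs must lie in (0, 100]")
  structure(v, class = "identity_cutoffs")
}

#' Z-score bands for structural homology classes
#'
#' Structural alignments are banded by Z-score: strictly above
#' `definite_above` is a definite homolog, between `probable_floor` and
#' `definite_above` (inclusive at both ends) a probable homolog, and strictly
#' below `probable_floor` probably unrelated.
#'
#' @param definite_above Definite-homolog threshold (default 20).
#' @param probable_floor Lower bound of the probable band (default 8).
#' @return A list of class `z_score_bands`.
#' @export
z_score_bands <- function(definite_above = 20, probable_floor = 8) {
  definite_above <- as.numeric(definite_above)
  probable_floor <- as.numeric(probable_floor)
  if (!is.finite(definite_above) || !is.finite(probable_floor) ||
      !(definite_above > probable_floor) || !(probable_floor > 0))
    fail("control", "bands must satisfy definite_above > probable_floor > 0")
  structure(list(definite_above = definite_above,
                 probable_floor = probable_floor),
            class = "z_score_bands")
}

#' Control parameters for the triage pipeline
#'
#' Collects every tunable of the four stages in one object with the defaults
#' used throughout: the uninformative-name blacklist, the minimum GO term
#' count, the per-domain identity cutoffs, the Z-score bands, and the
#' provenance options.
#'
#' @param min_go_terms Minimum number of GO terms for a profile to count as
#'   sufficient (default 3).
#' @param blacklist A [name_blacklist()].
#' @param accession_policy How to combine multiple mapped accessions:
#'   `"any-sufficient"` (an entry is sufficiently annotated if any resolvable
#'   record is; the first resolvable record is otherwise decisive) or
#'   `"first"` (only the first resolvable record is consulted).
#' @param cutoffs An [identity_cutoffs()] vector.
#' @param bands A [z_score_bands()] object.
#' @param date_denominator Denominator convention for the postdating
#'   fractions: per `"queries"` (default) or per `"alignments"`.
#' @param function_vocabulary Regular expressions matched against name tokens
#'   to decide whether a free-text name names a function (default: tokens
#'   ending in "ase", e.g. "kinase", "ligase", "ATP-ase").
#' @param strict_hits If `TRUE`, a sequence hit whose subject accession is
#'   absent from the annotations mapping is an error; if `FALSE` (default)
#'   such hits are flagged and excluded.
#' @return A list of class `triage_control`.
#' @export
#' @examples
#' ctl <- triage_control(min_go_terms = 4)
#' ctl$cutoffs
triage_control <- function(min_go_terms = 3,
                           blacklist = name_blacklist(),
                           accession_policy = c("any-sufficient", "first"),
                           cutoffs = identity_cutoffs(),
                           bands = z_score_bands(),
                           date_denominator = c("queries", "alignments"),
                           function_vocabulary = c("ase$"),
                           strict_hits = FALSE) {
  min_go_terms <- as.integer(min_go_terms)
  if (is.na(min_go_terms) || min_go_terms < 1L)
    fail("control", "min_go_terms must be a positive integer")
  if (!inherits(blacklist, "name_blacklist")) blacklist <- name_blacklist(blacklist)
  if (!inherits(cutoffs, "identity_cutoffs"))
    cutoffs <- do.call(identity_cutoffs, as.list(unname(cutoffs)))
  if (!inherits(bands, "z_score_bands"))
    bands <- do.call(z_score_bands, as.list(bands))
  structure(list(min_go_terms = min_go_terms,
                 blacklist = blacklist,
                 accession_policy = match.arg(accession_policy),
                 cutoffs = cutoffs,
                 bands = bands,
                 date_denominator = match.arg(date_denominator),
                 function_vocabulary = as.character(function_vocabulary),
                 strict_hits = isTRUE(strict_hits)),
            class = "triage_control")
}

#' Read a triage configuration file
#'
#' Reads a YAML configuration whose keys mirror the stage config names
#' (`triage.min_go_terms`, `triage.name_blacklist`, `triage.accession_policy`,
#' `seq.cutoff_bp`, `seq.cutoff_mf`, `seq.cutoff_cc`, `struct.z_definite`,
#' `struct.z_probable_floor`, `dates.fraction_denominator`,
#' `dates.function_vocabulary`) and returns the corresponding
#' [triage_control()]. Keys may be flat ("seq.cutoff_bp: 40") or nested under
#' a section ("seq: {cutoff_bp: 40}"). Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `triage_control` object.
#' @export
read_triage_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    fail("config", "the 'yaml' package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  get_key <- function(section, key) {
    flat <- raw[[paste(section, key, sep = ".")]]
    if (!is.null(flat)) return(flat)
    sec <- raw[[section]]
    if (is.list(sec)) sec[[key]] else NULL
  }
  ctl <- triage_control()
  args <- list(
    min_go_terms = get_key("triage", "min_go_terms") %||% ctl$min_go_terms,
    blacklist = name_blacklist(get_key("triage", "name_blacklist") %||%
                                 unclass(ctl$blacklist)),
    accession_policy = get_key("triage", "accession_policy") %||%
      ctl$accession_policy,
    cutoffs = identity_cutoffs(
      get_key("seq", "cutoff_bp") %||% ctl$cutoffs[["BIOLOGICAL_PROCESS"]],
      get_key("seq", "cutoff_mf") %||% ctl$cutoffs[["MOLECULAR_FUNCTION"]],
      get_key("seq", "cutoff_cc") %||% ctl$cutoffs[["CELLULAR_COMPONENT"]]),
    bands = z_score_bands(
      get_key("struct", "z_definite") %||% ctl$bands$definite_above,
      get_key("struct", "z_probable_floor") %||% ctl$bands$probable_floor),
    date_denominator = get_key("dates", "fraction_denominator") %||%
      ctl$date_denominator,
    function_vocabulary = get_key("dates", "function_vocabulary") %||%
      ctl$function_vocabulary)
  do.call(triage_control, args)
}
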