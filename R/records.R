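#' Build a table of GO term annotations
#'
#' Convenience constructor for the small data frame used throughout the
#' package to represent a protein's Gene Ontology profile. Inputs are
#' recycled to a common length and validated against the GO accession
#' pattern and the three ontology domains.
#'
#' @param go_id GO accessions, `"GO:"` followed by 7 digits.
#' @param domain One of `"BIOLOGICAL_PROCESS"`, `"MOLECULAR_FUNCTION"`,
#'   `"CELLULAR_COMPONENT"` per term.
#' @param term_name Free-text term names (e.g. `"kinase activity"`).
#' @param evidence_code Optional evidence codes (e.g. `"IEA"`); not used by
#'   any classification rule.
#' @return A data frame with columns `go_id`, `domain`, `term_name`,
#'   `evidence_code`.
#' @export
#' @examples
#' go_terms(c("GO:0016301", "GO:0006096"),
#'          c("MOLECULAR_FUNCTION", "BIOLOGICAL_PROCESS"),
#'          c("kinase activity", "glycolytic process"))
go_terms <- function(go_id = character(0), domain = character(0),
                     term_name = character(0), evidence_code = NA_character_) {
  n <- max(length(go_id), length(domain), length(term_name))
  if (n == 0L) {
    return(data.frame(go_id = character(0), domain = character(0),
                      term_name = character(0), evidence_code = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(go_id = rep_len(as.character(go_id), n),
                   domain = rep_len(as.character(domain), n),
                   term_name = rep_len(as.character(term_name), n),
                   evidence_code = rep_len(as.character(evidence_code), n),
                   stringsAsFactors = FALSE)
  bad <- !is_valid_go_id(df$go_id)
  if (any(bad))
    fail("records", "malformed GO id(s): ", paste(df$go_id[bad], collapse = ", "))
  bad <- !(df$domain %in% GO_DOMAINS)
  if (any(bad))
    fail("records", "unknown GO domain token(s): ",
         paste(unique(df$domain[bad]), collapse = ", "))
  df
}

#' Construct a protein annotation record
#'
#' One sequence-database record: the evidence inspected by the
#' annotation-sufficiency stage. Empty strings denote absent free-text
#' fields; `go` may have zero rows.
#'
#' @param accession Non-empty accession string.
#' @param protein_name Record name (free text, may be empty).
#' @param reviewed Logical; `TRUE` for the manually curated database section.
#' @param function_text,catalytic_activity Free-text annotation fields.
#' @param ec_numbers Character vector of EC numbers (`d.d.d.d`, trailing
#'   fields may be `"-"` wildcards); may be empty.
#' @param go A [go_terms()] data frame.
#' @param integration_date Date the record entered the database (ISO 8601
#'   string or `Date`).
#' @return A list of class `protein_annotation`.
#' @export
protein_annotation <- function(accession, protein_name = "", reviewed = FALSE,
                               function_text = "", catalytic_activity = "",
                               ec_numbers = character(0), go = go_terms(),
                               integration_date = NA) {
  accession <- as.character(accession)
  if (length(accession) != 1L || is.na(accession) || !nzchar(accession))
    fail("records", "accession must be a single non-empty string")
  ec_numbers <- as.character(ec_numbers[nzchar(ec_numbers)])
  bad <- !is_valid_ec(ec_numbers)
  if (any(bad))
    fail("records", "malformed EC number(s) for ", accession, ": ",
         paste(ec_numbers[bad], collapse = ", "))
  d <- parse_iso_date(integration_date)
  if (length(d) != 1L || is.na(d))
    fail("records", "integration_date for ", accession,
         " is not a valid ISO 8601 date: ", as.character(integration_date))
  structure(list(accession = accession,
                 protein_name = as.character(protein_name),
                 reviewed = isTRUE(reviewed),
                 function_text = as.character(function_text),
                 catalytic_activity = as.character(catalytic_activity),
                 ec_numbers = ec_numbers,
                 go_terms = go,
                 integration_date = d),
            class = "protein_annotation")
}

## validate a structure-entry data.frame (pdb_id, molecule_name,
## classification_header, deposition_date (Date), species, accessions (list))
validate_entries <- function(entries, stage = "corpus") {
  need <- c("pdb_id", "molecule_name", "classification_header",
            "deposition_date", "species", "accessions")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    fail(stage, "entries table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !is_valid_pdb_id(entries$pdb_id)
  if (any(bad))
    fail(stage, "malformed pdb_id(s): ",
         paste(entries$pdb_id[bad], collapse = ", "))
  dup <- entries$pdb_id[duplicated(entries$pdb_id)]
  if (length(dup))
    fail(stage, "duplicate pdb_id(s): ", paste(unique(dup), collapse = ", "))
  if (any(is.na(entries$deposition_date)))
    fail(stage, "missing or malformed deposition date(s) for: ",
         paste(entries$pdb_id[is.na(entries$deposition_date)], collapse = ", "))
  dupacc <- vapply(entries$accessions, function(a) anyDuplicated(a) > 0L,
                   logical(1))
  if (any(dupacc))
    fail(stage, "duplicate accessions within entry: ",
         paste(entries$pdb_id[dupacc], collapse = ", "))
  invisible(entries)
}
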