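## Fixture file formats (all UTF-8, tab-separated, LF, one header row):
##
##   structure_entries.tsv : pdb_id, molecule_name, classification_header,
##                           deposition_date, species, accessions
##                           (accessions ";"-joined, may be empty)
##   annotations.tsv       : accession, protein_name, reviewed, function_text,
##                           catalytic_activity, ec_numbers, go_terms,
##                           integration_date
##                           (ec_numbers ";"-joined; go_terms serialized as
##                            "GO:0016301|MOLECULAR_FUNCTION|kinase activity[|IEA];...")
##   sequence_hits.tsv     : the 12 standard BLAST tabular columns
##                           qseqid sseqid pident length mismatch gapopen
##                           qstart qend sstart send evalue bitscore
##   structure_hits.tsv    : query_id, subject_pdb_id, z_score, rmsd_angstrom,
##                           subject_classification, subject_name,
##                           subject_deposition_date

ENTRY_COLUMNS <- c("pdb_id", "molecule_name", "classification_header",
                   "deposition_date", "species", "accessions")

ANNOTATION_COLUMNS <- c("accession", "protein_name", "reviewed",
                        "function_text", "catalytic_activity", "ec_numbers",
                        "go_terms", "integration_date")

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                   "bitscore")

STRUCT_HIT_COLUMNS <- c("query_id", "subject_pdb_id", "z_score",
                        "rmsd_angstrom", "subject_classification",
                        "subject_name", "subject_deposition_date")

#' Read a structure-entry metadata table
#'
#' Reads the tab-separated entry metadata file (one header row; columns
#' `pdb_id`, `molecule_name`, `classification_header`, `deposition_date`,
#' `species`, `accessions` with accessions `";"`-joined). Rows are returned
#' in file order; malformed identifiers or dates are reported with their
#' line numbers, and duplicate `pdb_id`s are rejected.
#'
#' @param path Path to the file.
#' @return A data frame with the six columns above, `deposition_date` as
#'   `Date` and `accessions` as a list column of character vectors.
#' @export
read_structure_entries <- function(path) {
  df <- read_tsv(path, "entries")
  check_columns(df, ENTRY_COLUMNS, path, "entries")
  n <- nrow(df)
  lines <- seq_len(n) + 1L  # header is line 1
  problems <- character(0)
  bad_id <- !is_valid_pdb_id(df$pdb_id)
  if (any(bad_id))
    problems <- c(problems, sprintf("line %d: malformed pdb_id '%s'",
                                    lines[bad_id], df$pdb_id[bad_id]))
  dates <- parse_iso_date(df$deposition_date)
  bad_date <- is.na(dates)
  if (any(bad_date & !bad_id))
    problems <- c(problems,
                  sprintf("line %d: malformed deposition_date '%s'",
                          lines[bad_date & !bad_id],
                          df$deposition_date[bad_date & !bad_id]))
  if (length(problems))
    fail("entries", "invalid rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  dup <- duplicated(df$pdb_id)
  if (any(dup))
    fail("entries", "duplicate pdb_id(s) in ", path, ": ",
         paste(unique(df$pdb_id[dup]), collapse = ", "))
  acc <- strsplit(df$accessions, ";", fixed = TRUE)
  acc <- lapply(acc, function(a) a[nzchar(a)])
  out <- data.frame(pdb_id = df$pdb_id,
                    molecule_name = df$molecule_name,
                    classification_header = df$classification_header,
                    deposition_date = dates,
                    species = df$species,
                    stringsAsFactors = FALSE)
  out$accessions <- acc
  validate_entries(out, "entries")
  out
}

#' Write a structure-entry metadata table
#'
#' Inverse of [read_structure_entries()]; writing then reading reproduces the
#' input exactly.
#'
#' @param entries Entry data frame as returned by [read_structure_entries()].
#' @param path Output path.
#' @export
write_structure_entries <- function(entries, path) {
  validate_entries(entries)
  df <- data.frame(pdb_id = entries$pdb_id,
                   molecule_name = entries$molecule_name,
                   classification_header = entries$classification_header,
                   deposition_date = format(entries$deposition_date, "%Y-%m-%d"),
                   species = entries$species,
                   accessions = vapply(entries$accessions, paste,
                                       character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

serialize_go <- function(go) {
  if (is.null(go) || nrow(go) == 0L) return("")
  parts <- paste(go$go_id, go$domain, go$term_name, sep = "|")
  has_ev <- !is.na(go$evidence_code) & nzchar(go$evidence_code)
  parts[has_ev] <- paste(parts[has_ev], go$evidence_code[has_ev], sep = "|")
  paste(parts, collapse = ";")
}

parse_go_field <- function(txt, line) {
  if (!nzchar(txt)) return(go_terms())
  items <- strsplit(txt, ";", fixed = TRUE)[[1]]
  items <- items[nzchar(items)]
  parts <- strsplit(items, "|", fixed = TRUE)
  np <- lengths(parts)
  if (any(np < 3L | np > 4L))
    fail("annotations", "line ", line,
         ": GO sub-field needs 3 or 4 '|'-separated parts: ",
         items[which(np < 3L | np > 4L)[1]])
  go_id <- vapply(parts, `[[`, character(1), 1L)
  domain <- vapply(parts, `[[`, character(1), 2L)
  term <- vapply(parts, `[[`, character(1), 3L)
  ev <- vapply(parts, function(p) if (length(p) >= 4L) p[[4]] else NA_character_,
               character(1))
  bad <- !(domain %in% GO_DOMAINS)
  if (any(bad))
    fail("annotations", "line ", line, ": unknown GO domain token '",
         domain[bad][1], "'")
  bad <- !is_valid_go_id(go_id)
  if (any(bad))
    fail("annotations", "line ", line, ": malformed GO id '", go_id[bad][1], "'")
  go_terms(go_id, domain, term, ev)
}

#' Read a protein annotation table
#'
#' Reads the tab-separated annotation file into a mapping (named list) of
#' accession to [protein_annotation()] record. GO terms are serialized in a
#' `";"`-delimited sub-field, each item
#' `"GO:0016301|MOLECULAR_FUNCTION|kinase activity"` with an optional fourth
#' `|`-separated evidence code. Duplicate accessions and unknown GO domain
#' tokens are rejected.
#'
#' @param path Path to the file.
#' @return A named list of `protein_annotation` records keyed by accession.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, "annotations")
  check_columns(df, ANNOTATION_COLUMNS, path, "annotations")
  dup <- duplicated(df$accession)
  if (any(dup))
    fail("annotations", "duplicate accession(s) in ", path, ": ",
         paste(unique(df$accession[dup]), collapse = ", "))
  n <- nrow(df)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    line <- i + 1L
    ec <- strsplit(df$ec_numbers[i], ";", fixed = TRUE)[[1]]
    rec <- tryCatch(
      protein_annotation(accession = df$accession[i],
                         protein_name = df$protein_name[i],
                         reviewed = toupper(df$reviewed[i]) %in% c("TRUE", "1"),
                         function_text = df$function_text[i],
                         catalytic_activity = df$catalytic_activity[i],
                         ec_numbers = ec,
                         go = parse_go_field(df$go_terms[i], line),
                         integration_date = df$integration_date[i]),
      error = function(e) fail("annotations", "line ", line, ": ",
                               conditionMessage(e)))
    out[[i]] <- rec
  }
  names(out) <- df$accession
  out
}

#' Write a protein annotation table
#'
#' Inverse of [read_annotations()].
#'
#' @param annotations Named list of [protein_annotation()] records.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    accession = vapply(annotations, `[[`, character(1), "accession"),
    protein_name = vapply(annotations, `[[`, character(1), "protein_name"),
    reviewed = ifelse(vapply(annotations, `[[`, logical(1), "reviewed"),
                      "TRUE", "FALSE"),
    function_text = vapply(annotations, `[[`, character(1), "function_text"),
    catalytic_activity = vapply(annotations, `[[`, character(1),
                                "catalytic_activity"),
    ec_numbers = vapply(annotations, function(a) paste(a$ec_numbers,
                                                       collapse = ";"),
                        character(1)),
    go_terms = vapply(annotations, function(a) serialize_go(a$go_terms),
                      character(1)),
    integration_date = vapply(annotations,
                              function(a) format(a$integration_date, "%Y-%m-%d"),
                              character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  write_tsv(df, path)
}

## join subject metadata from the annotations mapping onto a flat BLAST
## table and group by (chain-stripped) query id; shared by the file reader
## and the synthetic generator
group_sequence_hits <- function(flat, annotations, strict = FALSE) {
  if (nrow(flat) == 0L) return(structure(list(), names = character(0)))
  flat$query_id <- strip_chain(flat$qseqid)
  known <- flat$sseqid %in% names(annotations)
  dropped <- flat[!known, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    if (strict)
      fail("sequence-hits", "subject accession(s) absent from annotations: ",
           paste(unique(dropped$sseqid), collapse = ", "))
    flat <- flat[known, , drop = FALSE]
  }
  recs <- annotations[flat$sseqid]
  hits <- data.frame(query_id = flat$query_id,
                     subject_accession = flat$sseqid,
                     percent_identity = flat$pident,
                     alignment_length = flat$length,
                     e_value = flat$evalue,
                     bit_score = flat$bitscore,
                     subject_name = vapply(recs, `[[`, character(1),
                                           "protein_name"),
                     subject_reviewed = vapply(recs, `[[`, logical(1),
                                               "reviewed"),
                     stringsAsFactors = FALSE)
  hits$subject_integration_date <-
    as.Date(vapply(recs, function(r) as.numeric(r$integration_date),
                   numeric(1)))
  hits$subject_go <- lapply(recs, `[[`, "go_terms")
  rownames(hits) <- NULL
  out <- split_by(hits, "query_id")
  attr(out, "dropped") <- dropped
  attr(out, "n_rows") <- nrow(hits)
  out
}

#' Read a sequence-similarity hit table
#'
#' Reads a 12-column BLAST tabular file (standard column order `qseqid`,
#' `sseqid`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#' `sstart`, `send`, `evalue`, `bitscore`, with one header row), joins
#' subject metadata (name, review status, GO terms, integration date) from
#' the annotations mapping, and groups the hits by query entry ID. Chain
#' suffixes on query IDs (`"1htw_A"`) are stripped to the 4-character entry
#' ID before grouping. Row order within each query follows the file.
#'
#' @param path Path to the hit table.
#' @param annotations Mapping from [read_annotations()] supplying subject
#'   metadata.
#' @param strict If `TRUE`, a subject accession missing from `annotations`
#'   is an error; by default such hits are excluded and recorded in the
#'   `"dropped"` attribute of the result.
#' @return A named list, query ID to data frame of enriched hits. Queries
#'   absent from the file are simply absent (treat as zero hits).
#' @export
read_sequence_hits <- function(path, annotations, strict = FALSE) {
  df <- read_tsv(path, "sequence-hits")
  check_columns(df, BLAST_COLUMNS, path, "sequence-hits")
  lines <- seq_len(nrow(df)) + 1L
  pid <- suppressWarnings(as.numeric(df$pident))
  bad <- is.na(pid) | pid < 0 | pid > 100
  if (any(bad))
    fail("sequence-hits", "invalid pident at line(s) ",
         paste(lines[bad], collapse = ", "))
  ev <- suppressWarnings(as.numeric(df$evalue))
  bad <- is.na(ev) | ev < 0
  if (any(bad))
    fail("sequence-hits", "invalid evalue at line(s) ",
         paste(lines[bad], collapse = ", "))
  len <- suppressWarnings(as.integer(df$length))
  bad <- is.na(len) | len <= 0L
  if (any(bad))
    fail("sequence-hits", "invalid alignment length at line(s) ",
         paste(lines[bad], collapse = ", "))
  flat <- data.frame(qseqid = df$qseqid, sseqid = df$sseqid, pident = pid,
                     length = len, evalue = ev,
                     bitscore = suppressWarnings(as.numeric(df$bitscore)),
                     stringsAsFactors = FALSE)
  group_sequence_hits(flat, annotations, strict = strict)
}

#' Write a sequence-similarity hit table
#'
#' Writes a flat 12-column BLAST tabular file (with header). The input is a
#' data frame holding at least `qseqid`, `sseqid`, `pident`, `length`,
#' `evalue`, `bitscore`; the remaining standard columns are filled with
#' consistent placeholder coordinates when absent.
#'
#' @param flat Data frame of hit rows.
#' @param path Output path.
#' @export
write_sequence_hits <- function(flat, path) {
  n <- nrow(flat)
  filler <- function(col, default) {
    if (col %in% names(flat)) flat[[col]] else rep_len(default, n)
  }
  df <- data.frame(qseqid = flat$qseqid,
                   sseqid = flat$sseqid,
                   pident = format(flat$pident, trim = TRUE, nsmall = 1),
                   length = flat$length,
                   mismatch = filler("mismatch", 0L),
                   gapopen = filler("gapopen", 0L),
                   qstart = filler("qstart", 1L),
                   qend = filler("qend", if (n) flat$length else integer(0)),
                   sstart = filler("sstart", 1L),
                   send = filler("send", if (n) flat$length else integer(0)),
                   evalue = format(flat$evalue, trim = TRUE, scientific = TRUE),
                   bitscore = format(flat$bitscore, trim = TRUE, nsmall = 1),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a structural-alignment hit table
#'
#' Reads the tab-separated structural hit file (columns `query_id`,
#' `subject_pdb_id`, `z_score`, `rmsd_angstrom`, `subject_classification`,
#' `subject_name`, `subject_deposition_date`) and groups rows by query.
#' Z-scores may carry any sign; negative RMSD values are rejected.
#'
#' @param path Path to the file.
#' @return A named list, query ID to data frame of hits (with
#'   `subject_deposition_date` parsed as `Date`).
#' @export
read_structure_hits <- function(path) {
  df <- read_tsv(path, "structure-hits")
  check_columns(df, STRUCT_HIT_COLUMNS, path, "structure-hits")
  lines <- seq_len(nrow(df)) + 1L
  z <- suppressWarnings(as.numeric(df$z_score))
  if (any(is.na(z)))
    fail("structure-hits", "invalid z_score at line(s) ",
         paste(lines[is.na(z)], collapse = ", "))
  rmsd <- suppressWarnings(as.numeric(df$rmsd_angstrom))
  bad <- is.na(rmsd) | rmsd < 0
  if (any(bad))
    fail("structure-hits", "invalid (negative?) rmsd at line(s) ",
         paste(lines[bad], collapse = ", "))
  bad <- !is_valid_pdb_id(df$subject_pdb_id)
  if (any(bad))
    fail("structure-hits", "malformed subject_pdb_id at line(s) ",
         paste(lines[bad], collapse = ", "))
  dates <- parse_iso_date(df$subject_deposition_date)
  if (any(is.na(dates)))
    fail("structure-hits", "malformed subject_deposition_date at line(s) ",
         paste(lines[is.na(dates)], collapse = ", "))
  out <- data.frame(query_id = strip_chain(df$query_id),
                    subject_pdb_id = df$subject_pdb_id,
                    z_score = z,
                    rmsd_angstrom = rmsd,
                    subject_classification = df$subject_classification,
                    subject_name = df$subject_name,
                    stringsAsFactors = FALSE)
  out$subject_deposition_date <- dates
  split_by(out, "query_id")
}

#' Write a structural-alignment hit table
#'
#' Inverse of [read_structure_hits()], taking the flat (ungrouped) hit data
#' frame.
#'
#' @param flat Data frame with the seven structural hit columns.
#' @param path Output path.
#' @export
write_structure_hits <- function(flat, path) {
  df <- data.frame(query_id = flat$query_id,
                   subject_pdb_id = flat$subject_pdb_id,
                   z_score = format(flat$z_score, trim = TRUE, nsmall = 1),
                   rmsd_angstrom = format(flat$rmsd_angstrom, trim = TRUE,
                                          nsmall = 2),
                   subject_classification = flat$subject_classification,
                   subject_name = flat$subject_name,
                   subject_deposition_date = format(flat$subject_deposition_date,
                                                    "%Y-%m-%d"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
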