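# shared fixture builders: tiny corpora constructed in code

`%||%` <- function(a, b) if (is.null(a)) b else a

mk_entries <- function(ids, dates = "2005-06-15", accessions = NULL,
                       classification = "unknown function",
                       molecule = "Hypothetical protein") {
  n <- length(ids)
  df <- data.frame(pdb_id = ids,
                   molecule_name = rep_len(molecule, n),
                   classification_header = rep_len(classification, n),
                   deposition_date = rep_len(as.Date(dates), n),
                   species = rep_len("Escherichia coli", n),
                   stringsAsFactors = FALSE)
  df$accessions <- accessions %||% lapply(seq_len(n), function(i)
    sprintf("P%04d", i))
  df
}

mk_annotation <- function(accession, name = "Thymidine kinase", go = go_terms(),
                          function_text = "", catalytic = "", ec = character(0),
                          reviewed = TRUE, date = "2003-01-01") {
  protein_annotation(accession, protein_name = name, reviewed = reviewed,
                     function_text = function_text,
                     catalytic_activity = catalytic, ec_numbers = ec,
                     go = go, integration_date = date)
}

go_mixed3 <- function() {
  go_terms(c("GO:0006096", "GO:0016301", "GO:0005737"),
           c("BIOLOGICAL_PROCESS", "MOLECULAR_FUNCTION", "CELLULAR_COMPONENT"),
           c("glycolytic process", "kinase activity", "cytoplasm"))
}

go_bp <- function(name = "glycolytic process") {
  go_terms("GO:0006096", "BIOLOGICAL_PROCESS", name)
}

mk_seq_hit <- function(query_id, subject_name = "Thymidine kinase",
                       pident = 45, go = go_bp(), date = "2006-01-01",
                       accession = "B0001") {
  df <- data.frame(query_id = query_id, subject_accession = accession,
                   percent_identity = pident, alignment_length = 100L,
                   e_value = 1e-30, bit_score = 200,
                   subject_name = subject_name, subject_reviewed = TRUE,
                   stringsAsFactors = FALSE)
  df$subject_integration_date <- as.Date(date)
  df$subject_go <- list(go)
  df
}

mk_struct_hit <- function(query_id, subject = "9abc", z = 25,
                          classification = "isomerase",
                          name = "Triosephosphate isomerase",
                          date = "2006-01-01", rmsd = 2.1) {
  df <- data.frame(query_id = query_id, subject_pdb_id = subject,
                   z_score = z, rmsd_angstrom = rmsd,
                   subject_classification = classification,
                   subject_name = name, stringsAsFactors = FALSE)
  df$subject_deposition_date <- as.Date(date)
  df
}

# random but internally consistent corpus specification
random_corpus_spec <- function(seed, n_max = 500L, n_min = 20L) {
  with_seed_local(seed, {
    n <- sample(n_min:n_max, 1L)
    st <- as.integer(stats::rmultinom(1, n, c(0.3, 0.2, 0.4, 0.1)))
    fwd <- n - st[1]
    sq <- if (fwd > 0)
      as.integer(stats::rmultinom(1, fwd, c(0.18, 0.05, 0.2, 0.38, 0.19)))
    else integer(5)
    ts <- fwd - sq[1] - sq[2]
    sc <- if (ts > 0)
      as.integer(stats::rmultinom(1, ts, c(0.17, 0.29, 0.27, 0.27)))
    else integer(4)
    corpus_spec(n_entries = n, statuses = st, seq_classes = sq,
                struct_classes = sc, seed = seed + 1L)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

run_generated <- function(corpus, control = triage_control()) {
  triage_corpus(corpus$entries, corpus$annotations, corpus$sequence_hits,
                corpus$structure_hits, control)
}
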