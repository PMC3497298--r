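# Independent straight-line re-implementation of every triage rule, used as
# the test oracle on small corpora. Deliberately written with different
# mechanics than the package (regex word boundaries instead of token sets,
# flat loops, no shared helpers) so that agreement is informative.

oracle_bad_name <- function(x) {
  x <- tolower(as.character(x))
  if (is.na(x) || !nzchar(trimws(x))) return(TRUE)
  grepl("\\b(uncharacterized|putative|unknown|predicted|unnamed|probable|hypothetical)\\b",
        x)
}

oracle_all_binding <- function(term_names) {
  all(grepl("\\bbinding\\s*$", tolower(term_names)))
}

oracle_record_sufficient <- function(rec) {
  # returns one of the three mapped statuses
  if (oracle_bad_name(rec$protein_name)) return("UNCHARACTERIZED_EQUIVALENT")
  go <- rec$go_terms
  go_ok <- nrow(go) >= 3 &&
    !all(go$domain == "CELLULAR_COMPONENT") &&
    !oracle_all_binding(go$term_name)
  has_text <- nzchar(trimws(rec$function_text)) ||
    nzchar(trimws(rec$catalytic_activity)) || length(rec$ec_numbers) > 0
  if (has_text || go_ok) "SUFFICIENT" else "INSUFFICIENT"
}

oracle_seq_class <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return("NO_HITS")
  n_sig <- n_disc <- n_sub <- 0
  for (i in seq_len(nrow(hits))) {
    if (oracle_bad_name(hits$subject_name[i])) {
      n_disc <- n_disc + 1
      next
    }
    pid <- hits$percent_identity[i]
    go <- hits$subject_go[[i]]
    sup <- FALSE
    if (nrow(go) > 0) {
      if (pid > 40 && any(go$domain == "BIOLOGICAL_PROCESS")) sup <- TRUE
      if (pid > 60 && any(go$domain == "CELLULAR_COMPONENT")) sup <- TRUE
      mf <- go$domain == "MOLECULAR_FUNCTION"
      if (pid > 50 && any(mf) && !oracle_all_binding(go$term_name[mf]))
        sup <- TRUE
    }
    if (sup) n_sig <- n_sig + 1 else n_sub <- n_sub + 1
  }
  if (n_sig > 0 && n_disc == 0) return("SIGNIFICANT_ALL_CHARACTERIZED")
  if (n_sig > 0) return("SIGNIFICANT_MIXED")
  if (n_disc > 0 && n_sub == 0) return("DISCARDED_ONLY")
  "SUB_THRESHOLD"
}

oracle_struct_class <- function(hits, dataset_ids) {
  if (is.null(hits) || nrow(hits) == 0) return("NO_HITS")
  best <- -Inf
  best_subject <- NULL
  for (i in seq_len(nrow(hits))) {
    if (hits$subject_pdb_id[i] %in% dataset_ids) next
    cls <- tolower(trimws(hits$subject_classification[i]))
    if (cls == "unknown function") next
    if (oracle_bad_name(cls)) next
    if (oracle_bad_name(hits$subject_name[i])) next
    z <- hits$z_score[i]
    if (z > best || (z == best && hits$subject_pdb_id[i] < best_subject)) {
      best <- z
      best_subject <- hits$subject_pdb_id[i]
    }
  }
  if (is.null(best_subject)) return("NO_HITS")
  if (best > 20) "DEFINITE" else if (best < 8) "UNRELATED" else "PROBABLE"
}

# full per-entry labelling, mirroring the four stages independently
oracle_labels <- function(entries, annotations, seq_hits, struct_hits) {
  n <- nrow(entries)
  status <- seq_cl <- struct_cl <- final <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    acc <- entries$accessions[[i]]
    acc <- acc[acc %in% names(annotations)]
    if (length(acc) == 0) {
      status[i] <- "NO_MAPPING"
    } else {
      st <- vapply(acc, function(a)
        oracle_record_sufficient(annotations[[a]]), character(1))
      status[i] <- if ("SUFFICIENT" %in% st) "SUFFICIENT" else st[[1]]
    }
    if (status[i] == "SUFFICIENT") {
      final[i] <- "CHARACTERIZED_IN_SEQUENCE_DB"
      next
    }
    seq_cl[i] <- oracle_seq_class(seq_hits[[entries$pdb_id[i]]])
    if (seq_cl[i] %in% c("SIGNIFICANT_ALL_CHARACTERIZED", "SIGNIFICANT_MIXED")) {
      final[i] <- "REANNOTATION_CANDIDATE"
      next
    }
    struct_cl[i] <- oracle_struct_class(struct_hits[[entries$pdb_id[i]]],
                                        entries$pdb_id)
    final[i] <- if (struct_cl[i] == "DEFINITE") "REANNOTATION_CANDIDATE"
                else "TRUE_UNKNOWN"
  }
  data.frame(pdb_id = entries$pdb_id, annotation_status = status,
             sequence_class = seq_cl, structure_class = struct_cl,
             final_label = final, stringsAsFactors = FALSE)
}
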