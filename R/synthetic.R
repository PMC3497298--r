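## Seeded synthetic corpus generator. Every entry is constructed so that the
## pipeline classifies it into a pre-assigned stage class; the per-class
## counts of a generated corpus therefore equal the spec's counts exactly,
## which is the module's core guarantee (and the pipeline's strongest
## end-to-end test). Boundary records -- identities exactly at the 40/50/60
## cutoffs, Z-scores exactly 8 and 20 -- are deliberately injected into the
## non-significant pools to police the strict inequalities.

FIXTURE_FILES <- c(entries = "structure_entries.tsv",
                   annotations = "annotations.tsv",
                   seq_hits = "sequence_hits.tsv",
                   struct_hits = "structure_hits.tsv")

## name vocabularies: informative names echo the enzyme families that turn
## up around re-annotated unknown-function entries; uninformative names are
## built from the blacklist plus locus-tag-style suffixes
INFORMATIVE_NAMES <- c("Thymidine kinase", "NAD(P)H-hydrate epimerase",
                       "Carboxy-cis,cis-muconate cyclase",
                       "Glucosyl-3-phosphoglycerate synthase",
                       "Phosphoglycolate phosphatase",
                       "6-phosphogluconolactonase",
                       "Aspartate aminotransferase",
                       "Triosephosphate isomerase",
                       "Glutamate--cysteine ligase",
                       "Walker type ATP-ase")

UNINFORMATIVE_STEMS <- c("Uncharacterized protein",
                         "Putative uncharacterized protein",
                         "Hypothetical protein", "Unknown protein",
                         "Predicted protein", "Probable exported protein",
                         "Unnamed protein product")

FUNCTION_CLASSES <- c("isomerase", "lyase", "transferase", "ligase",
                      "hydrolase", "oxidoreductase", "synthase")

SPECIES_POOL <- c("Thermus thermophilus", "Bacillus subtilis",
                  "Escherichia coli", "Haemophilus influenzae",
                  "Pseudomonas aeruginosa", "Methanocaldococcus jannaschii")

GO_BP <- c("glycolytic process" = "GO:0006096",
           "DNA repair" = "GO:0006281",
           "protein phosphorylation" = "GO:0006468",
           "carbohydrate metabolic process" = "GO:0005975")
GO_MF <- c("kinase activity" = "GO:0016301",
           "isomerase activity" = "GO:0016853",
           "hydrolase activity" = "GO:0016787",
           "ligase activity" = "GO:0016874")
GO_MF_BINDING <- c("ATP binding" = "GO:0005524",
                   "DNA binding" = "GO:0003677",
                   "zinc ion binding" = "GO:0008270",
                   "metal ion binding" = "GO:0046872")
GO_CC <- c("cytoplasm" = "GO:0005737",
           "nucleus" = "GO:0005634",
           "plasma membrane" = "GO:0005886")

base36 <- function(i, width = 3) {
  digits <- c(0:9, letters)
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k]; s <- character(0)
    repeat {
      s <- c(digits[v %% 36L + 1L], s)
      v <- v %/% 36L
      if (v == 0L) break
    }
    out[k] <- paste(c(rep("0", max(0L, width - length(s))), s), collapse = "")
  }
  out
}

## corpus entry IDs: leading digit 1-8 plus a base-36 suffix; structural
## subject IDs use the reserved leading digit 9, so the two pools never clash
make_entry_ids <- function(n, offset = 0L) {
  paste0(1L + (seq_len(n) - 1L) %% 8L, base36(seq_len(n) + offset))
}

#' Specify a synthetic triage corpus
#'
#' Fixes the per-stage class structure of a corpus to generate: how many
#' entries fall into each annotation status, how the forwarded entries split
#' across the five sequence-evidence classes, and how the
#' sequence-non-significant entries split across the four structural
#' classes. [generate_corpus()] guarantees that running the pipeline on the
#' generated corpus reproduces these counts exactly.
#'
#' @param n_entries Corpus size.
#' @param statuses Integer vector of length 4: counts for `SUFFICIENT`,
#'   `INSUFFICIENT`, `UNCHARACTERIZED_EQUIVALENT`, `NO_MAPPING`; must sum to
#'   `n_entries`.
#' @param seq_classes Integer vector of length 5: counts for
#'   `SIGNIFICANT_ALL_CHARACTERIZED`, `SIGNIFICANT_MIXED`, `DISCARDED_ONLY`,
#'   `NO_HITS`, `SUB_THRESHOLD`; must sum to `n_entries - SUFFICIENT`.
#' @param struct_classes Integer vector of length 4: counts for `DEFINITE`,
#'   `PROBABLE`, `UNRELATED`, `NO_HITS`; must sum to the sequence-stage
#'   total minus the significant count.
#' @param date_window Two `Date`s (or ISO strings): the deposition-date
#'   range of the corpus.
#' @param fraction_postdating Length-2 numeric (percent): target fraction of
#'   sequence-significant (resp. structure-definite) queries whose evidence
#'   postdates the query; enforced by construction, rounded to whole
#'   queries.
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the seed.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_entries, statuses, seq_classes, struct_classes,
                        date_window = c("1999-12-13", "2012-05-16"),
                        fraction_postdating = c(blast = 43.65, dali = 69.10),
                        seed = 1L) {
  n_entries <- as.integer(n_entries)
  statuses <- as.integer(statuses)
  seq_classes <- as.integer(seq_classes)
  struct_classes <- as.integer(struct_classes)
  if (n_entries < 1L) fail("synthetic", "n_entries must be positive")
  if (length(statuses) != 4L || any(statuses < 0L) ||
      sum(statuses) != n_entries)
    fail("synthetic", "statuses must be 4 non-negative counts summing to ",
         n_entries)
  forwarded <- n_entries - statuses[1]
  if (length(seq_classes) != 5L || any(seq_classes < 0L) ||
      sum(seq_classes) != forwarded)
    fail("synthetic", "seq_classes must be 5 non-negative counts summing to ",
         forwarded)
  to_struct <- forwarded - seq_classes[1] - seq_classes[2]
  if (length(struct_classes) != 4L || any(struct_classes < 0L) ||
      sum(struct_classes) != to_struct)
    fail("synthetic", "struct_classes must be 4 non-negative counts ",
         "summing to ", to_struct)
  window <- parse_iso_date(date_window)
  if (length(window) != 2L || any(is.na(window)) || window[1] >= window[2])
    fail("synthetic", "date_window must be two ordered ISO dates")
  fraction_postdating <- as.numeric(fraction_postdating)
  if (length(fraction_postdating) != 2L ||
      any(fraction_postdating < 0 | fraction_postdating > 100))
    fail("synthetic", "fraction_postdating must be two percentages")
  structure(list(n_entries = n_entries,
                 statuses = stats::setNames(statuses, ANNOTATION_STATUSES),
                 seq_classes = stats::setNames(seq_classes,
                                               c("SIGNIFICANT_ALL_CHARACTERIZED",
                                                 "SIGNIFICANT_MIXED",
                                                 "DISCARDED_ONLY", "NO_HITS",
                                                 "SUB_THRESHOLD")),
                 struct_classes = stats::setNames(struct_classes,
                                                  STRUCTURE_CLASSES),
                 date_window = window,
                 fraction_postdating = stats::setNames(fraction_postdating,
                                                        c("blast", "dali")),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' The printed-funnel corpus specification
#'
#' The fixed [corpus_spec()] reproducing the reference funnel: 2549 entries
#' partitioned 868 / 520 / 1097 / 64 by annotation status; the 1681
#' forwarded queries split 299 / 79 / 335 / 647 / 321 across the sequence
#' classes; the 1303 structure-stage queries split 219 / 381 / 703 across
#' definite, probable, and unrelated-or-no-hits (the 703 residual is divided
#' 352 / 351 between the last two classes, which the funnel only ever
#' reports combined). Construction re-checks every sum.
#'
#' @param seed RNG seed for the generator (default 20120516); the class
#'   counts are invariant across seeds.
#' @return A `corpus_spec`.
#' @export
#' @examples
#' spec <- printed_funnel_spec()
#' sum(spec$statuses)  # 2549
printed_funnel_spec <- function(seed = 20120516L) {
  corpus_spec(n_entries = 2549L,
              statuses = c(868L, 520L, 1097L, 64L),
              seq_classes = c(299L, 79L, 335L, 647L, 321L),
              struct_classes = c(219L, 381L, 352L, 351L),
              seed = seed)
}

## internal mutable accumulator for generated rows / records
new_bag <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- list()
  e$n <- 0L
  e
}
bag_add <- function(bag, x) {
  bag$n <- bag$n + 1L
  bag$items[[bag$n]] <- x
  invisible(bag)
}

#' Generate a synthetic fixture corpus
#'
#' Builds the four fixture inputs (entry metadata, annotation records,
#' sequence hits, structural hits) so that the pipeline's per-class counts
#' equal the spec's exactly. Sufficient entries get informative records via
#' rotating evidence routes (GO profile, function text, EC number, catalytic
#' activity); insufficient entries rotate through the failure modes
#' (too few terms, all-cellular-component, all "*-binding"); significant
#' sequence hits draw identities strictly above the relevant cutoff and
#' sub-threshold hits strictly below, with exact-boundary identities (40 /
#' 50 / 60) and Z-scores (8 / 20) injected into the non-significant pools.
#' Deposition dates are drawn uniformly in the spec's window and the
#' postdating fractions are enforced by construction. Fully deterministic
#' given the spec's seed; different seeds change names and dates but never
#' class counts.
#'
#' @param spec A [corpus_spec()].
#' @param dir Directory to write the four fixture files into (created if
#'   missing), or `NULL` to generate in memory only.
#' @return Invisibly (visibly when `dir` is `NULL`), a list with `entries`,
#'   `annotations`, `sequence_hits`, `structure_hits` (ready for
#'   [triage_corpus()]), the flat `seq_flat` / `struct_flat` tables, the
#'   per-entry `assignment` table of intended classes, and `paths` when
#'   files were written.
#' @export
generate_corpus <- function(spec, dir = NULL) {
  if (!inherits(spec, "corpus_spec"))
    fail("synthetic", "spec must be a corpus_spec")
  corpus <- with_seed(spec$seed, build_corpus(spec))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, FIXTURE_FILES)
    names(paths) <- names(FIXTURE_FILES)
    write_structure_entries(corpus$entries, paths[["entries"]])
    write_annotations(corpus$annotations, paths[["annotations"]])
    write_sequence_hits(corpus$seq_flat, paths[["seq_hits"]])
    write_structure_hits(corpus$struct_flat, paths[["struct_hits"]])
    corpus$paths <- paths
    return(invisible(corpus))
  }
  corpus
}

build_corpus <- function(spec) {
  n <- spec$n_entries
  ids <- make_entry_ids(n)
  window_days <- as.integer(spec$date_window[2] - spec$date_window[1])
  qdate <- spec$date_window[1] + sample.int(window_days + 1L, n,
                                            replace = TRUE) - 1L
  status <- sample(rep(ANNOTATION_STATUSES, times = spec$statuses))

  ## --- entry-side metadata (classification header / molecule name) -----
  classification <- rep("unknown function", n)
  molecule <- paste(sample(UNINFORMATIVE_STEMS, n, replace = TRUE),
                    toupper(base36(seq_len(n) + 500L)))
  idx13 <- which(seq_len(n) %% 13L == 0L)   # class names a function
  classification[idx13] <- sample(FUNCTION_CLASSES, length(idx13),
                                  replace = TRUE)
  idx17 <- which(seq_len(n) %% 17L == 0L & seq_len(n) %% 13L != 0L)
  molecule[idx17] <- sample(INFORMATIVE_NAMES, length(idx17), replace = TRUE)
  species <- sample(SPECIES_POOL, n, replace = TRUE)

  annotations <- new_bag()
  rand_date <- function(k = 1L) {
    spec$date_window[1] + sample.int(window_days + 1L, k, replace = TRUE) - 1L
  }

  ## --- stage-1 records for mapped entries ------------------------------
  accessions <- vector("list", n)
  for (i in seq_len(n)) {
    if (status[i] == "NO_MAPPING") {
      # mostly no accession at all; sometimes an unresolvable one
      accessions[[i]] <- if (i %% 3L == 0L) paste0("X", base36(i, 5)) else
        character(0)
      next
    }
    acc <- sprintf("P%05d", i)
    accessions[[i]] <- acc
    rec <- switch(status[i],
      SUFFICIENT = make_sufficient_record(acc, i),
      INSUFFICIENT = make_insufficient_record(acc, i),
      UNCHARACTERIZED_EQUIVALENT = make_equivalent_record(acc, i))
    rec$integration_date <- rand_date()
    bag_add(annotations, rec)
  }

  entries <- data.frame(pdb_id = ids, molecule_name = molecule,
                        classification_header = classification,
                        deposition_date = qdate, species = species,
                        stringsAsFactors = FALSE)
  entries$accessions <- accessions

  ## --- stage-2 assignments and hits ------------------------------------
  forwarded <- which(status != "SUFFICIENT")
  seq_class <- rep(NA_character_, n)
  seq_class[forwarded] <- sample(rep(names(spec$seq_classes),
                                     times = spec$seq_classes))
  significant <- which(!is.na(seq_class) &
                         seq_class %in% c("SIGNIFICANT_ALL_CHARACTERIZED",
                                          "SIGNIFICANT_MIXED"))
  k_blast <- round(spec$fraction_postdating[["blast"]] / 100 *
                     length(significant))
  postdate_blast <- stats::setNames(rep(FALSE, length(significant)),
                                    ids[significant])
  if (k_blast > 0) postdate_blast[seq_len(k_blast)] <- TRUE

  subj_counter <- new.env(parent = emptyenv()); subj_counter$i <- 0L
  next_subject_acc <- function() {
    subj_counter$i <- subj_counter$i + 1L
    sprintf("B%05d", subj_counter$i)
  }
  seq_rows <- new_bag()
  cutoffs <- identity_cutoffs()

  add_seq_hit <- function(query_id, with_chain, subject_rec, pident) {
    bag_add(seq_rows, list(qseqid = if (with_chain) paste0(query_id, "_A")
                           else query_id,
                           sseqid = subject_rec$accession, pident = pident))
    bag_add(annotations, subject_rec)
  }

  characterized_subject <- function(go, date) {
    rec <- protein_annotation(next_subject_acc(),
                              protein_name = sample(INFORMATIVE_NAMES, 1),
                              reviewed = TRUE, go = go,
                              integration_date = date)
    rec
  }
  discarded_subject <- function(date) {
    protein_annotation(next_subject_acc(),
                       protein_name = paste(sample(UNINFORMATIVE_STEMS, 1),
                                            toupper(base36(subj_counter$i))),
                       reviewed = FALSE,
                       go = pick_go("BIOLOGICAL_PROCESS"),
                       integration_date = date)
  }

  for (j in seq_along(forwarded)) {
    i <- forwarded[j]
    cl <- seq_class[i]
    if (cl == "NO_HITS") next
    qid <- ids[i]
    with_chain <- j %% 10L == 0L
    if (cl %in% c("SIGNIFICANT_ALL_CHARACTERIZED", "SIGNIFICANT_MIXED")) {
      d <- GO_DOMAINS[(j %% 3L) + 1L]
      pident <- round(stats::runif(1, cutoffs[[d]] + 1, 95), 1)
      postdates <- postdate_blast[[qid]]
      offset <- sample(30:3650, 1)
      hdate <- if (postdates) qdate[i] + offset else qdate[i] - offset
      add_seq_hit(qid, with_chain,
                  characterized_subject(pick_go(d), hdate), pident)
      if (j %% 2L == 0L) {
        # extra characterized hit below every cutoff: stays out of S, and
        # being sub-threshold it must not drag the class down either
        extra_date <- if (postdates) qdate[i] + offset + 200L else
          qdate[i] - offset - 200L
        add_seq_hit(qid, with_chain,
                    characterized_subject(pick_go("BIOLOGICAL_PROCESS"),
                                          extra_date),
                    round(stats::runif(1, 10, 35), 1))
      }
      if (cl == "SIGNIFICANT_MIXED") {
        add_seq_hit(qid, with_chain, discarded_subject(rand_date()),
                    round(stats::runif(1, 30, 90), 1))
      }
    } else if (cl == "DISCARDED_ONLY") {
      for (r in seq_len(1L + j %% 2L)) {
        add_seq_hit(qid, with_chain, discarded_subject(rand_date()),
                    round(stats::runif(1, 20, 90), 1))
      }
    } else if (cl == "SUB_THRESHOLD") {
      pattern <- j %% 5L
      if (pattern == 0L) {
        add_seq_hit(qid, with_chain,
                    characterized_subject(pick_go("BIOLOGICAL_PROCESS"),
                                          rand_date()),
                    round(stats::runif(1, 10, 39), 1))
      } else if (pattern == 1L) {
        # exact-boundary identity: strictly-greater rule keeps it out
        d <- GO_DOMAINS[(j %% 3L) + 1L]
        add_seq_hit(qid, with_chain,
                    characterized_subject(pick_go(d), rand_date()),
                    unname(cutoffs[[d]]))
      } else if (pattern == 2L) {
        if (j %% 2L == 0L) {
          # all of the subject's MF terms end in "binding": excluded even
          # though the identity clears the MF cutoff
          go <- go_terms(unname(GO_MF_BINDING[1:2]),
                         "MOLECULAR_FUNCTION", names(GO_MF_BINDING)[1:2])
          add_seq_hit(qid, with_chain, characterized_subject(go, rand_date()),
                      55.0)
        } else {
          # subject with no GO terms at all: nothing to support
          add_seq_hit(qid, with_chain,
                      characterized_subject(go_terms(), rand_date()), 80.0)
        }
      } else if (pattern == 3L) {
        add_seq_hit(qid, with_chain,
                    characterized_subject(pick_go("CELLULAR_COMPONENT"),
                                          rand_date()),
                    round(stats::runif(1, 10, 59), 1))
      } else {
        add_seq_hit(qid, with_chain,
                    characterized_subject(pick_go("BIOLOGICAL_PROCESS"),
                                          rand_date()), 35.0)
        add_seq_hit(qid, with_chain, discarded_subject(rand_date()),
                    round(stats::runif(1, 20, 90), 1))
      }
    }
  }

  ## --- stage-3 assignments and hits ------------------------------------
  to_struct <- forwarded[!(forwarded %in% significant)]
  struct_class <- rep(NA_character_, n)
  struct_class[to_struct] <- sample(rep(names(spec$struct_classes),
                                        times = spec$struct_classes))
  definite <- which(!is.na(struct_class) & struct_class == "DEFINITE")
  k_dali <- round(spec$fraction_postdating[["dali"]] / 100 * length(definite))
  postdate_dali <- stats::setNames(rep(FALSE, length(definite)),
                                   ids[definite])
  if (k_dali > 0) postdate_dali[seq_len(k_dali)] <- TRUE

  struct_counter <- new.env(parent = emptyenv()); struct_counter$i <- 0L
  next_struct_id <- function() {
    struct_counter$i <- struct_counter$i + 1L
    paste0("9", base36(struct_counter$i))
  }
  struct_rows <- new_bag()
  add_struct_hit <- function(query_id, subject_id, z, classification, name,
                             date) {
    bag_add(struct_rows, list(query_id = query_id, subject_pdb_id = subject_id,
                              z_score = z,
                              rmsd_angstrom = round(stats::runif(1, 0.5, 4), 2),
                              subject_classification = classification,
                              subject_name = name, subject_deposition_date = date))
  }
  admissible_hit <- function(query_id, z, date) {
    add_struct_hit(query_id, next_struct_id(), z,
                   sample(FUNCTION_CLASSES, 1), sample(INFORMATIVE_NAMES, 1),
                   date)
  }
  unknown_decoy <- function(query_id, z) {
    add_struct_hit(query_id, next_struct_id(), z, "unknown function",
                   paste("Hypothetical protein",
                         toupper(base36(struct_counter$i))), rand_date())
  }
  indataset_decoy <- function(query_id, z, i) {
    add_struct_hit(query_id, ids[(i * 7L) %% n + 1L], z,
                   sample(FUNCTION_CLASSES, 1), sample(INFORMATIVE_NAMES, 1),
                   rand_date())
  }

  for (j in seq_along(to_struct)) {
    i <- to_struct[j]
    cl <- struct_class[i]
    qid <- ids[i]
    if (cl == "DEFINITE") {
      z <- round(stats::runif(1, 20.5, 60), 1)
      offset <- sample(30:3650, 1)
      hdate <- if (postdate_dali[[qid]]) qdate[i] + offset else
        qdate[i] - offset
      admissible_hit(qid, z, hdate)
      if (j %% 2L == 0L) admissible_hit(qid, round(stats::runif(1, 9, 19), 1),
                                        rand_date())
      # inadmissible decoys above the best admissible Z must not matter
      if (j %% 6L == 0L) unknown_decoy(qid, z + 5)
      if (j %% 6L == 3L) indataset_decoy(qid, z + 3, i)
    } else if (cl == "PROBABLE") {
      z <- if (j %% 7L == 0L) 20.0 else if (j %% 7L == 3L) 8.0 else
        round(stats::runif(1, 8.1, 19.9), 1)
      admissible_hit(qid, z, rand_date())
      if (j %% 9L == 0L) admissible_hit(qid, z, rand_date())  # Z tie
      if (j %% 6L == 0L) unknown_decoy(qid, 30)
    } else if (cl == "UNRELATED") {
      z <- if (j %% 5L == 0L) 7.9 else round(stats::runif(1, 0.5, 7.8), 1)
      admissible_hit(qid, z, rand_date())
    } else if (cl == "NO_HITS") {
      if (j %% 3L == 2L) {
        # only inadmissible hits, some with very high Z
        unknown_decoy(qid, round(stats::runif(1, 10, 45), 1))
        if (j %% 2L == 0L) indataset_decoy(qid,
                                           round(stats::runif(1, 10, 45), 1), i)
      }
    }
  }

  ## --- assemble ---------------------------------------------------------
  ann_list <- annotations$items[seq_len(annotations$n)]
  names(ann_list) <- vapply(ann_list, `[[`, character(1), "accession")

  sq <- seq_rows$items[seq_len(seq_rows$n)]
  seq_flat <- data.frame(
    qseqid = vapply(sq, `[[`, character(1), "qseqid"),
    sseqid = vapply(sq, `[[`, character(1), "sseqid"),
    pident = vapply(sq, `[[`, numeric(1), "pident"),
    stringsAsFactors = FALSE)
  if (nrow(seq_flat) > 0L) {
    seq_flat$length <- 80L + (seq_len(nrow(seq_flat)) %% 200L)
    seq_flat$evalue <- signif(10^(-stats::runif(nrow(seq_flat), 5, 80)), 3)
    # descending bit score within each query, matching real tabular output
    ord_rank <- stats::ave(seq_len(nrow(seq_flat)), seq_flat$qseqid,
                           FUN = seq_along)
    seq_flat$bitscore <- round(500 - 50 * (ord_rank - 1) +
                                 stats::runif(nrow(seq_flat), 0, 10), 1)
  } else {
    seq_flat$length <- integer(0); seq_flat$evalue <- numeric(0)
    seq_flat$bitscore <- numeric(0)
  }

  st <- struct_rows$items[seq_len(struct_rows$n)]
  struct_flat <- data.frame(
    query_id = vapply(st, `[[`, character(1), "query_id"),
    subject_pdb_id = vapply(st, `[[`, character(1), "subject_pdb_id"),
    z_score = vapply(st, `[[`, numeric(1), "z_score"),
    rmsd_angstrom = vapply(st, `[[`, numeric(1), "rmsd_angstrom"),
    subject_classification = vapply(st, `[[`, character(1),
                                    "subject_classification"),
    subject_name = vapply(st, `[[`, character(1), "subject_name"),
    stringsAsFactors = FALSE)
  struct_flat$subject_deposition_date <-
    as.Date(vapply(st, function(r) as.numeric(r$subject_deposition_date),
                   numeric(1)))

  assignment <- data.frame(pdb_id = ids, annotation_status = status,
                           sequence_class = seq_class,
                           structure_class = struct_class,
                           stringsAsFactors = FALSE)

  list(entries = entries,
       annotations = ann_list,
       sequence_hits = group_sequence_hits(seq_flat, ann_list),
       structure_hits = split_by(struct_flat, "query_id"),
       seq_flat = seq_flat,
       struct_flat = struct_flat,
       assignment = assignment,
       spec = spec)
}

## draw 1-3 GO terms in one domain (non-binding for MF); used for subjects
pick_go <- function(domain, k = NULL) {
  pool <- switch(domain,
                 BIOLOGICAL_PROCESS = GO_BP,
                 MOLECULAR_FUNCTION = GO_MF,
                 CELLULAR_COMPONENT = GO_CC)
  if (is.null(k)) k <- sample(1:3, 1)
  k <- min(k, length(pool))
  sel <- sample(length(pool), k)
  go_terms(unname(pool[sel]), domain, names(pool)[sel])
}

make_sufficient_record <- function(acc, i) {
  name <- sample(INFORMATIVE_NAMES, 1)
  route <- i %% 4L
  if (route == 0L) {
    go <- rbind(pick_go("BIOLOGICAL_PROCESS", 1), pick_go("MOLECULAR_FUNCTION", 1),
                pick_go("CELLULAR_COMPONENT", 1))
    protein_annotation(acc, name, reviewed = TRUE, go = go,
                       integration_date = "2000-01-01")
  } else if (route == 1L) {
    protein_annotation(acc, name, reviewed = i %% 2L == 0L,
                       function_text = "Catalyzes the phosphorylation of its substrate.",
                       go = pick_go("BIOLOGICAL_PROCESS", 1),
                       integration_date = "2000-01-01")
  } else if (route == 2L) {
    protein_annotation(acc, name, reviewed = TRUE,
                       ec_numbers = sample(c("2.7.1.21", "5.5.1.5", "1.1.1.-"), 1),
                       integration_date = "2000-01-01")
  } else {
    protein_annotation(acc, name, reviewed = FALSE,
                       catalytic_activity = "ATP + thymidine = ADP + TMP",
                       integration_date = "2000-01-01")
  }
}

make_insufficient_record <- function(acc, i) {
  name <- sample(INFORMATIVE_NAMES, 1)
  route <- i %% 4L
  go <- if (route == 0L) {
    go_terms()                                   # no terms at all
  } else if (route == 1L) {
    rbind(pick_go("BIOLOGICAL_PROCESS", 1),      # too few terms
          pick_go("MOLECULAR_FUNCTION", 1))
  } else if (route == 2L) {
    pick_go("CELLULAR_COMPONENT", 3)             # localization only
  } else {
    k <- 3L + i %% 2L                            # all terms "*-binding"
    sel <- sample(length(GO_MF_BINDING), k, replace = k > length(GO_MF_BINDING))
    sel <- sel[!duplicated(sel)]
    if (length(sel) < 3L) sel <- seq_len(3L)
    go_terms(unname(GO_MF_BINDING[sel]), "MOLECULAR_FUNCTION",
             names(GO_MF_BINDING)[sel])
  }
  protein_annotation(acc, name, reviewed = i %% 2L == 0L, go = go,
                     integration_date = "2000-01-01")
}

make_equivalent_record <- function(acc, i) {
  name <- paste(sample(UNINFORMATIVE_STEMS, 1), toupper(base36(i)))
  # a rich GO profile or even function text must not rescue a record whose
  # own name is uninformative
  go <- if (i %% 3L == 0L)
    rbind(pick_go("BIOLOGICAL_PROCESS", 2), pick_go("MOLECULAR_FUNCTION", 2))
  else go_terms()
  protein_annotation(acc, name, reviewed = FALSE,
                     function_text = if (i %% 5L == 0L)
                       "May play a role in DNA repair." else "",
                     go = go, integration_date = "2000-01-01")
}

#' Perturb a generated fixture corpus
#'
#' Metamorphic-testing support: `"shuffle_rows"` permutes the data rows of
#' each fixture file (headers kept), `"relabel_ids"` renames every corpus
#' entry ID by a fresh bijective map (applied consistently to entry rows,
#' sequence-hit query IDs including chain suffixes, and structural-hit query
#' and in-dataset subject IDs). Pipeline class counts are invariant under
#' both operations; relabelling also relabels the reported ID lists.
#'
#' @param dir Directory holding the four fixture files (as written by
#'   [generate_corpus()]).
#' @param op `"shuffle_rows"` or `"relabel_ids"`.
#' @param seed RNG seed; the same seed gives byte-identical output.
#' @param out_dir Output directory (defaults to perturbing in place).
#' @return Invisibly, the named vector of output paths; for
#'   `"relabel_ids"` the ID map is attached as the `"id_map"` attribute.
#' @export
perturb_corpus <- function(dir, op = c("shuffle_rows", "relabel_ids"),
                           seed = 1L, out_dir = dir) {
  op <- match.arg(op)
  src <- file.path(dir, FIXTURE_FILES)
  names(src) <- names(FIXTURE_FILES)
  missing <- !file.exists(src)
  if (any(missing))
    fail("synthetic", "fixture file(s) not found: ",
         paste(src[missing], collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dst <- file.path(out_dir, FIXTURE_FILES)
  names(dst) <- names(FIXTURE_FILES)
  if (op == "shuffle_rows") {
    with_seed(seed, {
      for (k in names(src)) {
        lines <- readLines(src[[k]], encoding = "UTF-8")
        body <- lines[-1]
        if (length(body) > 1L) body <- body[sample.int(length(body))]
        writeLines(c(lines[1], body), dst[[k]], useBytes = TRUE)
      }
    })
    return(invisible(dst))
  }
  ## relabel_ids: bijective rename of the corpus entry IDs
  entries <- read_tsv(src[["entries"]], "synthetic")
  old <- entries$pdb_id
  new <- with_seed(seed, {
    offset <- sample(10000:40000, 1)
    make_entry_ids(length(old), offset = offset)
  })
  if (anyDuplicated(new) || length(new) != length(old))
    fail("synthetic", "relabel map is not bijective")
  map <- stats::setNames(new, old)
  remap <- function(x) ifelse(x %in% names(map), map[x], x)
  entries$pdb_id <- unname(remap(entries$pdb_id))
  write_tsv(entries, dst[["entries"]])
  file.copy(src[["annotations"]], dst[["annotations"]], overwrite = TRUE)
  seqh <- read_tsv(src[["seq_hits"]], "synthetic")
  if (nrow(seqh) > 0L) {
    core <- strip_chain(seqh$qseqid)
    suffix <- substring(seqh$qseqid, nchar(core) + 1L)
    seqh$qseqid <- paste0(unname(remap(core)), suffix)
  }
  write_tsv(seqh, dst[["seq_hits"]])
  sth <- read_tsv(src[["struct_hits"]], "synthetic")
  if (nrow(sth) > 0L) {
    sth$query_id <- unname(remap(sth$query_id))
    sth$subject_pdb_id <- unname(remap(sth$subject_pdb_id))
  }
  write_tsv(sth, dst[["struct_hits"]])
  invisible(structure(dst, id_map = map))
}
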