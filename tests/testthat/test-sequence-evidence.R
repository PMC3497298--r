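go_of <- function(domain, name) {
  go_terms("GO:0012345", domain, name)
}

test_that("hit characterization follows the subject-name blacklist", {
  expect_true(hit_is_characterized(list(subject_name = "ATP-dependent protein kinase")))
  expect_false(hit_is_characterized(list(subject_name = "Probable kinase yfgh")))
  expect_true(hit_is_characterized(list(subject_name = "NAD(P)H-hydrate epimerase")))
})

test_that("supported domains respect per-domain cutoffs, strictly", {
  co <- identity_cutoffs()
  h <- function(pid, go) list(percent_identity = pid, subject_go = go)
  bp_mf <- rbind(go_of("BIOLOGICAL_PROCESS", "DNA repair"),
                 go_of("MOLECULAR_FUNCTION", "kinase activity"))
  expect_identical(hit_supported_domains(h(45, bp_mf), co),
                   "BIOLOGICAL_PROCESS")
  expect_identical(hit_supported_domains(h(55, bp_mf), co),
                   c("BIOLOGICAL_PROCESS", "MOLECULAR_FUNCTION"))
  # the "*-binding" exclusion bites only molecular function
  expect_identical(hit_supported_domains(
    h(55, go_of("MOLECULAR_FUNCTION", "zinc ion binding")), co), character(0))
  # exact boundary identities never qualify
  expect_identical(hit_supported_domains(
    h(40.0, go_of("BIOLOGICAL_PROCESS", "DNA repair")), co), character(0))
  expect_identical(hit_supported_domains(
    h(50.0, go_of("MOLECULAR_FUNCTION", "kinase activity")), co), character(0))
  expect_identical(hit_supported_domains(
    h(60.0, go_of("CELLULAR_COMPONENT", "cytoplasm")), co), character(0))
  expect_identical(hit_supported_domains(
    h(61, go_of("CELLULAR_COMPONENT", "cytoplasm")), co), "CELLULAR_COMPONENT")
  # no GO terms, nothing to support
  expect_identical(hit_supported_domains(h(99, go_terms()), co), character(0))
})

test_that("query outcomes partition into the five evidence classes", {
  # two kinase subjects above the biological-process cutoff
  kin <- rbind(mk_seq_hit("1htw", "Thymidine kinase", 43,
                          go_bp("protein phosphorylation")),
               mk_seq_hit("1htw", "Homoserine kinase", 47,
                          go_bp("protein phosphorylation"), accession = "B0002"))
  ev <- classify_sequence_evidence(kin)
  expect_identical(ev$value, "SIGNIFICANT_ALL_CHARACTERIZED")
  expect_identical(nrow(ev$supporting_hits), 2L)

  mixed <- rbind(kin[1, ], mk_seq_hit("1htw", "Putative kinase", 80,
                                      go_bp(), accession = "B0003"))
  expect_identical(classify_sequence_evidence(mixed)$value,
                   "SIGNIFICANT_MIXED")

  disc <- mk_seq_hit("1xyz", "Uncharacterized protein TM0001", 90, go_bp())
  expect_identical(classify_sequence_evidence(disc)$value, "DISCARDED_ONLY")

  sub <- mk_seq_hit("1xyz", "Thymidine kinase", 35, go_bp())
  expect_identical(classify_sequence_evidence(sub)$value, "SUB_THRESHOLD")
  expect_null(classify_sequence_evidence(sub)$supporting_hits)

  # sub-threshold beats discarded-only when both kinds are present
  expect_identical(classify_sequence_evidence(rbind(sub, disc))$value,
                   "SUB_THRESHOLD")

  expect_identical(classify_sequence_evidence(NULL)$value, "NO_HITS")
})

test_that("stage summary counts are conserved and significance is derived", {
  outcomes <- list(
    a = classify_sequence_evidence(mk_seq_hit("1aaa", "Thymidine kinase", 45,
                                              go_bp())),
    b = classify_sequence_evidence(NULL),
    c = classify_sequence_evidence(mk_seq_hit("1ccc", "Putative protein", 45,
                                              go_bp())))
  s <- summarize_sequence_stage(outcomes)
  primitive <- c("SIGNIFICANT_ALL_CHARACTERIZED", "SIGNIFICANT_MIXED",
                 "DISCARDED_ONLY", "SUB_THRESHOLD", "NO_HITS")
  expect_identical(sum(s[primitive]), 3L)
  expect_identical(unname(s[["SIGNIFICANT"]]), 1L)
  empty <- summarize_sequence_stage(list())
  expect_true(all(empty == 0L))
})

test_that("raising any cutoff never turns a query significant", {
  with_seed_local(11, {
    for (rep in 1:25) {
      k <- sample(1:4, 1)
      hits <- do.call(rbind, lapply(seq_len(k), function(j) {
        dm <- sample(c("BIOLOGICAL_PROCESS", "MOLECULAR_FUNCTION",
                       "CELLULAR_COMPONENT"), 1)
        nm <- sample(c("kinase activity", "ATP binding", "cytoplasm",
                       "DNA repair"), 1)
        mk_seq_hit("1aaa",
                   sample(c("Thymidine kinase", "Putative protein"), 1),
                   round(runif(1, 5, 95), 1), go_of(dm, nm),
                   accession = sprintf("B%04d", j))
      }))
      base <- classify_sequence_evidence(hits)$value
      for (bump in list(c(20, 0, 0), c(0, 20, 0), c(0, 0, 20), c(30, 30, 30))) {
        raised <- identity_cutoffs(min(40 + bump[1], 100),
                                   min(50 + bump[2], 100),
                                   min(60 + bump[3], 100))
        after <- classify_sequence_evidence(hits, raised)$value
        if (!grepl("^SIGNIFICANT", base)) {
          expect_false(grepl("^SIGNIFICANT", after))
        }
      }
    }
  })
})

test_that("with tiny cutoffs and a no-op blacklist every GO-annotated hit wins", {
  tiny <- identity_cutoffs(1e-6, 1e-6, 1e-6)
  noop <- name_blacklist("zzzznotaword")
  hits <- rbind(mk_seq_hit("1aaa", "Putative uncharacterized protein", 15,
                           go_bp()),
                mk_seq_hit("1aaa", "Hypothetical protein", 5,
                           go_of("CELLULAR_COMPONENT", "cytoplasm"),
                           accession = "B0002"))
  ev <- classify_sequence_evidence(hits, tiny, noop)
  expect_identical(ev$value, "SIGNIFICANT_ALL_CHARACTERIZED")
})
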