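test_that("uninformative-name detection is whole-word and case-insensitive", {
  cases <- c("Hypothetical protein ybdK" = TRUE,
             "Putative uncharacterized protein" = TRUE,
             "Walker type ATP-ase" = FALSE,
             "Thymidine kinase" = FALSE,
             "UNKNOWN protein 12" = TRUE,
             "probability factor" = FALSE,   # no whole-word blacklist token
             "Probable kinase yfgh" = TRUE,
             " " = TRUE)
  expect_identical(unname(is_uninformative_name(names(cases))), unname(cases))
  expect_true(is_uninformative_name(""))
})

test_that("GO profile sufficiency applies the count and the two exceptions", {
  expect_true(go_profile_sufficient(go_mixed3()))
  # all cellular-component: localization only, insufficient at any count
  cc3 <- go_terms(sprintf("GO:000573%d", 1:3), "CELLULAR_COMPONENT",
                  c("cytoplasm", "nucleus", "membrane"))
  expect_false(go_profile_sufficient(cc3))
  cc5 <- rbind(cc3, cc3[1:2, ])
  expect_false(go_profile_sufficient(cc5))
  # every term name ends in "binding"
  bind3 <- go_terms(sprintf("GO:000552%d", 1:3), "MOLECULAR_FUNCTION",
                    c("ATP binding", "DNA binding", "metal ion binding"))
  expect_false(go_profile_sufficient(bind3))
  # mixed binding and non-binding clears the exception
  expect_true(go_profile_sufficient(rbind(bind3[1:2, ],
                                          go_terms("GO:0016301",
                                                   "MOLECULAR_FUNCTION",
                                                   "kinase activity"))))
  # below the count
  expect_false(go_profile_sufficient(go_mixed3()[1:2, ]))
  expect_false(go_profile_sufficient(go_terms()))
  # configurable minimum
  expect_false(go_profile_sufficient(go_mixed3(), min_terms = 4))
})

test_that("annotation status follows the mapping, name, and evidence routes", {
  ann <- list(
    PSUF = mk_annotation("PSUF", "Thymidine kinase", go_mixed3()),
    PEQ = mk_annotation("PEQ", "Uncharacterized protein yabc",
                        rbind(go_mixed3(), go_bp(), go_bp("DNA repair"))),
    PINS = mk_annotation("PINS", "Thymidine kinase", go_mixed3()[1:2, ]),
    PTXT = mk_annotation("PTXT", "Phosphoglycolate phosphatase",
                         function_text = "Dephosphorylates 2-phosphoglycolate."))
  status <- function(acc) classify_annotation_status(
    list(accessions = acc), ann)
  expect_identical(status(character(0)), "NO_MAPPING")
  expect_identical(status("NOT_IN_DB"), "NO_MAPPING")
  expect_identical(status("PEQ"), "UNCHARACTERIZED_EQUIVALENT")
  expect_identical(status("PSUF"), "SUFFICIENT")
  expect_identical(status("PTXT"), "SUFFICIENT")
  expect_identical(status("PINS"), "INSUFFICIENT")
  # any-sufficient policy: one sufficient record among several decides
  expect_identical(status(c("PINS", "PSUF")), "SUFFICIENT")
  expect_identical(classify_annotation_status(
    list(accessions = c("PINS", "PSUF")), ann, accession_policy = "first"),
    "INSUFFICIENT")
})

test_that("empty function fields with enough GO still qualify, and vice versa", {
  ann <- list(
    PGO = mk_annotation("PGO", "Aspartate aminotransferase", go_mixed3()),
    PEC = mk_annotation("PEC", "Aspartate aminotransferase", ec = "2.6.1.1"),
    PCAT = mk_annotation("PCAT", "Aspartate aminotransferase",
                         catalytic = "L-aspartate + 2-oxoglutarate = ..."))
  for (acc in names(ann)) {
    expect_identical(classify_annotation_status(list(accessions = acc), ann),
                     "SUFFICIENT")
  }
})

test_that("corpus partition is disjoint, exhaustive, and order-preserving", {
  ann <- list(P0001 = mk_annotation("P0001", "Thymidine kinase", go_mixed3()),
              P0002 = mk_annotation("P0002", "Putative uncharacterized protein"),
              P0003 = mk_annotation("P0003", "Thymidine kinase"))
  entries <- mk_entries(c("1aaa", "1bbb", "1ccc", "1ddd"),
                        accessions = list("P0001", "P0002", "P0003",
                                          character(0)))
  buckets <- partition_corpus(entries, ann)
  expect_identical(buckets$SUFFICIENT, "1aaa")
  expect_identical(buckets$UNCHARACTERIZED_EQUIVALENT, "1bbb")
  expect_identical(buckets$INSUFFICIENT, "1ccc")
  expect_identical(buckets$NO_MAPPING, "1ddd")
  expect_identical(sort(unlist(buckets, use.names = FALSE)),
                   sort(entries$pdb_id))

  single <- partition_corpus(mk_entries("1ddd", accessions = list(character(0))),
                             ann)
  expect_identical(single$NO_MAPPING, "1ddd")
  expect_identical(lengths(single)[c("SUFFICIENT", "INSUFFICIENT",
                                     "UNCHARACTERIZED_EQUIVALENT")],
                   c(SUFFICIENT = 0L, INSUFFICIENT = 0L,
                     UNCHARACTERIZED_EQUIVALENT = 0L))
})

test_that("adding a GO term never flips SUFFICIENT to INSUFFICIENT", {
  extra <- go_terms("GO:0099999", "MOLECULAR_FUNCTION", "hydrolase activity")
  extra_cc <- go_terms("GO:0088888", "CELLULAR_COMPONENT", "cytoplasm")
  extra_bind <- go_terms("GO:0077777", "MOLECULAR_FUNCTION", "ATP binding")
  with_seed_local(42, {
    pools <- list(go_terms(), go_mixed3()[1, ], go_mixed3()[1:2, ],
                  go_mixed3(),
                  go_terms(sprintf("GO:000573%d", 1:3), "CELLULAR_COMPONENT",
                           c("cytoplasm", "nucleus", "membrane")),
                  go_terms(sprintf("GO:000552%d", 1:3), "MOLECULAR_FUNCTION",
                           c("ATP binding", "DNA binding", "zinc ion binding")))
    for (base in pools) {
      for (add in list(extra, extra_cc, extra_bind)) {
        before <- go_profile_sufficient(base)
        after <- go_profile_sufficient(rbind(base, add))
        if (before) expect_true(after)
      }
    }
  })
})

test_that("an uninformative record name dominates any annotation richness", {
  rich <- mk_annotation("PX", "Hypothetical protein TM0021",
                        go = rbind(go_mixed3(), go_mixed3()),
                        function_text = "May be a kinase.",
                        ec = "2.7.1.21")
  expect_identical(classify_annotation_status(
    list(accessions = "PX"), list(PX = rich)), "UNCHARACTERIZED_EQUIVALENT")
})
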