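test_that("whole-year lags reproduce the reference deposition gaps", {
  expect_identical(lag_years("2000-08-13", "2011-03-08"), 10L)  # 1fl9 / Q66624
  expect_identical(lag_years("2002-02-04", "2011-04-28"), 9L)   # 1kyh / 3rqh
  expect_identical(lag_years("2005-01-01", "2005-01-01"), 0L)
  expect_identical(lag_years("2011-03-08", "2000-08-13"), -11L) # hit predates
})

test_that("lag is antisymmetric under date swap up to the floor offset", {
  with_seed_local(3, {
    d1 <- as.Date("1995-01-01") + sample.int(9000, 40)
    d2 <- as.Date("1995-01-01") + sample.int(9000, 40)
    fwd <- lag_years(d1, d2)
    bwd <- lag_years(d2, d1)
    # floor() makes -(x) and floor(-x) differ by one off integer years
    expect_true(all((fwd + bwd) %in% c(0L, -1L)))
  })
})

test_that("metadata discrepancy flags match the reference examples", {
  ctl <- triage_control()
  flag_of <- function(class, name) {
    e <- mk_entries("1aaa", classification = class, molecule = name)
    build_provenance(e[1, ], control = ctl)$discrepancy_flags
  }
  # functional molecule name under an unknown-function header (2qen-like)
  expect_identical(flag_of("unknown function", "Walker type ATP-ase"),
                   "NAME_VS_CLASS")
  # functional header with an uninformative molecule name (1r8g-, 3eb0-like)
  expect_identical(flag_of("ligase", "Hypothetical protein ybdK"),
                   "CLASS_VS_NAME")
  expect_identical(flag_of("transferase", "Putative uncharacterized protein"),
                   "CLASS_VS_NAME")
  # consistent metadata raises nothing
  expect_identical(flag_of("unknown function", "Hypothetical protein"),
                   character(0))
  expect_identical(flag_of("ligase", "Glutamate--cysteine ligase"),
                   character(0))
  # pure function of the two strings: same inputs, same flags
  expect_identical(flag_of("ligase", "Hypothetical protein ybdK"),
                   flag_of("ligase", "Hypothetical protein ybdK"))
})

test_that("provenance combines the earliest evidence date across channels", {
  e <- mk_entries("1fl9", dates = "2000-08-13")
  seq_ev <- classify_sequence_evidence(
    mk_seq_hit("1fl9", "Thymidine kinase", 45, go_bp(), date = "2011-03-08"))
  rec <- build_provenance(e[1, ], seq = seq_ev)
  expect_identical(rec$earliest_hit_date, as.Date("2011-03-08"))
  expect_true(rec$hit_postdates_query)
  expect_identical(rec$lag_years, 10L)

  struct_ev <- classify_structure_evidence(
    mk_struct_hit("1fl9", "9aaa", 30, date = "2009-06-01"))
  both <- build_provenance(e[1, ], seq = seq_ev, struct = struct_ev)
  expect_identical(both$earliest_hit_date, as.Date("2009-06-01"))

  # a probable (non-definite) structural hit contributes no evidence date
  weak <- classify_structure_evidence(
    mk_struct_hit("1fl9", "9aaa", 15, date = "1999-01-01"))
  none <- build_provenance(e[1, ], struct = weak)
  expect_true(is.na(none$earliest_hit_date))
  expect_true(is.na(none$hit_postdates_query))
  expect_true(is.na(none$lag_years))

  # evidence available on deposition day does not postdate
  same_day <- build_provenance(e[1, ], seq = classify_sequence_evidence(
    mk_seq_hit("1fl9", "Thymidine kinase", 45, go_bp(), date = "2000-08-13")))
  expect_false(same_day$hit_postdates_query)
})

test_that("date accounting matches a brute-force comparison on a small corpus", {
  # 20 queries: 12 with sequence evidence (7 postdating), 5 with definite
  # structural evidence (2 postdating), 3 with none
  with_seed_local(9, {
    qdate <- as.Date("2003-01-01") + sample.int(1000, 20)
    ids <- sprintf("1a%02d", 1:20)
    records <- vector("list", 20)
    expected_blast <- logical(0)
    expected_dali <- logical(0)
    expected_predating <- character(0)
    for (i in 1:20) {
      e <- mk_entries(ids[i], dates = format(qdate[i], "%Y-%m-%d"))
      seq_ev <- struct_ev <- NULL
      if (i <= 12) {
        post <- i <= 7
        hd <- qdate[i] + if (post) sample(30:900, 1) else -sample(30:900, 1)
        seq_ev <- classify_sequence_evidence(
          mk_seq_hit(ids[i], "Thymidine kinase", 45, go_bp(),
                     date = format(hd, "%Y-%m-%d")))
        expected_blast <- c(expected_blast, hd > qdate[i])
        if (hd < qdate[i]) expected_predating <- c(expected_predating, ids[i])
      } else if (i <= 17) {
        post <- i <= 14
        hd <- qdate[i] + if (post) sample(30:900, 1) else -sample(30:900, 1)
        struct_ev <- classify_structure_evidence(
          mk_struct_hit(ids[i], "9aaa", 30, date = format(hd, "%Y-%m-%d")))
        expected_dali <- c(expected_dali, hd > qdate[i])
        if (hd < qdate[i]) expected_predating <- c(expected_predating, ids[i])
      }
      records[[i]] <- build_provenance(e[1, ], seq = seq_ev, struct = struct_ev)
    }
    acc <- summarize_dates(records)
    expect_equal(acc$fraction_hits_postdate_blast,
                 round(100 * sum(expected_blast) / length(expected_blast), 2))
    expect_equal(acc$fraction_hits_postdate_dali,
                 round(100 * sum(expected_dali) / length(expected_dali), 2))
    expect_identical(acc$predating_query_ids, sort(expected_predating))
    # XOR: with no equal-date ties every evidence-bearing query is either
    # postdated or in the predating list, never both
    for (i in 1:17) {
      r <- records[[i]]
      expect_true(xor(isTRUE(r$hit_postdates_query),
                      r$query_id %in% acc$predating_query_ids))
    }
  })
})

test_that("degenerate date accountings hit the documented limits", {
  e <- mk_entries(c("1aaa", "1bbb"), dates = "2003-01-01")
  mk_rec <- function(i, hit_date) {
    build_provenance(e[i, ], seq = classify_sequence_evidence(
      mk_seq_hit(e$pdb_id[i], "Thymidine kinase", 45, go_bp(),
                 date = hit_date)))
  }
  all_post <- list(mk_rec(1, "2005-01-01"), mk_rec(2, "2006-01-01"))
  acc <- summarize_dates(all_post)
  expect_identical(acc$fraction_hits_postdate_blast, 100)
  expect_identical(acc$predating_query_ids, character(0))

  none_post <- list(mk_rec(1, "2001-01-01"), mk_rec(2, "2000-01-01"))
  acc <- summarize_dates(none_post)
  expect_identical(acc$fraction_hits_postdate_blast, 0)
  expect_identical(acc$predating_query_ids, c("1aaa", "1bbb"))
  expect_true(is.na(acc$fraction_hits_postdate_dali))
})
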