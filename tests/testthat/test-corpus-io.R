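test_that("structure entries round-trip and preserve file order", {
  entries <- mk_entries(c("1htw", "1jzt", "1l0b"),
                        dates = c("2001-01-01", "2001-09-17", "2002-03-01"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure_entries(entries, path)
  back <- read_structure_entries(path)
  expect_identical(back$pdb_id, c("1htw", "1jzt", "1l0b"))
  expect_identical(back$deposition_date, entries$deposition_date)
  expect_identical(back$accessions, entries$accessions)
  # byte-identical on rewrite
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_structure_entries(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an entries file with only a header yields an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("pdb_id", "molecule_name", "classification_header",
                     "deposition_date", "species", "accessions"),
                   collapse = "\t"), path)
  expect_identical(nrow(read_structure_entries(path)), 0L)
})

test_that("malformed entry rows are rejected with their line numbers", {
  entries <- mk_entries(c("1htw", "2abc"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure_entries(entries, path)
  lines <- readLines(path)
  lines[2] <- sub("^1htw", "XY", lines[2])
  writeLines(lines, path)
  expect_error(read_structure_entries(path), "line 2.*XY")

  write_structure_entries(mk_entries(c("1htw", "2abc")), path)
  lines <- readLines(path)
  lines[3] <- sub("2005-06-15", "15 June 2005", lines[3])
  writeLines(lines, path)
  expect_error(read_structure_entries(path), "line 3.*deposition_date")

  write_structure_entries(mk_entries(c("1htw", "2abc")), path)
  lines <- readLines(path)
  lines[3] <- sub("^2abc", "1htw", lines[3])
  writeLines(lines, path)
  expect_error(read_structure_entries(path), "duplicate pdb_id.*1htw")
})

test_that("annotations round-trip with GO sub-fields and dates intact", {
  ann <- list(
    Q66624 = mk_annotation("Q66624", "Thymidine kinase", go_mixed3(),
                           ec = "2.7.1.21", date = "2011-03-08"),
    P0001 = mk_annotation("P0001", "Uncharacterized protein YbdK",
                          date = "2004-05-06"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_named(back, c("Q66624", "P0001"))
  expect_identical(back$Q66624$integration_date, as.Date("2011-03-08"))
  expect_identical(back$Q66624$ec_numbers, "2.7.1.21")
  expect_identical(back$Q66624$go_terms$term_name, go_mixed3()$term_name)
  # a record with no GO terms and empty text fields is valid on read;
  # classification happens downstream
  expect_identical(nrow(back$P0001$go_terms), 0L)
})

test_that("annotation validation rejects bad domains, dups, and bad EC", {
  ann <- list(A1 = mk_annotation("A1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  lines <- readLines(path)
  lines[2] <- sub("\t\t2003-01-01", "\tGO:0016301|MF|kinase activity\t2003-01-01",
                  lines[2])
  writeLines(lines, path)
  expect_error(read_annotations(path), "unknown GO domain token 'MF'")

  write_annotations(c(ann, ann), path)
  expect_error(read_annotations(path), "duplicate accession")

  expect_error(mk_annotation("A2", ec = "not-an-ec"), "EC")
  expect_error(mk_annotation("A3", date = "8 March 2011"), "ISO 8601")
})

test_that("sequence hits group by query with subject metadata attached", {
  ann <- list(B1 = mk_annotation("B1", "Thymidine kinase", go_bp()),
              B2 = mk_annotation("B2", "NAD(P)H-hydrate epimerase", go_bp()),
              B3 = mk_annotation("B3", "Triosephosphate isomerase", go_bp()))
  flat <- data.frame(qseqid = c("1htw", "1htw_A", "1htw", "2abc"),
                     sseqid = c("B1", "B2", "B3", "B1"),
                     pident = c(45.5, 52.0, 38.0, 70.0),
                     length = 120L, evalue = 1e-20,
                     bitscore = c(300, 250, 200, 180),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_hits(flat, path)
  hits <- read_sequence_hits(path, ann)
  # chain suffix stripped: all three rows group under the entry id
  expect_named(hits, c("1htw", "2abc"))
  expect_identical(nrow(hits[["1htw"]]), 3L)
  expect_identical(hits[["1htw"]]$subject_name[2], "NAD(P)H-hydrate epimerase")
  expect_identical(hits[["1htw"]]$subject_integration_date,
                   rep(as.Date("2003-01-01"), 3))
  # file order (descending bit score) is preserved, per re-sort oracle
  expect_identical(hits[["1htw"]]$bit_score,
                   sort(hits[["1htw"]]$bit_score, decreasing = TRUE))
  # conservation in strict mode: grouped rows equal file rows
  expect_identical(sum(vapply(hits, nrow, integer(1))), nrow(flat))
})

test_that("sequence hit validation enforces identity and e-value ranges", {
  ann <- list(B1 = mk_annotation("B1"))
  flat <- data.frame(qseqid = "1htw", sseqid = "B1", pident = 101.0,
                     length = 100L, evalue = 1e-5, bitscore = 100,
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_hits(flat, path)
  expect_error(read_sequence_hits(path, ann), "pident.*line.* 2|pident at line")

  flat$pident <- 50
  flat$evalue <- -1
  write_sequence_hits(flat, path)
  expect_error(read_sequence_hits(path, ann), "evalue")
})

test_that("hits with unknown subjects are dropped leniently or fatal strictly", {
  ann <- list(B1 = mk_annotation("B1"))
  flat <- data.frame(qseqid = c("1htw", "1htw"), sseqid = c("B1", "ZMISSING"),
                     pident = c(50, 60), length = 100L, evalue = 1e-5,
                     bitscore = c(200, 100), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_hits(flat, path)
  hits <- read_sequence_hits(path, ann)
  expect_identical(nrow(hits[["1htw"]]), 1L)
  expect_identical(attr(hits, "dropped")$sseqid, "ZMISSING")
  expect_error(read_sequence_hits(path, ann, strict = TRUE),
               "ZMISSING")
})

test_that("structure hits parse Z-scores, dates, and reject negative RMSD", {
  flat <- mk_struct_hit("3hfq", subject = "1jof", z = 39.5,
                        classification = "isomerase",
                        name = "Carboxy-cis,cis-muconate cyclase")
  flat <- rbind(flat, mk_struct_hit("1kyh", subject = "3rqh", z = 12,
                                    classification = "lyase",
                                    date = "2011-04-28"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_structure_hits(flat, path)
  hits <- read_structure_hits(path)
  expect_identical(hits[["3hfq"]]$z_score, 39.5)
  expect_identical(hits[["1kyh"]]$subject_deposition_date,
                   as.Date("2011-04-28"))

  # header-only file: empty mapping
  writeLines(readLines(path)[1], path)
  expect_identical(length(read_structure_hits(path)), 0L)

  flat$rmsd_angstrom[1] <- -0.5
  write_structure_hits(flat, path)
  expect_error(read_structure_hits(path), "rmsd")
})

test_that("missing input files fail with a clear error", {
  expect_error(read_structure_entries("no/such/file.tsv"), "not found")
  expect_error(read_structure_hits("no/such/file.tsv"), "not found")
})
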