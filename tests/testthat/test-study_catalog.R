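test_that("study table parses rows, models and counts; bad input errors", {
  path <- write_tsv_fixture(c(
    "study_id\torganism\tdisease_models\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference",
    "a\tworm\tP\tHtt-Q150\tRNAi\t3\t3\tr1",
    "b\tyeast\tP and S\tHtt, synuclein\tgenetic\t5\t2\tr2",
    "c\tfly\tAbeta, T\tmix\tscreen\t0\t\tr3"))
  st <- read_study_table(path)
  expect_s3_class(st, "study_table")
  expect_equal(st$study_id, c("a", "b", "c"))
  expect_equal(st$disease_models[[2]], c("P", "S"))
  expect_equal(st$disease_models[[3]], c("Abeta", "T"))
  expect_true(is.na(st$n_orthologues_expected[3]))

  # header-only file -> empty table
  empty <- read_study_table(write_tsv_fixture(
    "study_id\torganism\tdisease_models\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference"))
  expect_equal(nrow(empty), 0L)

  # missing column named in the error
  expect_error(read_study_table(write_tsv_fixture(
    c("study_id\torganism\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference",
      "a\tworm\tc\ts\t1\t1\tr"))), "disease_models")
  # duplicate id
  expect_error(read_study_table(write_tsv_fixture(c(
    "study_id\torganism\tdisease_models\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference",
    "a\tworm\tP\tc\ts\t1\t1\tr",
    "a\tworm\tP\tc\ts\t1\t1\tr"))), "duplicate study_id")
  # unparseable count carries the row number
  expect_error(read_study_table(write_tsv_fixture(c(
    "study_id\torganism\tdisease_models\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference",
    "a\tworm\tP\tc\ts\tmany\t1\tr"))), "row 1")
})

test_that("gene lists keep duplicates, skip blank ids, enforce species", {
  studies <- make_studies("a", "worm")
  studies$n_reported <- 4L
  path <- write_tsv_fixture(c(
    "raw_id\teffect\tnote",
    "g1\tsuppressor\t",
    "g2\t\t",
    "\tenhancer\tblank id",
    "g1\tenhancer\tduplicate kept"))
  w <- capture_warnings(calls <- read_gene_list(path, studies[1]))
  expect_true(any(grepl("blank raw_id", w)))
  # count mismatch also warns (3 records vs n_reported 4)
  expect_true(any(grepl("n_reported", w)))
  expect_equal(calls$raw_id, c("g1", "g2", "g1"))
  expect_equal(calls$effect, c("suppressor", "unknown", "enhancer"))
  expect_equal(attr(calls, "n_skipped"), 1L)
  expect_true(all(calls$species == "worm"))

  # conflicting species column is a hard error
  bad <- write_tsv_fixture(c("raw_id\tspecies", "g1\tfly"))
  expect_error(read_gene_list(bad, studies[1]), "conflicts")
})

test_that("catalog summary partitions totals by organism and handles empties", {
  path <- write_tsv_fixture(c(
    "study_id\torganism\tdisease_models\tconstruct\tscreen_type\tn_reported\tn_orthologues_expected\treference",
    "a\tworm\tP\tc\ts\t10\t10\tr",
    "b\tworm\tS\tc\ts\t5\t5\tr",
    "c\tyeast\tP\tc\ts\t7\t3\tr"))
  s <- summarize_catalog(read_study_table(path))
  expect_equal(s$n_studies, 3L)
  expect_equal(s$n_reported, 22L)
  expect_equal(s$n_orthologues_expected, 18L)
  expect_equal(sum(s$by_organism$n_reported), s$n_reported)
  expect_equal(sum(s$by_organism$n_orthologues_expected),
               s$n_orthologues_expected)

  empty <- summarize_catalog(make_studies(character(), character())[0])
  expect_equal(empty$n_studies, 0L)
  expect_equal(empty$n_reported, 0L)
})

test_that("study table round-trips through TSV", {
  st <- load_fixture("table1_catalog")
  out <- tempfile(fileext = ".tsv")
  write_study_table(st, out)
  back <- read_study_table(out)
  expect_equal(back$study_id, st$study_id)
  expect_equal(back$n_reported, st$n_reported)
  expect_equal(back$n_orthologues_expected, st$n_orthologues_expected)
  expect_equal(lapply(back$disease_models, sort),
               lapply(st$disease_models, sort))
})
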