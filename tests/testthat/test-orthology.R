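groups_file <- function(lines) write_tsv_fixture(lines)

test_that("OrthoMCL groups parse; unknown prefixes and empty groups warn", {
  path <- groups_file(c(
    "G1: cel|F26D10.3 dme|Hsc70-4 sce|SSA1",
    "G2: xxx|foo cel|rab-1x",
    "G3: yyy|bar"))
  w <- capture_warnings(map <- read_orthomcl_groups(path))
  expect_true(any(grepl("unknown species prefix", w)))
  expect_true(any(grepl("empty group", w)))
  expect_equal(attr(map, "n_skipped_members"), 2L)
  expect_equal(attr(map, "n_skipped_groups"), 1L)
  expect_setequal(
    map$members[map$members$group_id == "G1"]$species,
    c("worm", "fly", "yeast"))

  expect_error(read_orthomcl_groups(groups_file(c("G1: cel|a", "no colon here"))),
               "line 2")
})

test_that("pairwise tables support one-to-many and reject paralogy", {
  path <- write_tsv_fixture(c(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence",
    "fly\tCG31196\tworm\tftt-2\tbest-blast",
    "fly\tCG31196\tworm\tpar-5\tbest-blast"))
  map <- read_pairwise_orthologs(path)
  expect_equal(worm_orthologues(map, "fly", "CG31196"), c("ftt-2", "par-5"))

  empty <- read_pairwise_orthologs(write_tsv_fixture(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence"))
  expect_equal(worm_orthologues(empty, "fly", "CG31196"), character())

  bad <- write_tsv_fixture(c(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence",
    "worm\ta\tworm\tb\tx"))
  expect_error(read_pairwise_orthologs(bad), "paralogy")
})

test_that("groups and pairwise sources merge with union semantics", {
  g <- read_orthomcl_groups(groups_file("G1: dme|CG31196 cel|F52D10.3 cel|M117.2"))
  p <- read_pairwise_orthologs(write_tsv_fixture(c(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence",
    "fly\tCG31196\tworm\tF52D10.3\tblast",
    "fly\tCG31196\tworm\tM117.2\tblast")))
  merged <- merge_orthology_maps(g, p)
  # same relation from both dialects: query answers unchanged, no duplicates
  expect_equal(worm_orthologues(merged, "fly", "CG31196"),
               worm_orthologues(g, "fly", "CG31196"))
  # disjoint extra relation unions in
  p2 <- read_pairwise_orthologs(write_tsv_fixture(c(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence",
    "fly\tCG31196\tworm\tX99Z9.9\tblast")))
  merged2 <- merge_orthology_maps(g, p2)
  expect_equal(worm_orthologues(merged2, "fly", "CG31196"),
               sort(c("F52D10.3", "M117.2", "X99Z9.9")))
})

test_that("query symmetry holds for genes sharing a group", {
  map <- read_orthomcl_groups(groups_file(c(
    "G1: sce|POX1 dme|CG5009 cel|F59F4.1 cel|F25C8.1",
    "G2: sce|POX1 cel|C48B4.1")))
  # fly gene reaches worm members of all POX1 groups it shares
  expect_equal(worm_orthologues(map, "fly", "CG5009"),
               c("F25C8.1", "F59F4.1"))
  expect_equal(worm_orthologues(map, "yeast", "POX1"),
               c("C48B4.1", "F25C8.1", "F59F4.1"))
  # symmetry on the cross-species pair itself
  expect_true("CG5009" %in% orthologues(map, "yeast", "POX1", "fly"))
  expect_true("POX1" %in% orthologues(map, "fly", "CG5009", "yeast"))
})

test_that("map_study counts distinct worm orthologues with expansion and misses", {
  map <- load_fixture("orthology_groups")
  st <- make_studies("f1", "fly")
  st$n_reported <- 1L
  ms <- map_study(st[1], make_calls(st[1], "CG31196"), map)
  expect_equal(nrow(ms$calls), 1L)
  expect_equal(ms$n_distinct_worm, 2L)
  expect_equal(ms$calls$status, "mapped")

  sty <- make_studies("y1", "yeast")
  msy <- map_study(sty[1], make_calls(sty[1], c("POX1", "LOST1", "POX1")), map)
  expect_equal(nrow(msy$calls), 3L)
  expect_equal(sum(msy$calls$status == "unmapped"), 1L)
  expect_equal(msy$n_distinct_worm, 7L)

  # distinct count never exceeds calls x max worm group size
  max_worm <- max(table(map$members$group_id[map$members$species == "worm"]))
  expect_lte(msy$n_distinct_worm, nrow(msy$calls) * max_worm)

  # worm study maps to itself
  stw <- make_studies("w1", "worm")
  msw <- map_study(stw[1], make_calls(stw[1], "Y53C10A.12"), map)
  expect_equal(msw$calls$status, "direct")
  expect_equal(msw$calls$worm_orthologues[[1]], "Y53C10A.12")
})
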