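test_that("catalog integrates evidence and matches a brute-force union", {
  cat3 <- catalog_from_sets(list(A = c("g1", "g2"), B = c("g2", "g3"),
                                 C = "g3"))
  expect_equal(cat3$entries$gene, c("g1", "g2", "g3"))
  expect_equal(nrow(cat3$evidence), 5L)
  ov <- find_overlaps(cat3)
  expect_equal(lapply(seq_len(nrow(ov)), function(i) ov$genes[[i]]),
               list("g2", "g3"))
  expect_equal(ov$studies, list(c("A", "B"), c("B", "C")))

  # single study: k distinct mappable hits -> k entries, no overlaps
  cat1 <- catalog_from_sets(list(A = c("x", "y", "x")))
  expect_equal(nrow(cat1$entries), 2L)
  expect_equal(nrow(find_overlaps(cat1)), 0L)

  expect_error(find_overlaps(cat3, min_studies = 1L), ">= 2")
})

test_that("overlap detection matches the brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:12) {
    n_studies <- sample(3:6, 1)
    universe <- sprintf("G%02d.1", 1:30)
    sets <- lapply(seq_len(n_studies), function(i)
      sample(universe, sample(3:12, 1)))
    names(sets) <- sprintf("S%d", seq_len(n_studies))
    cat <- catalog_from_sets(sets)
    for (k in 2:3) {
      found <- sort(c(character(), unlist(find_overlaps(cat, min_studies = k)$genes)))
      expect_equal(found, brute_force_overlap(sets, k),
                   info = sprintf("rep %d k %d", rep, k))
    }
  }
})

test_that("overlaps are monotone in min_studies and under added studies", {
  set.seed(5)
  sets <- list(A = sprintf("g%d", 1:8), B = sprintf("g%d", 5:12),
               C = sprintf("g%d", c(1, 5, 9, 13)))
  cat <- catalog_from_sets(sets)
  ov2 <- sort(unlist(find_overlaps(cat, 2)$genes))
  ov3 <- sort(unlist(find_overlaps(cat, 3)$genes))
  expect_true(all(ov3 %in% ov2))
  # adding a study never removes an overlap
  cat_plus <- catalog_from_sets(c(sets, list(D = "g99")))
  ov2_plus <- sort(unlist(find_overlaps(cat_plus, 2)$genes))
  expect_true(all(ov2 %in% ov2_plus))
  # overlap entries are a subset of the catalog with >= 2 studies each
  expect_true(all(ov2 %in% cat$entries$gene))
  expect_true(all(find_overlaps(cat, 2)$n_studies >= 2L))
})

test_that("paralogue grouping merges identical-evidence entries only", {
  # two fly studies both reporting the 14-3-3 gene: worm pair merges
  map <- load_fixture("orthology_groups")
  studies <- make_studies(c("f1", "f2"), c("fly", "fly"))
  mapped <- lapply(1:2, function(i)
    map_study(studies[i], make_calls(studies[i], "CG31196"), map))
  cat <- integrate_catalog(studies, mapped)
  ov <- find_overlaps(cat)
  expect_equal(nrow(ov), 2L)
  grouped <- group_paralogue_entries(ov, cat)
  expect_equal(nrow(grouped), 1L)
  expect_equal(grouped$genes[[1]], c("F52D10.3", "M117.2"))
  expect_equal(attr(grouped, "n_merged"), 1L)

  # different evidence -> no merge: one worm gene also reported directly
  studies2 <- make_studies(c("f1", "f2", "w1"), c("fly", "fly", "worm"))
  mapped2 <- c(
    lapply(1:2, function(i)
      map_study(studies2[i], make_calls(studies2[i], "CG31196"), map)),
    list(map_study(studies2[3], make_calls(studies2[3], "F52D10.3"), map)))
  cat2 <- integrate_catalog(studies2, mapped2)
  grouped2 <- group_paralogue_entries(find_overlaps(cat2), cat2)
  expect_equal(nrow(grouped2), 2L)
  expect_equal(attr(grouped2, "n_merged"), 0L)
})

test_that("overlap tables round-trip through TSV", {
  map <- load_fixture("orthology_groups")
  studies <- make_studies(c("f1", "y1"), c("fly", "yeast"),
                          models = list("P", "S"))
  mapped <- list(
    map_study(studies[1], make_calls(studies[1], c("CG31196", "CG5009")), map),
    map_study(studies[2], make_calls(studies[2], "POX1"), map))
  cat <- integrate_catalog(studies, mapped)
  ov <- group_paralogue_entries(find_overlaps(cat), cat)
  path <- tempfile(fileext = ".tsv")
  write_overlap_table(ov, path)
  back <- read_overlap_table(path)
  expect_equal(back$genes, ov$genes)
  expect_equal(lapply(back$organisms, sort), lapply(ov$organisms, sort))
  expect_equal(lapply(back$disease_models, sort),
               lapply(ov$disease_models, sort))

  # empty overlap set -> header-only file that reads back empty
  empty <- find_overlaps(catalog_from_sets(list(A = "g1")))
  p2 <- tempfile(fileext = ".tsv")
  write_overlap_table(empty, p2)
  expect_equal(nrow(read_overlap_table(p2)), 0L)
})
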