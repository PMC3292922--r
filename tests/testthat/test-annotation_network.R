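vocab_file <- function() {
  path <- tempfile(fileext = ".txt")
  writeLines(c("Molecular chaperones", "Vesicular transport"), path)
  path
}

test_that("annotations load against the vocabulary; violations error", {
  ann_path <- write_tsv_fixture(c(
    "gene\tfunctional_class\tsource",
    "F26D10.3\tMolecular chaperones\tcurated",
    "C39F7.4\tVesicular transport\tcurated"))
  ann <- load_annotations(ann_path, vocab_file())
  expect_equal(nrow(ann), 2L)
  expect_equal(attr(ann, "vocabulary"),
               c("Molecular chaperones", "Vesicular transport"))

  bad <- write_tsv_fixture(c("gene\tfunctional_class",
                             "F26D10.3\tTeleportation"))
  expect_error(load_annotations(bad, vocab_file()), "Teleportation")

  empty <- load_annotations(write_tsv_fixture("gene\tfunctional_class"),
                            vocab_file())
  expect_equal(nrow(empty), 0L)
})

test_that("functional matrix marks exactly the witnessed (study, class) cells", {
  ann <- load_annotations(write_tsv_fixture(c(
    "gene\tfunctional_class",
    "g1\tMolecular chaperones",
    "g3\tVesicular transport")), vocab_file())
  cat <- catalog_from_sets(list(s1 = c("g1", "g2"), s2 = c("g2", "g3")))
  mat <- build_functional_matrix(cat, ann)
  expect_equal(dim(mat), c(2L, 2L))
  expect_true(mat["s1", "Molecular chaperones"])
  expect_false(mat["s1", "Vesicular transport"])
  expect_true(mat["s2", "Vesicular transport"])
  # reverse lookup: every TRUE cell has a witness gene
  for (s in rownames(mat)) for (cl in colnames(mat)) {
    witness <- intersect(cat$evidence$gene[cat$evidence$study_id == s],
                         ann$gene[ann$functional_class == cl])
    expect_equal(mat[s, cl], length(witness) > 0L)
  }
  # catalog with no annotated genes -> all-false
  mat0 <- build_functional_matrix(catalog_from_sets(list(s1 = "zz")), ann)
  expect_false(any(mat0))
})

test_that("expression flags normalize and default to unknown", {
  ov <- load_fixture("table2_overlaps")
  ove <- attach_expression(ov, fixture_path("expression"))
  expect_setequal(unique(ove$neuronal_expression), c("yes", "no", "unknown"))
  # curated tally: bli-3, phi-49 "No" plus one "No?"
  expect_equal(sum(ove$neuronal_expression == "no"), 3L)
  bli3 <- which(vapply(ove$genes, function(g) "F56C11.1" %in% g, TRUE))
  expect_equal(ove$neuronal_expression[bli3], "no")

  # absent gene -> unknown; bad value -> error
  tiny <- attach_expression(ov[1:2], data.frame(gene = "ZZ99.9",
                                                neuronal_expression = "yes"))
  expect_true(all(tiny$neuronal_expression == "unknown"))
  expect_error(
    attach_expression(ov[1:2], data.frame(gene = "a", neuronal_expression = "maybe")),
    "outside")
})

test_that("human orthologue attachment flags full coverage", {
  hmap <- load_fixture("human_orthologs")
  ov <- load_fixture("table2_overlaps")
  ovh <- attach_human_orthologues(ov, hmap)
  expect_true(attr(ovh, "all_have_human"))
  chn1 <- which(vapply(ovh$genes, function(g) "T09B4.10" %in% g, TRUE))
  expect_equal(ovh$human_orthologues[[chn1]], "CHIP")
  # entry absent from the map -> empty set, flag drops
  fake <- ov[1:2]
  fake$genes[[1]] <- "UNMAPPED.1"
  fakeh <- attach_human_orthologues(fake, hmap)
  expect_equal(lengths(fakeh$human_orthologues)[[1]], 0L)
  expect_false(attr(fakeh, "all_have_human"))
})

test_that("PPI graphs are simple, restrictable, and components match BFS", {
  path <- write_tsv_fixture(c(
    "protein_a\tprotein_b\tprovenance",
    "A\tB\tdb", "B\tC\tdb", "A\tB\tdup", "D\tD\tself", "E\tF\tdb"))
  expect_warning(g <- build_ppi_graph(path), "self-loop")
  expect_equal(igraph::gsize(g), 3L)     # dup collapsed, loop dropped
  expect_equal(sort(names(igraph::V(g))), c("A", "B", "C", "E", "F"))

  r <- suppressWarnings(build_ppi_graph(path, restrict_to = c("A", "B", "Z")))
  expect_lte(igraph::gsize(r), igraph::gsize(g))
  expect_equal(sort(names(igraph::V(r))), c("A", "B", "Z"))
  expect_equal(connected_component(r, "Z"), "Z")

  expect_equal(connected_component(g, "A"), c("A", "B", "C"))
  expect_error(connected_component(g, "Q"), "not in the graph")

  # random small graphs vs exhaustive reachability
  set.seed(9)
  for (rep in 1:8) {
    nodes <- LETTERS[1:8]
    edges <- t(replicate(10, sample(nodes, 2)))
    ef <- write_tsv_fixture(c("protein_a\tprotein_b",
                              apply(edges, 1, paste, collapse = "\t")))
    gg <- suppressWarnings(build_ppi_graph(ef))
    adj <- lapply(stats::setNames(nm = names(igraph::V(gg))), function(v)
      names(igraph::neighbors(gg, v)))
    bfs_reach <- function(start) {
      seen <- start; frontier <- start
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(adj[frontier])), seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      sort(seen)
    }
    seed_v <- sample(names(igraph::V(gg)), 1)
    expect_equal(connected_component(gg, seed_v), bfs_reach(seed_v))
    # component decomposition partitions the node set
    comps <- unique(lapply(names(igraph::V(gg)),
                           function(v) connected_component(gg, v)))
    expect_equal(sort(unlist(comps)), sort(names(igraph::V(gg))))
  }
})
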