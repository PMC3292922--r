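test_that("identical config and seed give byte-identical bundles", {
  cfg <- small_synth_config(seed = 7L)
  d1 <- file.path(tempfile(), "b1"); d2 <- file.path(tempfile(), "b2")
  generate_synthetic_dataset(cfg, d1)
  generate_synthetic_dataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # different seed changes the bundle
  d3 <- file.path(tempfile(), "b3")
  generate_synthetic_dataset(small_synth_config(seed = 8L), d3)
  expect_false(identical(readLines(file.path(d1, "groups.txt")),
                         readLines(file.path(d3, "groups.txt"))))
})

test_that("perfect-information bundles are recovered exactly by the pipeline", {
  cfg <- small_synth_config(seed = 11L)
  dir <- tempfile()
  truth <- generate_synthetic_dataset(cfg, dir)
  res <- run_full_pipeline(file.path(dir, "studies.tsv"),
                           file.path(dir, "genes"),
                           groups_path = file.path(dir, "groups.txt"),
                           aliases_path = file.path(dir, "aliases.tsv"))
  rec <- evaluate_recovery(truth, res$overlaps, res$catalog,
                           run_id = res$summary$run_id)
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
  expect_equal(rec$catalog_delta, 0L)
  # stage conservation: raw = mapped + unmapped; catalog = truth distinct
  expect_equal(res$summary$n_calls,
               res$summary$n_mapped + res$summary$n_unmapped)
  expect_equal(res$summary$n_distinct, truth$n_distinct_total)
  expect_equal(res$summary$n_distinct,
               length(unique(unlist(truth$study_worm_sets))))
  # planted paralogue pairs came back merged
  expect_true(all(vapply(truth$paralogue_groups, function(pg)
    any(vapply(res$overlaps$genes, identical, TRUE, pg)), TRUE)))
  # per-study distinct counts agree with the manifest
  got <- vapply(res$mapped, function(m) m$n_distinct_worm, 0L)
  expect_equal(got, truth$per_study$n_distinct_worm)

  # run-id mismatch is an error
  expect_error(evaluate_recovery(truth, res$overlaps, run_id = "other"),
               "mismatch")
})

test_that("zero coverage with non-worm studies maps nothing", {
  cfg <- small_synth_config(n_studies = c(worm = 0L, yeast = 2L, fly = 2L),
                            orthology_coverage = 0, n_planted_shared = 0L,
                            paralogue_pair_rate = 0, seed = 3L)
  dir <- tempfile()
  generate_synthetic_dataset(cfg, dir)
  res <- run_full_pipeline(file.path(dir, "studies.tsv"),
                           file.path(dir, "genes"),
                           groups_path = file.path(dir, "groups.txt"),
                           aliases_path = file.path(dir, "aliases.tsv"))
  expect_equal(res$summary$n_mapped, 0L)
  expect_equal(res$summary$n_distinct, 0L)
  expect_equal(res$summary$n_overlaps, 0L)
})

test_that("infeasible planting errors before writing files", {
  cfg <- small_synth_config(n_studies = c(worm = 2L, yeast = 0L, fly = 0L),
                            hits_range = c(1L, 2L), n_planted_shared = 20L,
                            paralogue_pair_rate = 0, seed = 1L)
  dir <- tempfile()
  expect_error(generate_synthetic_dataset(cfg, dir), "infeasible|capacity")
  expect_false(dir.exists(dir))
})

test_that("empty planted set reports vacuous recovery", {
  cfg <- small_synth_config(n_planted_shared = 0L, paralogue_pair_rate = 0,
                            disjoint_background = TRUE, seed = 2L)
  truth <- generate_synthetic_dataset(cfg, NULL)
  empty_ov <- find_overlaps(catalog_from_sets(list(A = "g1")))
  rec <- evaluate_recovery(truth, empty_ov)
  expect_true(rec$vacuous)
  expect_equal(rec$recall, 1)
})

test_that("recovery recall is non-increasing in expectation as coverage drops", {
  mean_recall <- function(coverage, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- small_synth_config(n_studies = c(worm = 0L, yeast = 2L, fly = 2L),
                                orthology_coverage = coverage,
                                n_planted_shared = 0L,
                                paralogue_pair_rate = 0,
                                disjoint_background = FALSE, seed = s)
      truth <- generate_synthetic_dataset(cfg, NULL)
      # recall proxy: fraction of non-worm calls that mapped
      n_map <- sum(vapply(truth$study_worm_sets, length, 0L))
      n_hit <- sum(truth$per_study$n_hits)
      n_map / max(n_hit, 1L)
    }, 0))
  }
  seeds <- 1:20
  r_hi <- mean_recall(1.0, seeds)
  r_mid <- mean_recall(0.5, seeds)
  r_lo <- mean_recall(0.1, seeds)
  expect_gte(r_hi, r_mid)
  expect_gte(r_mid, r_lo)
})
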