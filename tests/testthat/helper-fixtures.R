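# Shared helpers: tiny in-code fixtures written to tempfiles, and a small
# study-set constructor used by several modules' tests.

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Minimal study table built in code (bypasses file parsing) for tests that
# need Study rows but are not about the reader.
make_studies <- function(ids, organisms, models = NULL) {
  n <- length(ids)
  if (is.null(models)) models <- rep(list("P"), n)
  out <- data.table::data.table(
    study_id = ids, organism = organisms, disease_models = models,
    construct = "c", screen_type = "s", n_reported = NA_integer_,
    n_orthologues_expected = NA_integer_, reference = "r")
  data.table::setattr(out, "class", c("study_table", class(out)))
  out
}

make_calls <- function(study, raw_ids, effect = "unknown") {
  data.table::data.table(
    study_id = study$study_id, raw_id = raw_ids, species = study$organism,
    effect = rep_len(effect, length(raw_ids)), note = "")
}

# Build a catalog directly from named per-study worm gene sets (all worm
# studies, direct mapping); the workhorse for overlap-logic tests.
catalog_from_sets <- function(sets) {
  studies <- make_studies(names(sets), rep("worm", length(sets)))
  empty_map <- read_pairwise_orthologs(write_tsv_fixture(
    "source_species\tsource_id\ttarget_species\ttarget_id\tevidence"))
  mapped <- lapply(seq_along(sets), function(i) {
    st <- studies[i]
    st$n_reported <- length(sets[[i]])
    map_study(st, make_calls(st, sets[[i]]), empty_map)
  })
  integrate_catalog(studies, mapped)
}

# Independent brute-force oracle: genes present in >= k of the given sets.
brute_force_overlap <- function(sets, k = 2L) {
  genes <- unique(unlist(sets))
  hit <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, TRUE)), 0L)
  sort(unname(genes[hit >= k]))
}

small_synth_config <- function(...) {
  args <- utils::modifyList(list(
    n_studies = c(worm = 3L, yeast = 2L, fly = 2L),
    universe_sizes = c(worm = 200L, yeast = 100L, fly = 100L),
    hits_range = c(5L, 20L),
    orthology_coverage = 1.0,
    one_to_many_rate = 0,
    n_planted_shared = 5L,
    planted_multiplicity = c(2L, 3L),
    paralogue_pair_rate = 0.2,
    disjoint_background = TRUE,
    seed = 42L), list(...))
  do.call(synthetic_config, args)
}
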