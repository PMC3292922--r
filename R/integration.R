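# Integration: deduplicated reference-space regulator catalog and
# cross-study overlap detection.
#
# The unit of analysis is the worm gene. Every mapped call contributes one
# evidence record per worm orthologue it reaches; the catalog is the union
# over studies; an overlap entry is a worm gene (or, after explicit
# grouping, a paralogue set with identical evidence) attributed to at least
# `min_studies` distinct publications. "More than one study" counts
# publications, even when both used the same disease model in one species.

#' Build the regulator catalog
#'
#' Collapses per-study mapped hit lists into one entry per distinct worm
#' gene, each carrying its full evidence trail: which study reported it,
#' through which source gene, with what effect direction. Effect direction
#' is carried but plays no role in overlap membership.
#'
#' @param studies A \code{study_table}.
#' @param mapped A list of \code{mapped_study} objects (one per study, any
#'   order).
#' @return An object of class \code{regulator_catalog}: \code{entries}
#'   (a \code{data.table} with \code{gene}, \code{display_name},
#'   \code{n_studies} and list columns \code{studies}, \code{organisms},
#'   \code{disease_models}), \code{evidence} (one row per
#'   (worm gene, study, source gene, effect) attribution) and
#'   \code{unmapped} (the calls that reached no worm gene).
#' @details Invariant: the number of evidence records equals the total
#'   number of (call, worm orthologue) attributions with non-empty mapping;
#'   entry count never exceeds the sum of per-study distinct counts.
#' @export
integrate_catalog <- function(studies, mapped) {
  stopifnot(all(vapply(mapped, inherits, TRUE, "mapped_study")))
  sdt <- unclass_study_table(studies)
  ev_list <- lapply(mapped, function(ms) {
    calls <- ms$calls[ms$calls$status != "unmapped"]
    if (!nrow(calls)) return(NULL)
    n_orth <- lengths(calls$worm_orthologues)
    data.table::data.table(
      gene = unlist(calls$worm_orthologues, use.names = FALSE),
      study_id = rep(calls$study_id, n_orth),
      source_species = rep(calls$species, n_orth),
      source_value = rep(calls$source_value, n_orth),
      source_display = rep(calls$display_name, n_orth),
      effect = rep(calls$effect, n_orth))
  })
  evidence <- data.table::rbindlist(Filter(Negate(is.null), ev_list))
  if (!nrow(evidence)) {
    evidence <- data.table::data.table(
      gene = character(), study_id = character(), source_species = character(),
      source_value = character(), source_display = character(),
      effect = character())
  }
  evidence <- unique(evidence)
  study_meta <- sdt[, .(study_id, organism, disease_models)]
  ev_meta <- merge(evidence, study_meta, by = "study_id", all.x = TRUE,
                   sort = FALSE)
  if (nrow(ev_meta)) {
    entries <- ev_meta[, .(
      studies = list(sort(unique(study_id))),
      organisms = list(sort(unique(organism))),
      disease_models = list(sort(unique(unlist(disease_models)))),
      display_name = {
        dn <- source_display[source_species == REFERENCE_SPECIES & !is.na(source_display)]
        if (length(dn)) dn[1L] else NA_character_
      },
      n_studies = data.table::uniqueN(study_id)), by = gene]
    data.table::setorderv(entries, "gene")
  } else {
    entries <- data.table::data.table(
      gene = character(), studies = list(), organisms = list(),
      disease_models = list(), display_name = character(),
      n_studies = integer())
  }
  unmapped <- data.table::rbindlist(
    lapply(mapped, function(ms) ms$calls[ms$calls$status == "unmapped",
                                         !"worm_orthologues"]),
    fill = TRUE)
  structure(list(entries = entries, evidence = evidence, unmapped = unmapped,
                 provenance = list(n_studies = nrow(sdt),
                                   built = "integrate_catalog")),
            class = "regulator_catalog")
}

#' @export
print.regulator_catalog <- function(x, ...) {
  cat("<regulator_catalog> ", nrow(x$entries), " distinct worm genes, ",
      nrow(x$evidence), " evidence records, ",
      nrow(x$unmapped), " unmapped calls\n", sep = "")
  invisible(x)
}

#' Detect cross-study overlapping regulators
#'
#' Returns catalog entries attributed to at least \code{min_studies}
#' distinct studies, one entry per worm gene (use
#' [group_paralogue_entries()] afterwards to merge joint-orthologue sets).
#' Entries are sorted by decreasing study count, then gene identifier.
#'
#' @param catalog A \code{regulator_catalog}.
#' @param min_studies Minimum number of distinct studies; must be >= 2.
#' @return A \code{data.table} of class \code{overlap_set} with list column
#'   \code{genes} (singleton sets before grouping), \code{display_names},
#'   \code{studies}, \code{organisms}, \code{disease_models} and
#'   \code{n_studies}.
#' @export
find_overlaps <- function(catalog, min_studies = 2L) {
  stopifnot(inherits(catalog, "regulator_catalog"))
  if (min_studies < 2L) {
    stop("min_studies must be >= 2 (an overlap needs at least two studies)",
         call. = FALSE)
  }
  e <- catalog$entries[catalog$entries$n_studies >= min_studies]
  out <- data.table::data.table(
    genes = lapply(e$gene, identity),
    display_names = lapply(e$display_name, function(d) d[!is.na(d)]),
    studies = e$studies,
    organisms = e$organisms,
    disease_models = e$disease_models,
    n_studies = e$n_studies)
  out <- out[order(-n_studies, vapply(genes, `[`, "", 1L))]
  data.table::setattr(out, "class", c("overlap_set", class(out)))
  out
}

# Evidence signature of one worm gene: the sorted set of
# (study, source species, source gene) attributions behind it.
evidence_signature <- function(catalog, query_gene) {
  keep <- catalog$evidence$gene == query_gene
  ev <- unique(catalog$evidence[keep, .(study_id, source_species, source_value)])
  paste(sort(paste(ev$study_id, ev$source_species, ev$source_value, sep = "\r")),
        collapse = "\n")
}

#' Merge paralogue overlap entries with identical evidence
#'
#' Two (or more) worm genes that are joint orthologues of the same source
#' gene(s) in the same studies — e.g. one fly 14-3-3 gene expanding to two
#' worm paralogues — carry exactly the same evidence and are merged into one
#' multi-gene overlap entry. Entries with any difference in their
#' (study, source gene) evidence are left alone.
#'
#' @param overlaps An \code{overlap_set} from [find_overlaps()].
#' @param catalog The \code{regulator_catalog} the overlaps came from.
#' @return An \code{overlap_set} with merged entries; sort order as in
#'   [find_overlaps()]. Attribute \code{n_merged} counts entries absorbed
#'   into another.
#' @export
group_paralogue_entries <- function(overlaps, catalog) {
  stopifnot(inherits(overlaps, "overlap_set"),
            inherits(catalog, "regulator_catalog"))
  if (!nrow(overlaps)) {
    data.table::setattr(overlaps, "n_merged", 0L)
    return(overlaps)
  }
  gene1 <- vapply(overlaps$genes, `[`, "", 1L)
  sig <- vapply(gene1, function(g) evidence_signature(catalog, g), "")
  grp <- match(sig, sig)  # first index with the same signature
  merged <- data.table::rbindlist(lapply(unique(grp), function(i) {
    idx <- which(grp == i)
    data.table::data.table(
      genes = list(sort(unlist(overlaps$genes[idx]))),
      display_names = list(sort(unique(unlist(overlaps$display_names[idx])))),
      studies = list(sort(unique(unlist(overlaps$studies[idx])))),
      organisms = list(sort(unique(unlist(overlaps$organisms[idx])))),
      disease_models = list(sort(unique(unlist(overlaps$disease_models[idx])))),
      n_studies = overlaps$n_studies[idx[1L]])
  }))
  merged <- merged[order(-n_studies, vapply(genes, `[`, "", 1L))]
  data.table::setattr(merged, "class", c("overlap_set", class(merged)))
  data.table::setattr(merged, "n_merged", nrow(overlaps) - nrow(merged))
  merged
}

#' Write an overlap table
#'
#' Renders overlap entries as a deterministic TSV: one row per entry,
#' multi-gene entries with comma-joined identifiers, set-valued columns
#' comma-joined in sorted order.
#'
#' @param overlaps An \code{overlap_set} (possibly annotated by
#'   [attach_expression()] / [load_annotations()] companions; a
#'   \code{description} or \code{neuronal_expression} column is used when
#'   present).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_overlap_table <- function(overlaps, path) {
  n <- nrow(overlaps)
  out <- data.table::data.table(
    sequence_names = join_set(overlaps$genes),
    gene_names = join_set(overlaps$display_names),
    description = if ("description" %in% names(overlaps)) overlaps$description
                  else rep("", n),
    organisms = join_set(overlaps$organisms),
    disease_models = join_set(overlaps$disease_models),
    neuronal_expression = if ("neuronal_expression" %in% names(overlaps))
      overlaps$neuronal_expression else rep("", n))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an overlap table
#'
#' Inverse of [write_overlap_table()]; also the loader for the curated
#' overlap fixture. Set-valued cells are split on commas; organisms are
#' case-folded; disease models are validated against the five-code
#' vocabulary.
#'
#' @param path TSV as written by [write_overlap_table()], optionally with
#'   \code{provenance}.
#' @return An \code{overlap_set} (with \code{description},
#'   \code{neuronal_expression} columns carried through).
#' @export
read_overlap_table <- function(path) {
  dt <- read_tsv_commented(path)
  assert_columns(dt, c("sequence_names", "gene_names", "organisms",
                       "disease_models"), path)
  norm_genes <- lapply(split_set(dt$sequence_names), function(g) {
    if (!length(g)) return(character())
    sort(normalize_gene_id(g, "worm")$value)
  })
  models <- lapply(split_set(dt$disease_models), function(m) {
    m[m %in% c("Ab", "Abeta", "A-beta", "Aβ")] <- "Abeta"
    bad <- setdiff(m, DISEASE_MODEL_CODES)
    if (length(bad)) stop("unknown disease-model code: ", bad[1L], call. = FALSE)
    sort(m)
  })
  n <- nrow(dt)
  out <- data.table::data.table(
    genes = norm_genes,
    display_names = lapply(split_set(dt$gene_names), function(x)
      sort(setdiff(x, "-"))),
    studies = rep(list(character()), n),
    organisms = lapply(split_set(dt$organisms), function(o) sort(tolower(o))),
    disease_models = models,
    n_studies = rep(NA_integer_, n),
    description = if ("description" %in% names(dt)) dt$description
                  else rep("", n),
    neuronal_expression = if ("neuronal_expression" %in% names(dt))
      dt$neuronal_expression else rep("", n))
  data.table::setattr(out, "class", c("overlap_set", class(out)))
  out
}

#' Write the regulator catalog as TSV
#'
#' @param catalog A \code{regulator_catalog}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_catalog_table <- function(catalog, path) {
  e <- catalog$entries
  out <- data.table::data.table(
    gene = e$gene,
    display_name = ifelse(is.na(e$display_name), "", e$display_name),
    studies = join_set(e$studies),
    organisms = join_set(e$organisms),
    disease_models = join_set(e$disease_models),
    n_studies = e$n_studies)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
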