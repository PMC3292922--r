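# Orthology maps and reference-space projection.
#
# Orthology relations are consumed, never inferred: maps come from
# OrthoMCL-style group files and/or pairwise ortholog tables, and every
# source-species gene is projected onto the set of its C. elegans
# orthologues. One-to-many relations are fully expanded (one fly 14-3-3 gene
# can legitimately map to two worm genes), which is why a study's distinct
# orthologue count can exceed its hit count.

DEFAULT_SPECIES_PREFIXES <- c(cel = "worm", sce = "yeast", dme = "fly",
                              hsa = "human")

new_orthology_map <- function(members, dialect) {
  # members: data.table(group_id, species, value)
  members <- unique(members)
  data.table::setkeyv(members, c("species", "value"))
  structure(list(members = members, dialect = dialect),
            class = "orthology_map")
}

#' Read an OrthoMCL-style groups file
#'
#' Each line is \code{"GROUPID: prefix|gene prefix|gene ..."}; prefixes map
#' to species codes (defaults: \code{cel} worm, \code{sce} yeast, \code{dme}
#' fly, \code{hsa} human). Member identifiers pass through
#' [normalize_gene_id()].
#'
#' @param path Path to the groups file. \code{#} lines are comments.
#' @param species_prefixes Named character vector, prefix to species code.
#' @param aliases Optional \code{alias_table} applied to members.
#' @param strip_isoform Passed to [normalize_gene_id()].
#' @return An \code{orthology_map}. Attributes \code{n_skipped_members} and
#'   \code{n_skipped_groups} count members with unknown prefixes and groups
#'   left empty after skipping (each class raises one summary warning).
#' @details A line without a colon is a hard error reported with its line
#'   number.
#' @export
read_orthomcl_groups <- function(path, species_prefixes = DEFAULT_SPECIES_PREFIXES,
                                 aliases = empty_alias_table(),
                                 strip_isoform = TRUE) {
  assert_file(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    map <- new_orthology_map(
      data.table::data.table(group_id = character(), species = character(),
                             value = character()),
      dialect = "orthomcl-groups")
    data.table::setattr(map, "n_skipped_members", 0L)
    data.table::setattr(map, "n_skipped_groups", 0L)
    return(map)
  }
  no_colon <- !grepl(":", lines, fixed = TRUE)
  if (any(no_colon)) {
    stop("malformed groups line (no ':') at line ", which(no_colon)[1L],
         ": '", lines[which(no_colon)[1L]], "'", call. = FALSE)
  }
  group_id <- trimws(sub(":.*$", "", lines))
  body <- trimws(sub("^[^:]*:", "", lines))
  tokens <- strsplit(body, "\\s+")
  n_tok <- lengths(tokens)
  memb <- data.table::data.table(
    group_id = rep(group_id, n_tok),
    token = unlist(tokens, use.names = FALSE))
  memb <- memb[nzchar(token)]
  memb[, prefix := sub("\\|.*$", "", token)]
  memb[, raw := sub("^[^|]*\\|", "", token)]
  known <- memb$prefix %in% names(species_prefixes) & memb$prefix != memb$token
  n_skipped_members <- sum(!known)
  if (n_skipped_members) {
    warning(n_skipped_members, " group member(s) with unknown species prefix skipped",
            call. = FALSE)
  }
  memb <- memb[known]
  if (nrow(memb)) {
    norm <- normalize_gene_id(memb$raw, unname(species_prefixes[memb$prefix]),
                              aliases, strip_isoform = strip_isoform)
    members <- data.table::data.table(group_id = memb$group_id,
                                      species = norm$species,
                                      value = norm$value)
  } else {
    members <- data.table::data.table(group_id = character(),
                                      species = character(),
                                      value = character())
  }
  n_skipped_groups <- length(setdiff(group_id, members$group_id))
  if (n_skipped_groups) {
    warning(n_skipped_groups, " empty group(s) skipped", call. = FALSE)
  }
  map <- new_orthology_map(members, dialect = "orthomcl-groups")
  data.table::setattr(map, "n_skipped_members", n_skipped_members)
  data.table::setattr(map, "n_skipped_groups", n_skipped_groups)
  map
}

#' Read a pairwise ortholog table
#'
#' Each row declares one cross-species ortholog pair and becomes a
#' two-member group; repeated source genes accumulate, so one-to-many
#' relations are expressed as multiple rows.
#'
#' @param path TSV with columns \code{source_species}, \code{source_id},
#'   \code{target_species}, \code{target_id} and optionally \code{evidence}.
#' @param aliases Optional \code{alias_table}.
#' @param strip_isoform Passed to [normalize_gene_id()].
#' @return An \code{orthology_map}.
#' @details A row with \code{source_species == target_species} is a hard
#'   error: within-species paralogy is not accepted through this file.
#' @export
read_pairwise_orthologs <- function(path, aliases = empty_alias_table(),
                                    strip_isoform = TRUE) {
  dt <- read_tsv_commented(path)
  if (!length(names(dt)) || !nrow(dt)) {
    return(new_orthology_map(
      data.table::data.table(group_id = character(), species = character(),
                             value = character()),
      dialect = "pairwise"))
  }
  assert_columns(dt, c("source_species", "source_id", "target_species",
                       "target_id"), path)
  dt[, source_species := tolower(trimws(source_species))]
  dt[, target_species := tolower(trimws(target_species))]
  assert_species(c(dt$source_species, dt$target_species))
  same <- which(dt$source_species == dt$target_species)
  if (length(same)) {
    stop("pairwise ortholog row ", same[1L],
         " relates a species to itself (", dt$source_species[same[1L]],
         "); paralogy is not accepted here", call. = FALSE)
  }
  src <- normalize_gene_id(dt$source_id, dt$source_species, aliases, strip_isoform)
  tgt <- normalize_gene_id(dt$target_id, dt$target_species, aliases, strip_isoform)
  gid <- sprintf("pair_%06d", seq_len(nrow(dt)))
  members <- data.table::data.table(
    group_id = rep(gid, 2L),
    species = c(src$species, tgt$species),
    value = c(src$value, tgt$value))
  new_orthology_map(members, dialect = "pairwise")
}

#' Merge orthology maps
#'
#' Union semantics: a gene's orthologue set under the merged map is the
#' union of its sets under the inputs, with no confidence weighting and no
#' duplicated answers.
#'
#' @param ... \code{orthology_map} objects.
#' @return A single merged \code{orthology_map}.
#' @export
merge_orthology_maps <- function(...) {
  maps <- Filter(Negate(is.null), list(...))
  stopifnot(all(vapply(maps, inherits, TRUE, "orthology_map")))
  if (length(maps) == 1L) return(maps[[1L]])
  tabs <- lapply(seq_along(maps), function(i) {
    m <- data.table::copy(maps[[i]]$members)
    m[, group_id := paste0("m", i, "_", group_id)]
    m
  })
  new_orthology_map(data.table::rbindlist(tabs),
                    dialect = paste(vapply(maps, function(m) m$dialect, ""),
                                    collapse = "+"))
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("<orthology_map> ", data.table::uniqueN(x$members$group_id), " groups, ",
      nrow(x$members), " memberships (", x$dialect, ")\n", sep = "")
  invisible(x)
}

#' Number of distinct genes reachable for one species
#'
#' Counts the distinct reference-species genes an orthology map can reach;
#' used as the default discovery universe for the overlap null model.
#'
#' @param map An \code{orthology_map}.
#' @param species Species code, default the reference species (worm).
#' @return Integer count.
#' @export
map_universe_size <- function(map, species = REFERENCE_SPECIES) {
  stopifnot(inherits(map, "orthology_map"))
  m <- map$members
  data.table::uniqueN(m$value[m$species == species])
}

#' Project genes onto another species
#'
#' Returns, for one query gene, all \code{target_species} members of all
#' groups containing the query, sorted lexicographically. A reference-species
#' query projected onto the reference species returns itself only (identity:
#' worm genes never expand to worm paralogues through the map). An absent
#' gene returns the empty set.
#'
#' @param map An \code{orthology_map}.
#' @param species,value Namespace and canonical value of the query gene
#'   (already normalized).
#' @param target_species Species to project onto; default worm.
#' @return Sorted character vector of canonical identifiers in
#'   \code{target_species}.
#' @export
orthologues <- function(map, species, value, target_species = REFERENCE_SPECIES) {
  stopifnot(inherits(map, "orthology_map"), length(species) == 1L,
            length(value) == 1L)
  assert_species(species)
  if (species == target_species) {
    if (species == REFERENCE_SPECIES) return(value)
    # same-species projection other than reference identity: group co-members
  }
  m <- map$members
  # plain-vector query to dodge column-name capture in join scope
  q <- data.table::data.table(qs = species, qv = value)
  gids <- unique(m[q, on = c(species = "qs", value = "qv"),
                   nomatch = NULL]$group_id)
  if (!length(gids)) return(character())
  hits <- m[m$group_id %in% gids & m$species == target_species]
  out <- setdiff(unique(hits$value), if (species == target_species) value else character())
  sort(out)
}

#' Worm orthologue set of a gene
#'
#' Convenience wrapper for [orthologues()] with the reference species as the
#' target.
#'
#' @inheritParams orthologues
#' @return Sorted character vector of worm gene identifiers.
#' @export
worm_orthologues <- function(map, species, value) {
  orthologues(map, species, value, target_species = REFERENCE_SPECIES)
}

#' Project one study's hit list onto the reference space
#'
#' Normalizes every raw call and resolves its worm orthologue set. Worm
#' calls map to themselves (\code{status = "direct"}); non-worm calls map
#' through the orthology map (\code{"mapped"}) or fail to (\code{"unmapped"},
#' empty set). Every call yields exactly one mapped record; the study's
#' distinct-orthologue count is the size of the union of all worm sets, which
#' can exceed the call count (one-to-many) or fall below it (unmapped or
#' convergent mapping).
#'
#' @param study Single-row \code{study_table} subset.
#' @param calls Hit list from [read_gene_list()] for this study.
#' @param map An \code{orthology_map}.
#' @param aliases An \code{alias_table}.
#' @param strip_isoform Passed to [normalize_gene_id()].
#' @return A list of class \code{mapped_study}: \code{calls} (a
#'   \code{data.table} with \code{study_id}, \code{raw_id}, \code{species},
#'   \code{source_value}, \code{display_name}, \code{effect},
#'   \code{status}, and list column \code{worm_orthologues}),
#'   \code{n_distinct_worm} (the union size) and \code{study_id}.
#' @export
map_study <- function(study, calls, map, aliases = empty_alias_table(),
                      strip_isoform = TRUE) {
  stopifnot(nrow(study) == 1L)
  if (nrow(calls) && !all(calls$study_id == study$study_id)) {
    stop("calls do not belong to study ", study$study_id, call. = FALSE)
  }
  if (!nrow(calls)) {
    out <- data.table::data.table(
      study_id = character(), raw_id = character(), species = character(),
      source_value = character(), display_name = character(),
      effect = character(), status = character(),
      worm_orthologues = list())
    return(structure(list(calls = out, n_distinct_worm = 0L,
                          study_id = study$study_id), class = "mapped_study"))
  }
  norm <- normalize_gene_id(calls$raw_id, calls$species, aliases, strip_isoform)
  worm_sets <- vector("list", nrow(calls))
  status <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (norm$species[i] == REFERENCE_SPECIES) {
      worm_sets[[i]] <- norm$value[i]
      status[i] <- "direct"
    } else {
      w <- worm_orthologues(map, norm$species[i], norm$value[i])
      worm_sets[[i]] <- w
      status[i] <- if (length(w)) "mapped" else "unmapped"
    }
  }
  out <- data.table::data.table(
    study_id = calls$study_id,
    raw_id = calls$raw_id,
    species = norm$species,
    source_value = norm$value,
    display_name = norm$display_name,
    effect = calls$effect,
    status = status,
    worm_orthologues = worm_sets)
  structure(list(calls = out,
                 n_distinct_worm = length(unique(unlist(worm_sets))),
                 study_id = study$study_id),
            class = "mapped_study")
}

#' @export
print.mapped_study <- function(x, ...) {
  cat("<mapped_study> ", x$study_id, ": ", nrow(x$calls), " calls, ",
      sum(x$calls$status == "unmapped"), " unmapped, ",
      x$n_distinct_worm, " distinct worm orthologues\n", sep = "")
  invisible(x)
}
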