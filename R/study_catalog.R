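# Study catalog: the screen-level metadata table (one row per published
# screen) and per-study hit lists in native identifiers.

STUDY_COLUMNS <- c("study_id", "organism", "disease_models", "construct",
                   "screen_type", "n_reported", "n_orthologues_expected",
                   "reference")

#' Read the study catalog
#'
#' Loads the catalog of published modifier screens: one row per study with
#' the organism, the disease model codes, the screen type, the number of
#' genetic modifiers the study reported, and (for non-worm studies mapped by
#' curation) the expected number of C. elegans orthologues.
#'
#' Disease models are a closed five-code vocabulary: \code{P} (polyglutamine:
#' huntingtin fragments and SCA constructs), \code{S} (alpha-synuclein),
#' \code{T} (tau), \code{SOD} (mutant SOD1), \code{Abeta} (amyloid-beta
#' 1-42). A cell may carry several codes separated by commas or \code{"and"}
#' (\code{"P and S"} parses to both codes); a study with several models is
#' still one study for overlap counting.
#'
#' @param path TSV with columns \code{study_id}, \code{organism},
#'   \code{disease_models}, \code{construct}, \code{screen_type},
#'   \code{n_reported}, \code{n_orthologues_expected}, \code{reference}.
#'   \code{#} lines are comments.
#' @return A \code{data.table} of class \code{study_table}, one row per
#'   study, in file order. \code{disease_models} is a list column of code
#'   vectors; counts are integers (\code{n_orthologues_expected} may be
#'   \code{NA} when absent).
#' @details Hard errors: a missing or renamed required column (named in the
#'   message), a duplicated \code{study_id}, an unparseable count (with its
#'   row number), an empty disease-model cell, or a code outside the
#'   vocabulary.
#' @export
read_study_table <- function(path) {
  dt <- read_tsv_commented(path)
  if (!length(names(dt))) stop("empty study table file: ", path, call. = FALSE)
  assert_columns(dt, STUDY_COLUMNS, path)
  if (!nrow(dt)) {
    out <- data.table::data.table(
      study_id = character(), organism = character(),
      disease_models = list(), construct = character(),
      screen_type = character(), n_reported = integer(),
      n_orthologues_expected = integer(), reference = character())
    data.table::setattr(out, "class", c("study_table", class(out)))
    return(out)
  }
  dt[, study_id := trimws(study_id)]
  if (anyDuplicated(dt$study_id)) {
    stop("duplicate study_id: ",
         paste(unique(dt$study_id[duplicated(dt$study_id)]), collapse = ", "),
         call. = FALSE)
  }
  dt[, organism := tolower(trimws(organism))]
  bad_org <- setdiff(unique(dt$organism), c("worm", "yeast", "fly"))
  if (length(bad_org)) {
    stop("unknown organism(s) in ", path, ": ", paste(bad_org, collapse = ", "),
         call. = FALSE)
  }
  parse_count <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.integer(x))
    bad <- which(nzchar(x) & (is.na(out) | out < 0L))
    if (length(bad)) {
      stop("unparseable ", col, " at row ", bad[1L], ": '", x[bad[1L]], "'",
           call. = FALSE)
    }
    out[!nzchar(x)] <- NA_integer_
    out
  }
  n_rep <- parse_count(dt$n_reported, "n_reported")
  if (anyNA(n_rep)) {
    stop("missing n_reported at row ", which(is.na(n_rep))[1L], call. = FALSE)
  }
  models <- split_set(dt$disease_models)
  models <- lapply(models, function(m) {
    m[m %in% c("Ab", "Abeta", "A-beta", "Aβ")] <- "Abeta"
    m
  })
  bad_code <- lapply(models, setdiff, DISEASE_MODEL_CODES)
  bad_row <- which(vapply(bad_code, length, 0L) > 0L)
  if (length(bad_row)) {
    stop("unknown disease-model code(s) at row ", bad_row[1L], ": ",
         paste(bad_code[[bad_row[1L]]], collapse = ", "), call. = FALSE)
  }
  empty <- which(vapply(models, length, 0L) == 0L)
  if (length(empty)) {
    stop("empty disease-model cell at row ", empty[1L], call. = FALSE)
  }
  out <- data.table::data.table(
    study_id = dt$study_id,
    organism = dt$organism,
    disease_models = models,
    construct = dt$construct,
    screen_type = dt$screen_type,
    n_reported = n_rep,
    n_orthologues_expected = parse_count(dt$n_orthologues_expected,
                                         "n_orthologues_expected"),
    reference = dt$reference)
  data.table::setattr(out, "class", c("study_table", class(out)))
  out
}

#' Write a study catalog back to TSV
#'
#' Inverse of [read_study_table()]: re-reading the written file yields an
#' identical record set.
#'
#' @param studies A \code{study_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_study_table <- function(studies, path) {
  out <- data.table::as.data.table(unclass_study_table(studies))
  out[, disease_models := join_set(studies$disease_models)]
  out[, n_orthologues_expected :=
        ifelse(is.na(n_orthologues_expected), "", as.character(n_orthologues_expected))]
  data.table::fwrite(out[, STUDY_COLUMNS, with = FALSE], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

unclass_study_table <- function(studies) {
  out <- data.table::copy(studies)
  data.table::setattr(out, "class", c("data.table", "data.frame"))
  out
}

#' Read one study's hit list
#'
#' Loads the curated list of modifier genes one study reported, in that
#' organism's native identifiers, exactly as curated: duplicates are kept
#' (deduplication happens at integration) and row order is preserved.
#'
#' @param path TSV with column \code{raw_id} and optional columns
#'   \code{effect} (\code{suppressor}/\code{enhancer}/\code{modifier}/
#'   \code{unknown}), \code{note} and \code{species}.
#' @param study A single-row subset of a \code{study_table}, used to stamp
#'   the species and cross-check the record count.
#' @return A \code{data.table} with columns \code{study_id}, \code{raw_id},
#'   \code{species}, \code{effect}, \code{note}. Attribute
#'   \code{n_skipped} counts rows dropped for a blank \code{raw_id} (each
#'   dropped row raises a warning).
#' @details A \code{species} column that contradicts the study's organism is
#'   a hard error. A record count differing from the study's
#'   \code{n_reported} raises a warning, not an error: catalog counts and
#'   supplementary lists are known to disagree in curated data.
#' @export
read_gene_list <- function(path, study) {
  stopifnot(nrow(study) == 1L)
  dt <- read_tsv_commented(path)
  if (!length(names(dt))) {
    dt <- data.table::data.table(raw_id = character())
  }
  assert_columns(dt, "raw_id", path)
  if ("species" %in% names(dt) && nrow(dt)) {
    sp <- tolower(trimws(dt$species))
    conflict <- which(nzchar(sp) & sp != study$organism)
    if (length(conflict)) {
      stop("species column conflicts with study organism '", study$organism,
           "' at row ", conflict[1L], " (", sp[conflict[1L]], ")", call. = FALSE)
    }
  }
  raw <- trimws(dt$raw_id %||% character())
  blank <- !nzchar(raw)
  n_skipped <- sum(blank)
  if (n_skipped) {
    warning(n_skipped, " row(s) with blank raw_id skipped in ", path,
            call. = FALSE)
  }
  keep <- which(!blank)
  effect <- if ("effect" %in% names(dt)) tolower(trimws(dt$effect[keep])) else
    rep("unknown", length(keep))
  effect[!nzchar(effect)] <- "unknown"
  bad <- setdiff(unique(effect), EFFECT_CODES)
  if (length(bad)) {
    stop("unknown effect code(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.table::data.table(
    study_id = study$study_id,
    raw_id = raw[keep],
    species = study$organism,
    effect = effect,
    note = if ("note" %in% names(dt)) dt$note[keep] else rep("", length(keep)))
  if (nrow(out) != study$n_reported) {
    warning("study ", study$study_id, ": hit list has ", nrow(out),
            " records but catalog reports n_reported = ", study$n_reported,
            call. = FALSE)
  }
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

#' Summarize a study catalog
#'
#' Exact integer accounting over a study catalog: study counts and sums of
#' reported modifiers and expected worm orthologues, overall and per
#' organism. The per-organism rows partition the overall totals.
#'
#' @param studies A \code{study_table} (may be empty).
#' @return A list of class \code{catalog_summary} with elements
#'   \code{n_studies}, \code{n_reported}, \code{n_orthologues_expected} and
#'   \code{by_organism} (a \code{data.table} with the same three quantities
#'   per organism).
#' @export
summarize_catalog <- function(studies) {
  dt <- unclass_study_table(studies)
  by_org <- if (nrow(dt)) {
    dt[, .(n_studies = .N,
           n_reported = sum(n_reported),
           n_orthologues_expected = sum(n_orthologues_expected, na.rm = TRUE)),
       by = organism][order(organism)]
  } else {
    data.table::data.table(organism = character(), n_studies = integer(),
                           n_reported = integer(),
                           n_orthologues_expected = integer())
  }
  structure(list(
    n_studies = nrow(dt),
    n_reported = sum(dt$n_reported %||% 0L),
    n_orthologues_expected = sum(dt$n_orthologues_expected, na.rm = TRUE),
    by_organism = by_org), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Study catalog: ", x$n_studies, " studies, ", x$n_reported,
      " reported modifiers, ", x$n_orthologues_expected,
      " expected worm orthologues\n", sep = "")
  if (nrow(x$by_organism)) print(x$by_organism)
  invisible(x)
}
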