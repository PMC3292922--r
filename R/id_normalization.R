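# Gene identifier normalization.
#
# Screen hit lists mix gene symbols ("hsf-1"), sequence names ("Y53C10A.12"),
# isoform-level sequence names ("ZK256.1a") and inconsistent casing. Set
# operations downstream (union, overlap) are only well defined once every
# identifier is reduced to one canonical string per gene within its species
# namespace.

#' Load a gene alias table
#'
#' Reads a tab-separated alias table mapping identifier variants to canonical
#' gene identifiers within a species namespace. Matching at lookup time is
#' case-insensitive on the alias; the canonical value keeps the casing given
#' in the table.
#'
#' Canonical values are themselves passed through the canonicalization rules
#' (worm isoform suffixes are stripped), so that normalization is idempotent:
#' the output of a lookup is always a fixed point.
#'
#' @param path Path to a TSV with columns \code{species}, \code{alias},
#'   \code{canonical} and optionally \code{provenance}. Lines starting with
#'   \code{#} are ignored.
#' @return An object of class \code{alias_table}.
#' @details An alias that maps to two different canonical values within one
#'   species is a hard error: such a table would make normalization
#'   ambiguous. A canonical value that also appears as an alias for a
#'   different gene is rejected for the same reason (it would break
#'   idempotence).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("species\talias\tcanonical",
#'              "worm\thsf-1\tY53C10A.12"), tf)
#' ali <- load_alias_table(tf)
#' alias_lookup(ali, "worm", "HSF-1")
#' @export
load_alias_table <- function(path) {
  dt <- read_tsv_commented(path)
  if (!nrow(dt) && !length(names(dt))) {
    dt <- data.table::data.table(species = character(), alias = character(),
                                 canonical = character())
  }
  assert_columns(dt, c("species", "alias", "canonical"), path)
  if (!"provenance" %in% names(dt)) dt[, provenance := ""]
  assert_species(dt$species)
  dt[, alias := trimws(alias)]
  dt[, canonical := trimws(canonical)]
  # canonical values live in the same namespace: apply the same
  # canonicalization (worm isoform stripping) to them
  dt[, canonical := strip_isoform_suffix(canonical, species)]
  dt[, alias_fold := tolower(alias)]
  dup <- dt[, .(n = data.table::uniqueN(canonical)), by = .(species, alias_fold)][n > 1L]
  if (nrow(dup)) {
    first <- dup[1L]
    targets <- unique(dt[species == first$species & alias_fold == first$alias_fold, canonical])
    stop("conflicting alias '", first$alias_fold, "' (", first$species,
         ") maps to multiple canonical values: ",
         paste(targets, collapse = " vs "), call. = FALSE)
  }
  dt <- unique(dt, by = c("species", "alias_fold"))
  # a canonical value that is itself an alias of something else breaks
  # idempotence: reject
  can <- dt[, .(species, canonical_fold = tolower(canonical))]
  hit <- dt[can, on = c("species", alias_fold = "canonical_fold"), nomatch = NULL]
  bad <- hit[tolower(canonical) != alias_fold]
  if (nrow(bad)) {
    stop("alias table is not idempotent: canonical value '", bad$alias_fold[1L],
         "' (", bad$species[1L], ") is itself an alias for '",
         bad$canonical[1L], "'", call. = FALSE)
  }
  data.table::setkeyv(dt, c("species", "alias_fold"))
  structure(list(table = dt[], source = path), class = "alias_table")
}

#' Empty alias table
#'
#' @return An \code{alias_table} with no entries; every lookup misses.
#' @export
empty_alias_table <- function() {
  dt <- data.table::data.table(species = character(), alias = character(),
                               canonical = character(), provenance = character(),
                               alias_fold = character())
  data.table::setkeyv(dt, c("species", "alias_fold"))
  structure(list(table = dt, source = NA_character_), class = "alias_table")
}

#' @export
print.alias_table <- function(x, ...) {
  cat("<alias_table> ", nrow(x$table), " aliases across ",
      data.table::uniqueN(x$table$species), " species\n", sep = "")
  invisible(x)
}

#' Look up aliases
#'
#' Case-insensitive alias lookup within a species namespace.
#'
#' @param aliases An \code{alias_table}.
#' @param species Species code, recycled against \code{alias}.
#' @param alias Character vector of alias strings.
#' @return Character vector of canonical values; \code{NA} where the alias is
#'   not in the table.
#' @export
alias_lookup <- function(aliases, species, alias) {
  stopifnot(inherits(aliases, "alias_table"))
  q <- data.table::data.table(species = species, alias_fold = tolower(trimws(alias)))
  aliases$table[q, on = c("species", "alias_fold")]$canonical
}

# Strip a single trailing lowercase isoform letter from worm sequence names:
# "ZK256.1a" -> "ZK256.1". Applies only to strings matching the sequence-name
# shape <alnum-with-digit>.<digits><letter>; symbols like "sir-2.1" and
# non-worm ids are untouched.
strip_isoform_suffix <- function(value, species) {
  is_worm <- species == "worm"
  pat <- "^([A-Za-z][A-Za-z0-9_]*[0-9][A-Za-z0-9_]*\\.[0-9]+)([a-z])$"
  hit <- is_worm & grepl(pat, value)
  value[hit] <- sub(pat, "\\1", value[hit])
  value
}

#' Normalize gene identifiers
#'
#' Canonicalizes raw identifier strings into namespaced gene identifiers.
#' The steps, in order: trim surrounding whitespace (and stray trailing
#' commas, which appear in curated tables); optionally strip a worm isoform
#' suffix (\code{ZK742.1a} to \code{ZK742.1}); resolve through the alias
#' table, case-insensitively. Identifiers that resolve through an alias carry
#' the alias as \code{display_name}. Unresolved identifiers pass through
#' unchanged (canonical by identity) and are flagged \code{resolved = FALSE}
#' rather than dropped, so catalog accounting stays conservative.
#'
#' Normalization is idempotent: \code{normalize_gene_id} applied to its own
#' output is a no-op.
#'
#' @param raw Character vector of raw identifiers (non-empty after trimming).
#' @param species Single species code or vector recycled against \code{raw}.
#' @param aliases An \code{alias_table}; defaults to empty.
#' @param strip_isoform Strip worm isoform suffixes. Default \code{TRUE}:
#'   the analysis unit is the gene, not the transcript.
#' @return A \code{data.table} with one row per input: \code{species},
#'   \code{value} (canonical identifier), \code{display_name} (gene symbol
#'   when known, else \code{NA}), \code{resolved} (logical: did an alias or
#'   isoform rule fire, or was the id already canonical input).
#' @examples
#' normalize_gene_id("ZK742.1a", "worm")
#' @export
normalize_gene_id <- function(raw, species, aliases = empty_alias_table(),
                              strip_isoform = TRUE) {
  if (!length(raw)) {
    return(data.table::data.table(species = character(), value = character(),
                                  display_name = character(), resolved = logical()))
  }
  assert_species(species)
  value <- trimws(raw)
  value <- sub("[,;]+$", "", value)  # curated-table stray punctuation
  value <- trimws(value)
  if (any(!nzchar(value))) {
    stop("empty gene identifier after trimming (position ",
         which(!nzchar(value))[1L], ")", call. = FALSE)
  }
  species <- rep_len(species, length(value))
  if (strip_isoform) value <- strip_isoform_suffix(value, species)
  canon <- alias_lookup(aliases, species, value)
  resolved <- !is.na(canon)
  display <- ifelse(resolved & tolower(canon) != tolower(value), value, NA_character_)
  value[resolved] <- canon[resolved]
  data.table::data.table(species = species, value = value,
                         display_name = display, resolved = resolved)
}
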