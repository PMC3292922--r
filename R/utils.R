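# Internal helpers shared across modules.

SPECIES_CODES <- c("worm", "yeast", "fly", "human")
REFERENCE_SPECIES <- "worm"
DISEASE_MODEL_CODES <- c("P", "S", "T", "SOD", "Abeta")
EFFECT_CODES <- c("suppressor", "enhancer", "modifier", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table fread fwrite data.table setkeyv rbindlist setorderv
#'   as.data.table copy setnames :=
NULL

# Namespaced gene key used wherever genes go into sets: equality on
# (species, value) only.
gene_key <- function(species, value) paste(species, value, sep = "|")

split_gene_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.table::data.table(
    species = vapply(parts, `[`, "", 1L),
    value = vapply(parts, function(p) paste(p[-1L], collapse = "|"), "")
  )
}

assert_species <- function(species) {
  bad <- setdiff(unique(species), SPECIES_CODES)
  if (length(bad)) {
    stop("unknown species code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(SPECIES_CODES, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(species)
}

assert_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  invisible(path)
}

assert_columns <- function(dt, required, path) {
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(dt)
}

read_tsv <- function(path, ...) {
  assert_file(path)
  data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                    na.strings = NULL, fill = TRUE, blank.lines.skip = TRUE,
                    quote = "", ...)
}

# fread has no comment-line support for multi-column TSVs; strip "#" lines
# up front so fixtures can carry provenance comments.
read_tsv_commented <- function(path, ...) {
  assert_file(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.table::data.table())
  }
  data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                    header = TRUE, colClasses = "character", na.strings = NULL,
                    quote = "", ...)
}

# Collapse / expand set-valued TSV cells ("P, S" <-> c("P","S")).
join_set <- function(x) vapply(x, function(v) paste(sort(unique(v)), collapse = ", "), "")

split_set <- function(x, split = "\\s*(,|;| and )\\s*") {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    parts <- trimws(strsplit(trimws(cell), split)[[1]])
    parts[nzchar(parts)]
  })
}

# Size-safe uniform sampling: never falls into sample()'s scalar-x trap.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Seed-scoped RNG: run `expr` under `seed` and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
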