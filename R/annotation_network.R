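# Functional annotation, human orthologues, neuronal expression and the
# protein-interaction subnetwork among overlapping regulators.

#' Load functional annotations against a controlled vocabulary
#'
#' @param path TSV with columns \code{gene} (canonical worm identifier or an
#'   alias resolvable through \code{aliases}), \code{functional_class}, and
#'   optionally \code{source}/\code{provenance}.
#' @param vocabulary_path Text file listing one allowed class per line
#'   (\code{#} lines ignored).
#' @param aliases Optional \code{alias_table} used to resolve gene symbols.
#' @return A \code{data.table} with \code{gene}, \code{functional_class},
#'   \code{source}; the vocabulary is carried in attribute
#'   \code{vocabulary}.
#' @details An annotation whose class is not in the vocabulary is a hard
#'   error naming the offending row.
#' @export
load_annotations <- function(path, vocabulary_path,
                             aliases = empty_alias_table()) {
  vocab <- read_vocabulary(vocabulary_path)
  dt <- read_tsv_commented(path)
  if (!length(names(dt)) || !nrow(dt)) {
    out <- data.table::data.table(gene = character(),
                                  functional_class = character(),
                                  source = character())
    data.table::setattr(out, "vocabulary", vocab)
    return(out)
  }
  assert_columns(dt, c("gene", "functional_class"), path)
  dt[, functional_class := trimws(functional_class)]
  bad <- which(!dt$functional_class %in% vocab)
  if (length(bad)) {
    stop("annotation row ", bad[1L], ": class '", dt$functional_class[bad[1L]],
         "' is not in the vocabulary (", vocabulary_path, ")", call. = FALSE)
  }
  norm <- normalize_gene_id(dt$gene, "worm", aliases)
  out <- data.table::data.table(
    gene = norm$value,
    functional_class = dt$functional_class,
    source = if ("source" %in% names(dt)) dt$source
             else if ("provenance" %in% names(dt)) dt$provenance
             else "")
  data.table::setattr(out, "vocabulary", vocab)
  out
}

#' Read a functional-class vocabulary file
#'
#' @param path One class name per line; \code{#} comments and blank lines
#'   ignored.
#' @return Character vector of class names, file order.
#' @export
read_vocabulary <- function(path) {
  assert_file(path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Build the study-by-class functional incidence matrix
#'
#' A cell (study, class) is \code{TRUE} when at least one catalog evidence
#' record links that study to a worm gene annotated with that class.
#' Vocabulary classes never hit by any study are retained as all-\code{FALSE}
#' columns, so the matrix shape is stable across catalogs.
#'
#' @param catalog A \code{regulator_catalog}.
#' @param annotations Output of [load_annotations()].
#' @return Logical matrix, studies as rows, vocabulary classes as columns.
#' @export
build_functional_matrix <- function(catalog, annotations) {
  stopifnot(inherits(catalog, "regulator_catalog"))
  vocab <- attr(annotations, "vocabulary", exact = TRUE)
  if (is.null(vocab)) vocab <- sort(unique(annotations$functional_class))
  studies <- sort(unique(catalog$evidence$study_id))
  mat <- matrix(FALSE, nrow = length(studies), ncol = length(vocab),
                dimnames = list(studies, vocab))
  if (!nrow(annotations) || !nrow(catalog$evidence)) return(mat)
  hit <- merge(catalog$evidence[, .(gene, study_id)], annotations,
               by = "gene", allow.cartesian = TRUE)
  if (nrow(hit)) {
    mat[cbind(hit$study_id, hit$functional_class)] <- TRUE
  }
  mat
}

#' Write a functional incidence matrix as TSV
#'
#' @param mat Matrix from [build_functional_matrix()].
#' @param path Output path. Studies become the first column.
#' @return \code{path}, invisibly.
#' @export
write_functional_matrix <- function(mat, path) {
  out <- data.table::as.data.table(mat, keep.rownames = "study_id")
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Attach human orthologue labels to overlap entries
#'
#' Projects every worm gene of every overlap entry onto the human namespace
#' of an orthology map and records the union per entry.
#'
#' @param overlaps An \code{overlap_set}.
#' @param map An \code{orthology_map} with human members (e.g. a pairwise
#'   worm-to-human table).
#' @return The \code{overlap_set} with a list column
#'   \code{human_orthologues}; attribute \code{all_have_human} is
#'   \code{TRUE} when every entry has at least one label.
#' @export
attach_human_orthologues <- function(overlaps, map) {
  stopifnot(inherits(overlaps, "overlap_set"))
  hs <- lapply(overlaps$genes, function(gs) {
    sort(unique(unlist(lapply(gs, function(g)
      orthologues(map, "worm", g, target_species = "human")))))
  })
  out <- data.table::copy(overlaps)
  out[, human_orthologues := hs]
  data.table::setattr(out, "class", class(overlaps))
  data.table::setattr(out, "all_have_human",
                      nrow(out) > 0L && all(lengths(hs) >= 1L))
  out
}

# Table-style expression strings -> {yes, no, unknown}. Curated tables mix
# "Yes", "yes", "No", "No?" (uncertain negative -> no) and "?" (-> unknown).
normalize_expression_value <- function(x) {
  v <- tolower(trimws(x))
  out <- rep(NA_character_, length(v))
  out[v %in% c("yes", "y")] <- "yes"
  out[v %in% c("no", "n", "no?")] <- "no"
  out[v %in% c("?", "unknown", "")] <- "unknown"
  if (anyNA(out)) {
    stop("expression value outside {yes, no, unknown}: '", x[which(is.na(out))[1L]],
         "'", call. = FALSE)
  }
  out
}

#' Attach neuronal-expression flags to overlap entries
#'
#' @param overlaps An \code{overlap_set}.
#' @param expression Either a path to a TSV with columns \code{gene} and
#'   \code{neuronal_expression}, or an equivalent \code{data.frame}. Raw
#'   values \code{Yes}/\code{yes}, \code{No}/\code{No?} and \code{?} are
#'   normalized to \code{yes}/\code{no}/\code{unknown}; anything else is a
#'   hard error.
#' @param aliases Optional \code{alias_table} for the gene column.
#' @return The \code{overlap_set} with a \code{neuronal_expression} column;
#'   entries absent from the table get \code{"unknown"}. A multi-gene entry
#'   takes the flag of its first annotated gene.
#' @export
attach_expression <- function(overlaps, expression,
                              aliases = empty_alias_table()) {
  stopifnot(inherits(overlaps, "overlap_set"))
  dt <- if (is.character(expression)) read_tsv_commented(expression)
        else data.table::as.data.table(expression)
  assert_columns(dt, c("gene", "neuronal_expression"), "expression table")
  flag <- normalize_expression_value(dt$neuronal_expression)
  gene <- if (nrow(dt)) normalize_gene_id(dt$gene, "worm", aliases)$value
          else character()
  lut <- stats::setNames(flag, gene)
  out <- data.table::copy(overlaps)
  out[, neuronal_expression := vapply(genes, function(gs) {
    f <- lut[gs]
    f <- f[!is.na(f)]
    if (length(f)) f[[1L]] else "unknown"
  }, "")]
  data.table::setattr(out, "class", class(overlaps))
  out
}

#' Build a protein-interaction graph
#'
#' Loads a binary interaction edge list into a simple undirected graph:
#' self-loops are skipped with a warning, duplicate edges collapse to one.
#'
#' @param edges_path TSV with columns \code{protein_a}, \code{protein_b} and
#'   optionally \code{provenance}.
#' @param restrict_to Optional character vector of node labels; only edges
#'   with both endpoints in the set are kept, and isolated members of the
#'   set remain as nodes.
#' @return An \code{igraph} object with edge attribute \code{provenance}.
#' @export
build_ppi_graph <- function(edges_path, restrict_to = NULL) {
  dt <- read_tsv_commented(edges_path)
  if (!length(names(dt)) || !nrow(dt)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    if (!is.null(restrict_to)) g <- g + igraph::vertices(sort(unique(restrict_to)))
    return(g)
  }
  assert_columns(dt, c("protein_a", "protein_b"), edges_path)
  dt[, protein_a := trimws(protein_a)]
  dt[, protein_b := trimws(protein_b)]
  loops <- dt$protein_a == dt$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) skipped in ", edges_path,
            call. = FALSE)
    dt <- dt[!loops]
  }
  if (!is.null(restrict_to)) {
    dt <- dt[protein_a %in% restrict_to & protein_b %in% restrict_to]
  }
  if (!"provenance" %in% names(dt)) dt[, provenance := ""]
  g <- igraph::graph_from_data_frame(
    dt[, .(from = protein_a, to = protein_b, provenance)], directed = FALSE,
    vertices = if (is.null(restrict_to)) NULL
               else data.frame(name = sort(unique(restrict_to))))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(provenance = function(x)
                     paste(sort(unique(x)), collapse = "; ")))
}

#' Connected component containing a seed node
#'
#' @param graph An \code{igraph} object.
#' @param seed_node Node label; must be present in the graph.
#' @return Sorted character vector: the maximal connected node set
#'   containing the seed.
#' @export
connected_component <- function(graph, seed_node) {
  if (!seed_node %in% igraph::V(graph)$name) {
    stop("seed node '", seed_node, "' is not in the graph", call. = FALSE)
  }
  sort(names(igraph::subcomponent(graph, seed_node, mode = "all")))
}
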