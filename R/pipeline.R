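# End-to-end pipeline, packaged fixtures and the command-line entry point.

#' Run the full integration pipeline
#'
#' Executes the whole chain — study catalog, identifier normalization,
#' orthology projection, catalog integration, overlap detection, optional
#' annotation and overlap statistics — and (optionally) writes
#' \code{catalog.tsv}, \code{overlaps.tsv} and a \code{summary.json} of
#' every stage count to \code{out_dir}.
#'
#' @param studies_path Study catalog TSV (see [read_study_table()]).
#' @param genes_dir Directory of per-study hit lists named
#'   \code{<study_id>.tsv}; a study without a file contributes zero calls.
#' @param groups_path,pairwise_path Orthology sources (either or both; see
#'   [read_orthomcl_groups()], [read_pairwise_orthologs()]); merged with
#'   union semantics.
#' @param aliases_path Optional alias table.
#' @param annotations_path,vocabulary_path Optional functional annotations;
#'   when both given, a study-by-class incidence matrix is computed (and
#'   written to \code{functional_matrix.tsv}).
#' @param expression_path Optional neuronal-expression table attached to
#'   the overlap entries.
#' @param out_dir Output directory; \code{NULL} for no file output.
#' @param min_studies,group_paralogues Overlap detection parameters.
#' @param stats Run the permutation overlap statistic (off by default: it is
#'   an extension of the integration analysis, not part of it).
#' @param universe_size,n_perm,seed Passed to [overlap_report()] when
#'   \code{stats} is \code{TRUE}.
#' @return A list of class \code{pipeline_result}: \code{studies},
#'   \code{mapped}, \code{catalog}, \code{overlaps}, \code{functional_matrix}
#'   (or \code{NULL}), \code{stats} (or \code{NULL}) and \code{summary}
#'   (stage counts; \code{n_warnings} counts validation warnings absorbed
#'   during loading).
#' @export
run_full_pipeline <- function(studies_path, genes_dir,
                              groups_path = NULL, pairwise_path = NULL,
                              aliases_path = NULL,
                              annotations_path = NULL, vocabulary_path = NULL,
                              expression_path = NULL,
                              out_dir = NULL, min_studies = 2L,
                              group_paralogues = TRUE, stats = FALSE,
                              universe_size = NULL, n_perm = 10000L,
                              seed = 17L) {
  n_warnings <- 0L
  absorb <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warnings <<- n_warnings + 1L
      invokeRestart("muffleWarning")
    })
  }
  studies <- read_study_table(studies_path)
  aliases <- if (!is.null(aliases_path)) load_alias_table(aliases_path)
             else empty_alias_table()
  maps <- list()
  if (!is.null(groups_path))
    maps <- c(maps, list(absorb(read_orthomcl_groups(groups_path, aliases = aliases))))
  if (!is.null(pairwise_path))
    maps <- c(maps, list(read_pairwise_orthologs(pairwise_path, aliases = aliases)))
  map <- if (length(maps)) do.call(merge_orthology_maps, maps)
         else new_orthology_map(data.table::data.table(
           group_id = character(), species = character(), value = character()),
           dialect = "empty")
  mapped <- lapply(seq_len(nrow(studies)), function(i) {
    st <- studies[i]
    gl_path <- file.path(genes_dir, paste0(st$study_id, ".tsv"))
    calls <- if (file.exists(gl_path)) absorb(read_gene_list(gl_path, st))
    else data.table::data.table(study_id = character(), raw_id = character(),
                                species = character(), effect = character(),
                                note = character())
    map_study(st, calls, map, aliases)
  })
  catalog <- integrate_catalog(studies, mapped)
  overlaps <- find_overlaps(catalog, min_studies = min_studies)
  n_merged <- 0L
  if (group_paralogues) {
    overlaps <- group_paralogue_entries(overlaps, catalog)
    n_merged <- attr(overlaps, "n_merged", exact = TRUE) %||% 0L
  }
  if (!is.null(expression_path)) {
    overlaps <- attach_expression(overlaps, expression_path, aliases)
  }
  fmat <- NULL
  if (!is.null(annotations_path) && !is.null(vocabulary_path)) {
    ann <- load_annotations(annotations_path, vocabulary_path, aliases)
    fmat <- build_functional_matrix(catalog, ann)
  }
  stat_res <- if (isTRUE(stats)) {
    overlap_report(catalog, overlaps, map = map, universe_size = universe_size,
                   n_perm = n_perm, seed = seed)
  } else NULL
  run_id_path <- file.path(dirname(genes_dir), "run_id.txt")
  n_calls <- sum(vapply(mapped, function(m) nrow(m$calls), 0L))
  summary <- list(
    run_id = if (file.exists(run_id_path)) readLines(run_id_path)[1L] else NA,
    n_studies = nrow(studies),
    n_calls = n_calls,
    n_mapped = n_calls - nrow(catalog$unmapped),
    n_unmapped = nrow(catalog$unmapped),
    n_distinct = nrow(catalog$entries),
    sum_per_study_distinct = sum(vapply(mapped, function(m)
      m$n_distinct_worm, 0L)),
    n_overlaps = nrow(overlaps),
    n_merged = n_merged,
    min_studies = as.integer(min_studies),
    n_warnings = n_warnings,
    p_value = if (!is.null(stat_res)) stat_res$p_value else NA)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_catalog_table(catalog, file.path(out_dir, "catalog.tsv"))
    write_overlap_table(overlaps, file.path(out_dir, "overlaps.tsv"))
    if (!is.null(fmat))
      write_functional_matrix(fmat, file.path(out_dir, "functional_matrix.tsv"))
    if (!is.null(stat_res)) {
      q <- stats::quantile(stat_res$null_counts, c(0.025, 0.5, 0.975),
                           names = FALSE)
      jsonlite::write_json(list(observed = stat_res$observed,
                                expectation = stat_res$expectation_closed_form,
                                mean_null = stat_res$mean_null,
                                null_q025 = q[1], null_median = q[2],
                                null_q975 = q[3],
                                p_value = stat_res$p_value),
                           file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(studies = studies, mapped = mapped, catalog = catalog,
                 overlaps = overlaps, functional_matrix = fmat,
                 stats = stat_res, map = map, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline run: ", s$n_studies, " studies, ", s$n_calls, " calls (",
      s$n_unmapped, " unmapped), ", s$n_distinct, " distinct worm genes, ",
      s$n_overlaps, " overlap entries\n", sep = "")
  invisible(x)
}

FIXTURE_FILES <- c(
  table1_catalog = "table1_studies.tsv",
  table2_overlaps = "table2_overlaps.tsv",
  table3_classes = "table3_annotations.tsv",
  fig3_edges = "fig3_ppi_edges.tsv",
  aliases = "aliases.tsv",
  orthology_groups = "orthology_groups.txt",
  human_orthologs = "human_orthologs.tsv",
  expression = "expression.tsv",
  table3_vocabulary = "table3_vocabulary.txt")

#' Path of a packaged fixture file
#'
#' @param name Fixture name, one of the names known to [load_fixture()].
#' @return Absolute path of the installed fixture file.
#' @export
fixture_path <- function(name) {
  if (!name %in% names(FIXTURE_FILES)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(FIXTURE_FILES), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "ndscreen",
                      mustWork = TRUE)
  path
}

#' Load a packaged fixture as a typed object
#'
#' Fixtures are transcriptions of the curated tables the pipeline targets,
#' shipped as data files with per-row provenance so that corrections never
#' require code changes. Available: \code{table1_catalog} (the 28-study
#' catalog), \code{table2_overlaps} (the 34 curated overlap entries),
#' \code{table3_classes} (functional annotations over a 12-class
#' vocabulary), \code{fig3_edges} (the chaperone/ubiquitin interaction
#' subnetwork), plus supporting tables \code{aliases},
#' \code{orthology_groups}, \code{human_orthologs}, \code{expression},
#' \code{table3_vocabulary}.
#'
#' @param name Fixture name; an unknown name raises an error listing the
#'   available fixtures.
#' @return The typed object: a \code{study_table}, \code{overlap_set},
#'   annotation table, \code{igraph}, \code{alias_table},
#'   \code{orthology_map}, \code{data.table} or character vector, by
#'   fixture.
#' @export
load_fixture <- function(name) {
  path <- fixture_path(name)
  switch(name,
    table1_catalog = read_study_table(path),
    table2_overlaps = read_overlap_table(path),
    table3_classes = load_annotations(path, fixture_path("table3_vocabulary"),
                                      aliases = load_fixture("aliases")),
    fig3_edges = build_ppi_graph(path),
    aliases = load_alias_table(path),
    orthology_groups = read_orthomcl_groups(path,
                                            aliases = load_fixture("aliases")),
    human_orthologs = read_pairwise_orthologs(path),
    expression = read_tsv_commented(path),
    table3_vocabulary = read_vocabulary(path))
}

# ---------------------------------------------------------------------------
# Command-line interface. One entry point with subcommands; logging goes to
# stderr, analysis outputs are files.

cli_flag_value <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1L] == length(args)) stop("flag ", flag, " needs a value", call. = FALSE)
  args[i[1L] + 1L]
}

cli_has_flag <- function(args, flag) flag %in% args

#' Command-line entry point
#'
#' Subcommands: \code{integrate} (full pipeline; flags \code{--studies},
#' \code{--genes-dir}, \code{--groups}, \code{--pairwise}, \code{--aliases},
#' \code{--annotations}, \code{--vocabulary}, \code{--expression},
#' \code{--out}, \code{--min-studies}, \code{--no-group-paralogues},
#' \code{--stats}, \code{--universe-size}, \code{--n-perm}, \code{--seed});
#' \code{simulate} (\code{--out}, \code{--seed}, \code{--config} pointing at
#' a JSON object of [synthetic_config()] overrides); \code{stats}
#' (\code{--observed-from} a pipeline output directory,
#' \code{--universe-size}, \code{--n-perm}, \code{--seed}, \code{--out});
#' \code{network} (\code{--edges}, \code{--seed-node}, \code{--out});
#' \code{report} (renders the curated overlap fixture; \code{--out}).
#'
#' @param args Character vector of command-line arguments; defaults to the
#'   process arguments.
#' @return Integer exit status, invisibly (0 on success). Errors are
#'   reported on stderr and yield status 1.
#' @export
ndscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: ndscreen <integrate|simulate|stats|network|report> [flags]",
                            call. = FALSE)
    cmd <- args[1L]
    rest <- args[-1L]
    switch(cmd,
      integrate = {
        res <- run_full_pipeline(
          studies_path = cli_flag_value(rest, "--studies"),
          genes_dir = cli_flag_value(rest, "--genes-dir"),
          groups_path = cli_flag_value(rest, "--groups"),
          pairwise_path = cli_flag_value(rest, "--pairwise"),
          aliases_path = cli_flag_value(rest, "--aliases"),
          annotations_path = cli_flag_value(rest, "--annotations"),
          vocabulary_path = cli_flag_value(rest, "--vocabulary"),
          expression_path = cli_flag_value(rest, "--expression"),
          out_dir = cli_flag_value(rest, "--out"),
          min_studies = as.integer(cli_flag_value(rest, "--min-studies", "2")),
          group_paralogues = !cli_has_flag(rest, "--no-group-paralogues"),
          stats = cli_has_flag(rest, "--stats"),
          universe_size = {
            u <- cli_flag_value(rest, "--universe-size")
            if (is.null(u)) NULL else as.integer(u)
          },
          n_perm = as.integer(cli_flag_value(rest, "--n-perm", "10000")),
          seed = as.integer(cli_flag_value(rest, "--seed", "17")))
        message("integrate: ", res$summary$n_studies, " studies, ",
                res$summary$n_distinct, " distinct genes, ",
                res$summary$n_overlaps, " overlaps")
      },
      simulate = {
        cfg_path <- cli_flag_value(rest, "--config")
        over <- if (!is.null(cfg_path)) jsonlite::read_json(cfg_path,
                                                            simplifyVector = TRUE)
                else list()
        seed <- cli_flag_value(rest, "--seed")
        if (!is.null(seed)) over$seed <- as.integer(seed)
        cfg <- do.call(synthetic_config, over)
        generate_synthetic_dataset(cfg, cli_flag_value(rest, "--out"))
        message("simulate: bundle written")
      },
      stats = {
        from <- cli_flag_value(rest, "--observed-from")
        if (is.null(from)) stop("stats needs --observed-from <pipeline outdir>",
                                call. = FALSE)
        summ <- jsonlite::read_json(file.path(from, "summary.json"))
        cat_tab <- read_tsv(file.path(from, "catalog.tsv"))
        sizes <- if (nrow(cat_tab)) {
          tab <- table(unlist(split_set(cat_tab$studies)))
          as.integer(tab)
        } else integer()
        u <- cli_flag_value(rest, "--universe-size")
        u <- if (is.null(u)) max(summ$n_distinct, 1L) else as.integer(u)
        cfg <- null_model_config(u, sizes,
                                 n_perm = as.integer(cli_flag_value(rest, "--n-perm", "10000")),
                                 seed = as.integer(cli_flag_value(rest, "--seed", "17")))
        res <- permutation_null(cfg, as.integer(summ$n_overlaps))
        out <- cli_flag_value(rest, "--out")
        if (!is.null(out)) {
          jsonlite::write_json(list(observed = res$observed,
                                    expectation = res$expectation_closed_form,
                                    mean_null = res$mean_null,
                                    p_value = res$p_value),
                               out, auto_unbox = TRUE, digits = NA)
        }
        message("stats: observed ", res$observed, ", p = ", res$p_value)
      },
      network = {
        g <- build_ppi_graph(cli_flag_value(rest, "--edges"))
        comp <- connected_component(g, cli_flag_value(rest, "--seed-node"))
        out <- cli_flag_value(rest, "--out")
        if (!is.null(out)) {
          jsonlite::write_json(list(seed = cli_flag_value(rest, "--seed-node"),
                                    component = comp, size = length(comp)),
                               out, auto_unbox = TRUE, digits = NA)
        }
        message("network: component of size ", length(comp))
      },
      report = {
        overlaps <- load_fixture("table2_overlaps")
        out_dir <- cli_flag_value(rest, "--out", ".")
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_overlap_table(overlaps, file.path(out_dir, "overlaps.tsv"))
        message("report: ", nrow(overlaps), " overlap rows rendered")
      },
      stop("unknown subcommand '", cmd, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
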