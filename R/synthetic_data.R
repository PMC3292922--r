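# Ground-truthed synthetic input bundles.
#
# The generator emits the same file shapes the pipeline consumes — a study
# catalog, per-study hit lists in species-native identifier styles, an
# OrthoMCL-style groups file, aliases, annotations and a PPI edge list —
# together with a truth manifest recording exactly what was planted. It
# imitates the *shapes* of curated screen data (identifier styles, skewed
# study sizes, partial orthology coverage, one-to-many expansion, paralogue
# pairs); it does not model screen biology.

#' Synthetic dataset configuration
#'
#' Defaults mirror the scale of the curated corpus the pipeline targets:
#' 28 studies (13 worm, 6 yeast, 9 fly), per-study hit counts between 1 and
#' 100, species gene universes near genome scale, roughly half of non-worm
#' hits mappable to a worm orthologue, a small one-to-many rate, 34 planted
#' shared regulators each appearing in 2 to 5 studies, and a 12-class
#' functional vocabulary.
#'
#' @param n_studies Named integer vector: studies per organism
#'   (\code{worm}, \code{yeast}, \code{fly}); zeros allowed.
#' @param universe_sizes Named integer vector: gene-universe size per
#'   species.
#' @param hits_range Length-2 integer range of per-study hit counts.
#' @param orthology_coverage Probability that a non-worm background hit has
#'   a worm orthologue.
#' @param one_to_many_rate Probability that a mapped background hit has two
#'   worm orthologues rather than one.
#' @param n_planted_shared Number of worm genes planted into >= 2 studies.
#' @param planted_multiplicity Length-2 range: studies per planted gene.
#' @param paralogue_pair_rate Fraction of planted genes that are emitted as
#'   a worm paralogue pair sharing identical (non-worm) source evidence.
#' @param alias_rate Fraction of planted worm genes given a gene-symbol
#'   alias that is then used in worm hit lists.
#' @param isoform_noise_rate Fraction of worm hit-list rows written with a
#'   spurious isoform suffix ("a") to exercise normalization.
#' @param n_classes Number of functional-vocabulary classes.
#' @param disjoint_background Force background draws (source genes and worm
#'   targets) to be disjoint across studies, so the planted set is the
#'   unique overlap; needed for exact-recovery tests.
#' @param seed RNG seed; the whole bundle is a deterministic function of the
#'   configuration including the seed.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_studies = c(worm = 13L, yeast = 6L, fly = 9L),
                             universe_sizes = c(worm = 20000L, yeast = 6000L,
                                                fly = 14000L),
                             hits_range = c(1L, 100L),
                             orthology_coverage = 0.5,
                             one_to_many_rate = 0.05,
                             n_planted_shared = 34L,
                             planted_multiplicity = c(2L, 5L),
                             paralogue_pair_rate = 0.05,
                             alias_rate = 0.1,
                             isoform_noise_rate = 0.1,
                             n_classes = 12L,
                             disjoint_background = FALSE,
                             seed = 1L) {
  fracs <- c(orthology_coverage, one_to_many_rate, paralogue_pair_rate,
             alias_rate, isoform_noise_rate)
  if (any(fracs < 0 | fracs > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  stopifnot(all(c("worm", "yeast", "fly") %in% names(n_studies)),
            all(c("worm", "yeast", "fly") %in% names(universe_sizes)),
            length(hits_range) == 2L, hits_range[1] >= 1L,
            hits_range[2] >= hits_range[1],
            length(planted_multiplicity) == 2L,
            planted_multiplicity[1] >= 2L,
            planted_multiplicity[2] >= planted_multiplicity[1],
            n_planted_shared >= 0L)
  structure(list(
    n_studies = vapply(n_studies[c("worm", "yeast", "fly")], as.integer, 0L),
    universe_sizes = vapply(universe_sizes[c("worm", "yeast", "fly")], as.integer, 0L),
    hits_range = as.integer(hits_range),
    orthology_coverage = orthology_coverage,
    one_to_many_rate = one_to_many_rate,
    n_planted_shared = as.integer(n_planted_shared),
    planted_multiplicity = as.integer(planted_multiplicity),
    paralogue_pair_rate = paralogue_pair_rate,
    alias_rate = alias_rate,
    isoform_noise_rate = isoform_noise_rate,
    n_classes = as.integer(n_classes),
    disjoint_background = isTRUE(disjoint_background),
    seed = as.integer(seed)), class = "synthetic_config")
}

# Species-native identifier styles (all safe under isoform stripping).
synth_worm_id <- function(i) sprintf("SYW%05d.1", i)
synth_yeast_id <- function(i) sprintf("YSY%04dW", i)
synth_fly_id <- function(i) sprintf("CG9%05d", i)
synth_human_id <- function(i) sprintf("HSY%04d", i)

#' Generate a synthetic input bundle with ground truth
#'
#' Writes \code{studies.tsv}, \code{genes/<study>.tsv}, \code{groups.txt},
#' \code{aliases.tsv}, \code{vocabulary.txt}, \code{annotations.tsv},
#' \code{ppi_edges.tsv}, \code{run_id.txt} and \code{truth.json} under
#' \code{out_dir}, and returns the ground truth as an R object. Identical
#' configuration (including seed) yields byte-identical bundles. Feasibility
#' (enough study capacity for the planted genes) is checked before any file
#' is written.
#'
#' Planted shared genes are guaranteed to appear, through orthology, in
#' every study they were assigned to; background hits are uniform draws
#' from the remaining universe (optionally globally disjoint). Paralogue
#' pairs are planted by giving one non-worm source gene two worm orthologues
#' with identical study evidence. Every planted gene also carries a human
#' orthologue label so annotation steps are exercised.
#'
#' @param config A \code{synthetic_config}.
#' @param out_dir Output directory (created if needed); \code{NULL} builds
#'   the dataset in memory only and returns the truth (useful for
#'   large-replicate calibration studies where file output is waste).
#' @return Invisibly, a list of class \code{synthetic_truth}: \code{run_id},
#'   \code{config}, \code{planted} (gene, optional partner, assigned
#'   studies), \code{planted_set} (all planted worm genes incl. partners),
#'   \code{paralogue_groups}, \code{per_study} (hit count, distinct worm
#'   orthologue count and the worm set per study), \code{n_distinct_total}
#'   (expected regulator-catalog size), \code{class_incidence}
#'   (study/class pairs expected \code{TRUE}), \code{human_labels}.
#' @export
generate_synthetic_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- with_seed(config$seed, synth_build(config))
  if (is.null(out_dir)) return(invisible(truth))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)
  synth_write_bundle(truth, out_dir)
  synth_verify_bundle(truth, out_dir)
  invisible(truth)
}

# All random decisions happen here, under the config seed.
synth_build <- function(cfg) {
  organisms <- rep(c("worm", "yeast", "fly"), times = cfg$n_studies)
  K <- length(organisms)
  if (cfg$n_planted_shared > 0L && K < 2L) {
    stop("infeasible planting: need at least 2 studies", call. = FALSE)
  }
  study_id <- sprintf("S%02d", seq_len(K))
  sizes <- resample(seq.int(cfg$hits_range[1], cfg$hits_range[2]), K,
                    replace = TRUE)

  # --- plant shared genes -------------------------------------------------
  n_plant <- cfg$n_planted_shared
  n_pairs <- min(round(cfg$paralogue_pair_rate * n_plant),
                 if (sum(organisms != "worm") >= 2L) n_plant else 0L)
  worm_pool <- seq_len(cfg$universe_sizes[["worm"]])
  planted_idx <- if (n_plant) resample(worm_pool, n_plant + n_pairs) else integer()
  planted_gene <- synth_worm_id(planted_idx[seq_len(n_plant)])
  partner_gene <- if (n_pairs) synth_worm_id(planted_idx[n_plant + seq_len(n_pairs)])
                  else character()

  capacity <- sizes  # remaining hit slots per study
  assign_studies <- function(m, allowed) {
    open <- which(allowed & capacity > 0L)
    if (length(open) < m) {
      stop("infeasible planting: not enough study capacity for planted genes",
           call. = FALSE)
    }
    pick <- resample(open, m)
    capacity[pick] <<- capacity[pick] - 1L
    pick
  }
  planted <- vector("list", n_plant)
  for (k in seq_len(n_plant)) {
    is_pair <- k <= n_pairs
    m <- resample(seq.int(cfg$planted_multiplicity[1],
                          cfg$planted_multiplicity[2]), 1L)
    allowed <- if (is_pair) organisms != "worm" else rep(TRUE, K)
    m <- min(m, sum(allowed))
    if (m < 2L) stop("infeasible planting: paralogue pairs need >= 2 non-worm studies",
                     call. = FALSE)
    planted[[k]] <- list(gene = planted_gene[k],
                         partner = if (is_pair) partner_gene[k] else NA_character_,
                         studies = study_id[sort(assign_studies(m, allowed))])
  }

  # one source gene per (planted gene, species); groups carry all species'
  # sources plus the worm member(s) and a human label
  src_counter <- c(yeast = 0L, fly = 0L)
  groups <- list()
  plant_calls <- vector("list", K)  # per study: data.table(raw_id, ...)
  for (i in seq_len(K)) plant_calls[[i]] <- character()
  human_labels <- character(n_plant)
  for (k in seq_len(n_plant)) {
    p <- planted[[k]]
    idx <- match(p$studies, study_id)
    members <- c(paste0("cel|", p$gene),
                 if (!is.na(p$partner)) paste0("cel|", p$partner))
    human_labels[k] <- synth_human_id(k)
    members <- c(members, paste0("hsa|", human_labels[k]))
    for (sp in c("yeast", "fly")) {
      if (any(organisms[idx] == sp)) {
        src_counter[sp] <- src_counter[sp] + 1L
        # planted sources sit above each species' background id space so
        # background draws can never collide with them
        src <- if (sp == "yeast")
          synth_yeast_id(cfg$universe_sizes[["yeast"]] + src_counter[sp])
        else synth_fly_id(cfg$universe_sizes[["fly"]] + src_counter[sp])
        pre <- if (sp == "yeast") "sce|" else "dme|"
        members <- c(members, paste0(pre, src))
        for (i in idx[organisms[idx] == sp]) {
          plant_calls[[i]] <- c(plant_calls[[i]], src)
        }
      }
    }
    for (i in idx[organisms[idx] == "worm"]) {
      plant_calls[[i]] <- c(plant_calls[[i]], p$gene)
    }
    groups[[length(groups) + 1L]] <- sprintf("GP%04d: %s", k,
                                             paste(members, collapse = " "))
  }

  # --- background hits ----------------------------------------------------
  planted_set <- c(planted_gene, partner_gene)
  bg_worm_pool <- setdiff(worm_pool, planted_idx)
  yeast_pool <- seq_len(cfg$universe_sizes[["yeast"]])
  fly_pool <- seq_len(cfg$universe_sizes[["fly"]])
  # planted sources occupy the top of each pool's id space, so background
  # draws from the base pools never collide with them
  per_study <- vector("list", K)
  bg_groups <- list()
  gb <- 0L
  study_worm_sets <- vector("list", K)
  for (i in seq_len(K)) {
    n_bg <- sizes[i] - length(plant_calls[[i]])
    org <- organisms[i]
    if (org == "worm") {
      pick <- if (n_bg > 0L) {
        if (length(bg_worm_pool) < n_bg)
          stop("worm universe too small for requested study sizes", call. = FALSE)
        drawn <- resample(bg_worm_pool, n_bg)
        if (cfg$disjoint_background) bg_worm_pool <- setdiff(bg_worm_pool, drawn)
        drawn
      } else integer()
      bg_ids <- synth_worm_id(pick)
      worm_set <- c(plant_calls[[i]], bg_ids)
      raw <- c(plant_calls[[i]], bg_ids)
    } else {
      pool <- if (org == "yeast") yeast_pool else fly_pool
      if (length(pool) < n_bg)
        stop(org, " universe too small for requested study sizes", call. = FALSE)
      pick <- if (n_bg > 0L) resample(pool, n_bg) else integer()
      if (cfg$disjoint_background) {
        if (org == "yeast") yeast_pool <- setdiff(yeast_pool, pick)
        else fly_pool <- setdiff(fly_pool, pick)
      }
      bg_ids <- if (org == "yeast") synth_yeast_id(pick) else synth_fly_id(pick)
      # coverage: map a fraction of background hits to worm targets
      mapped <- if (n_bg > 0L) stats::runif(n_bg) < cfg$orthology_coverage
                else logical()
      worm_set <- character()
      pre <- if (org == "yeast") "sce|" else "dme|"
      for (j in which(mapped)) {
        k_t <- if (stats::runif(1) < cfg$one_to_many_rate) 2L else 1L
        if (length(bg_worm_pool) < k_t)
          stop("worm universe exhausted while mapping backgrounds", call. = FALSE)
        tgt <- resample(bg_worm_pool, k_t)
        if (cfg$disjoint_background) bg_worm_pool <- setdiff(bg_worm_pool, tgt)
        tgt_ids <- synth_worm_id(tgt)
        worm_set <- c(worm_set, tgt_ids)
        gb <- gb + 1L
        bg_groups[[gb]] <- sprintf("GB%05d: %s%s %s", gb, pre, bg_ids[j],
                                   paste0("cel|", tgt_ids, collapse = " "))
      }
      # worm reach of this study's planted sources
      for (k in seq_len(n_plant)) {
        p <- planted[[k]]
        if (study_id[i] %in% p$studies) {
          worm_set <- c(worm_set, p$gene, if (!is.na(p$partner)) p$partner)
        }
      }
      raw <- c(plant_calls[[i]], bg_ids)
    }
    study_worm_sets[[i]] <- sort(unique(worm_set))
    per_study[[i]] <- data.table::data.table(
      raw_id = raw,
      effect = sample(c("suppressor", "enhancer"), length(raw), replace = TRUE))
  }

  # --- aliases and worm-list noise ---------------------------------------
  n_alias <- round(cfg$alias_rate * n_plant)
  alias_genes <- planted_gene[seq_len(n_alias)]
  aliases <- data.table::data.table(
    species = rep("worm", n_alias),
    alias = sprintf("sgn-%d", seq_len(n_alias)),
    canonical = alias_genes,
    provenance = rep("synthetic", n_alias))
  alias_lut <- stats::setNames(aliases$alias, aliases$canonical)
  for (i in which(organisms == "worm")) {
    raw <- per_study[[i]]$raw_id
    hit <- raw %in% names(alias_lut)
    raw[hit] <- alias_lut[raw[hit]]
    noise <- !hit & stats::runif(length(raw)) < cfg$isoform_noise_rate
    raw[noise] <- paste0(raw[noise], "a")
    per_study[[i]][, raw_id := raw]
  }

  # --- annotations / vocabulary / class incidence ------------------------
  vocab <- sprintf("class_%02d", seq_len(cfg$n_classes))
  ann_gene <- planted_set
  ann_class <- if (length(ann_gene))
    resample(vocab, length(ann_gene), replace = TRUE) else character()
  annotations <- data.table::data.table(gene = ann_gene,
                                        functional_class = ann_class,
                                        source = "synthetic")
  class_lut <- stats::setNames(ann_class, ann_gene)
  incidence <- data.table::rbindlist(lapply(seq_len(n_plant), function(k) {
    p <- planted[[k]]
    cls <- unique(stats::na.omit(class_lut[c(p$gene, p$partner)]))
    data.table::CJ(study_id = p$studies, functional_class = cls)
  }))
  if (nrow(incidence)) incidence <- unique(incidence)

  # --- PPI toy graph over the human labels -------------------------------
  ppi_n <- min(6L, length(human_labels))
  ppi <- if (ppi_n >= 2L) data.table::data.table(
    protein_a = human_labels[seq_len(ppi_n - 1L)],
    protein_b = human_labels[1L + seq_len(ppi_n - 1L)],
    provenance = "synthetic") else
    data.table::data.table(protein_a = character(), protein_b = character(),
                           provenance = character())

  studies <- data.table::data.table(
    study_id = study_id,
    organism = organisms,
    disease_models = vapply(seq_len(K), function(i)
      paste(sort(resample(DISEASE_MODEL_CODES,
                          resample(1:2, 1L))), collapse = ", "), ""),
    construct = "synthetic construct",
    screen_type = "Synthetic screen",
    n_reported = vapply(per_study, nrow, 0L),
    n_orthologues_expected = vapply(study_worm_sets, length, 0L),
    reference = "synthetic")

  structure(list(
    run_id = sprintf("synth-%d-%s", cfg$seed,
                     substr(paste(sizes, collapse = ""), 1L, 12L)),
    config = cfg,
    studies = studies,
    per_study_calls = stats::setNames(per_study, study_id),
    groups = as.character(c(unlist(groups), unlist(bg_groups))),
    aliases = aliases,
    vocabulary = vocab,
    annotations = annotations,
    ppi = ppi,
    planted = planted,
    planted_set = sort(planted_set),
    paralogue_groups = lapply(seq_len(n_pairs), function(j)
      sort(c(planted_gene[j], partner_gene[j]))),
    per_study = data.table::data.table(
      study_id = study_id,
      organism = organisms,
      n_hits = vapply(per_study, nrow, 0L),
      n_distinct_worm = vapply(study_worm_sets, length, 0L)),
    study_worm_sets = stats::setNames(study_worm_sets, study_id),
    n_distinct_total = length(unique(unlist(study_worm_sets))),
    class_incidence = incidence,
    human_labels = human_labels), class = "synthetic_truth")
}

synth_write_bundle <- function(truth, out_dir) {
  data.table::fwrite(truth$studies, file.path(out_dir, "studies.tsv"),
                     sep = "\t", quote = FALSE)
  for (sid in names(truth$per_study_calls)) {
    data.table::fwrite(truth$per_study_calls[[sid]],
                       file.path(out_dir, "genes", paste0(sid, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  writeLines(truth$groups, file.path(out_dir, "groups.txt"))
  data.table::fwrite(truth$aliases, file.path(out_dir, "aliases.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(truth$vocabulary, file.path(out_dir, "vocabulary.txt"))
  data.table::fwrite(truth$annotations, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(truth$ppi, file.path(out_dir, "ppi_edges.tsv"),
                     sep = "\t", quote = FALSE)
  writeLines(truth$run_id, file.path(out_dir, "run_id.txt"))
  manifest <- list(
    run_id = truth$run_id,
    seed = truth$config$seed,
    planted = lapply(truth$planted, function(p)
      list(gene = p$gene,
           partner = if (is.na(p$partner)) NULL else p$partner,
           studies = p$studies)),
    planted_set = truth$planted_set,
    paralogue_groups = truth$paralogue_groups,
    per_study = truth$per_study,
    n_distinct_total = truth$n_distinct_total)
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# Cheap consistency audit: the emitted files round-trip to the counts the
# truth manifest claims.
synth_verify_bundle <- function(truth, out_dir) {
  studies <- read_study_table(file.path(out_dir, "studies.tsv"))
  stopifnot(nrow(studies) == nrow(truth$studies))
  for (i in seq_len(nrow(studies))) {
    calls <- suppressWarnings(
      read_gene_list(file.path(out_dir, "genes",
                               paste0(studies$study_id[i], ".tsv")),
                     studies[i]))
    if (nrow(calls) != truth$per_study$n_hits[i]) {
      stop("bundle verification failed: hit-list size mismatch for ",
           studies$study_id[i], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate recovery of planted shared regulators
#'
#' Exact set comparison between the planted shared genes and the overlap
#' set a pipeline run recovered.
#'
#' @param truth A \code{synthetic_truth} (or the re-read \code{truth.json}).
#' @param overlaps An \code{overlap_set} from the pipeline run.
#' @param catalog Optional \code{regulator_catalog} for stage count deltas.
#' @param run_id Optional run identifier of the pipeline output; when given
#'   it must match the truth's \code{run_id}.
#' @return A list: \code{recall}, \code{precision}, \code{n_planted},
#'   \code{n_found}, \code{found_planted}, \code{vacuous} (\code{TRUE} when
#'   the planted set is empty, in which case recall is 1 by convention),
#'   \code{catalog_delta} (catalog size minus expected distinct count, when
#'   a catalog is given).
#' @export
evaluate_recovery <- function(truth, overlaps, catalog = NULL, run_id = NULL) {
  if (!is.null(run_id) && !identical(run_id, truth$run_id)) {
    stop("run identifier mismatch: truth is '", truth$run_id,
         "', pipeline output is '", run_id, "'", call. = FALSE)
  }
  planted <- truth$planted_set
  found <- sort(unique(unlist(overlaps$genes)))
  inter <- intersect(found, planted)
  vacuous <- length(planted) == 0L
  list(
    recall = if (vacuous) 1 else length(inter) / length(planted),
    precision = if (length(found)) length(inter) / length(found) else 1,
    n_planted = length(planted),
    n_found = length(found),
    found_planted = inter,
    vacuous = vacuous,
    catalog_delta = if (!is.null(catalog))
      nrow(catalog$entries) - truth$n_distinct_total else NA_integer_)
}
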