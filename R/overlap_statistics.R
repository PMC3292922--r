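# Overlap significance: is the observed number of genes recurring across
# >= 2 studies larger than expected for independent screens of the observed
# sizes drawn uniformly from a shared discovery universe?
#
# This is an explicit extension of the integration pipeline: the original
# analysis asserts a notable amount of sharing without a formal test. The
# null model here is deliberately simple — each study is an independent
# uniform draw without replacement — and carries no model of screen bias.

#' Null model configuration
#'
#' @param universe_size Number of reference-space genes eligible for
#'   discovery. A sensible default is [map_universe_size()] on the loaded
#'   orthology map (screens can only report mappable genes); the whole worm
#'   genome (~20000) is a conservative alternative for sensitivity analysis.
#' @param study_sizes Integer vector: distinct mapped worm genes per study.
#'   Every size must be between 0 and \code{universe_size}.
#' @param n_perm Number of permutation replicates (default 10000).
#' @param seed RNG seed for the permutation draw (default 17).
#' @return A list of class \code{null_model_config}.
#' @export
null_model_config <- function(universe_size, study_sizes, n_perm = 10000L,
                              seed = 17L) {
  universe_size <- as.integer(universe_size)
  study_sizes <- as.integer(study_sizes)
  if (length(universe_size) != 1L || is.na(universe_size) || universe_size < 1L)
    stop("universe_size must be a single positive integer", call. = FALSE)
  if (any(is.na(study_sizes) | study_sizes < 0L))
    stop("study_sizes must be non-negative integers", call. = FALSE)
  if (any(study_sizes > universe_size))
    stop("every study size must be <= universe_size", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be positive", call. = FALSE)
  structure(list(universe_size = universe_size, study_sizes = study_sizes,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "null_model_config")
}

#' Closed-form expected overlap count
#'
#' Exact expectation of the number of genes hit by two or more studies when
#' each study draws its hits uniformly without replacement from a shared
#' universe of size \eqn{U}, independently across studies. With
#' \eqn{p_i = s_i / U} the per-gene inclusion probability of study \eqn{i},
#' the expectation is
#' \deqn{U \left[1 - \prod_i (1 - p_i) - \sum_i p_i \prod_{j \ne i} (1 - p_j)\right],}
#' i.e. universe size times the per-gene probability of being hit at least
#' twice.
#'
#' @param config A \code{null_model_config}.
#' @return The expected count (a single real).
#' @examples
#' expected_overlap_closed_form(null_model_config(10, c(5, 5)))  # 2.5
#' @export
expected_overlap_closed_form <- function(config) {
  stopifnot(inherits(config, "null_model_config"))
  U <- config$universe_size
  p <- config$study_sizes / U
  if (any(p > 1)) stop("study size exceeds universe", call. = FALSE)
  if (length(p) < 2L) return(0)
  none <- prod(1 - p)
  exactly_one <- sum(vapply(seq_along(p), function(i)
    p[i] * prod(1 - p[-i]), 0))
  U * (1 - none - exactly_one)
}

#' Permutation null for the overlap count
#'
#' Draws \code{n_perm} independent replicates of the study ensemble — each
#' study a uniform subset without replacement of its observed size — and
#' counts, per replicate, the genes present in at least two subsets. The
#' p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + n_{perm})}, which is never 0.
#'
#' @param config A \code{null_model_config}.
#' @param observed Observed overlap count (non-negative integer).
#' @return A list of class \code{overlap_null}: \code{observed},
#'   \code{null_counts} (length \code{n_perm}), \code{mean_null},
#'   \code{sd_null}, \code{p_value}, \code{expectation_closed_form},
#'   \code{config}. Reproducible for a fixed seed; the caller's RNG state is
#'   left untouched.
#' @export
permutation_null <- function(config, observed) {
  stopifnot(inherits(config, "null_model_config"))
  observed <- as.integer(observed)
  if (is.na(observed) || observed < 0L)
    stop("observed must be a non-negative integer", call. = FALSE)
  U <- config$universe_size
  sizes <- config$study_sizes
  null_counts <- with_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(r) {
      hits <- unlist(lapply(sizes, function(s) sample.int(U, s)),
                     use.names = FALSE)
      sum(tabulate(hits, nbins = U) >= 2L)
    }, 0L)
  })
  structure(list(
    observed = observed,
    null_counts = null_counts,
    mean_null = mean(null_counts),
    sd_null = stats::sd(null_counts),
    p_value = (1 + sum(null_counts >= observed)) / (1 + config$n_perm),
    expectation_closed_form = expected_overlap_closed_form(config),
    config = config), class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat("Overlap permutation null (", x$config$n_perm, " replicates, seed ",
      x$config$seed, ")\n", sep = "")
  cat("  observed: ", x$observed, "\n  null mean: ",
      signif(x$mean_null, 4), " (closed form ",
      signif(x$expectation_closed_form, 4), ")\n  p-value: ",
      signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Overlap significance report for a pipeline run
#'
#' Binds the observed overlap count of a run to the permutation null.
#' Study sizes default to the per-study distinct worm-gene counts derivable
#' from the catalog evidence; the universe defaults to the distinct worm
#' genes reachable through the orthology map when one is supplied, else to
#' \code{universe_size}.
#'
#' @param catalog A \code{regulator_catalog}.
#' @param overlaps An \code{overlap_set} (observed count = number of
#'   entries).
#' @param map Optional \code{orthology_map} for the default universe.
#' @param universe_size Override for the universe size.
#' @param n_perm,seed Passed to [null_model_config()].
#' @param json_path Optional path; when given, a JSON report (observed,
#'   expectation, p-value, null quantiles) is written there.
#' @return An \code{overlap_null}.
#' @export
overlap_report <- function(catalog, overlaps, map = NULL, universe_size = NULL,
                           n_perm = 10000L, seed = 17L, json_path = NULL) {
  stopifnot(inherits(catalog, "regulator_catalog"))
  sizes <- if (nrow(catalog$evidence)) {
    catalog$evidence[, .(n = data.table::uniqueN(gene)), by = study_id]$n
  } else integer()
  if (is.null(universe_size)) {
    if (!is.null(map)) {
      universe_size <- max(map_universe_size(map), nrow(catalog$entries), 1L)
    } else {
      universe_size <- max(nrow(catalog$entries), 1L)
    }
  }
  observed <- nrow(overlaps)
  if (!length(sizes)) {
    cfg <- null_model_config(universe_size, integer(), n_perm = n_perm,
                             seed = seed)
    res <- structure(list(observed = observed,
                          null_counts = rep(0L, n_perm), mean_null = 0,
                          sd_null = 0, p_value = 1,
                          expectation_closed_form = 0, config = cfg),
                     class = "overlap_null")
  } else {
    cfg <- null_model_config(universe_size, sizes, n_perm = n_perm, seed = seed)
    res <- permutation_null(cfg, observed)
  }
  if (!is.null(json_path)) {
    q <- stats::quantile(res$null_counts, c(0.025, 0.5, 0.975), names = FALSE)
    jsonlite::write_json(list(
      observed = res$observed,
      universe_size = cfg$universe_size,
      study_sizes = cfg$study_sizes,
      n_perm = cfg$n_perm,
      seed = cfg$seed,
      expectation_closed_form = res$expectation_closed_form,
      mean_null = res$mean_null,
      null_q025 = q[1], null_median = q[2], null_q975 = q[3],
      p_value = res$p_value), json_path, auto_unbox = TRUE, digits = NA)
  }
  res
}
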