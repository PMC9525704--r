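# End-to-end orchestration: simulate (or ingest) -> preprocess -> AMGM filter
# (mRNA-like mode only) -> graph selection -> classification -> class-rule
# mining -> report. One master seed derives every stage seed, so a config
# reproduces its run exactly.

#' Pipeline configuration
#'
#' `mode = "mrna"` inserts the AMGM top-k pre-filter before the graph stage
#' (defaults k = 1000, beta = 0.5); `mode = "mirna"` builds the graph on all
#' retained features (beta = 0.6). gamma defaults to 0.3 and the rule-mining
#' thresholds to min-support 0.1, max-length 4, lift 1.1 in both modes.
#'
#' @param mode `"mrna"` or `"mirna"`.
#' @param sim A [sim_config()] used when no cohort is passed to
#'   [run_pipeline()].
#' @param k Top-k cut of the AMGM filter (mrna mode).
#' @param beta,gamma Graph blend and adjacency threshold parameters.
#' @param fractions Hold-out train/validation/test fractions.
#' @param min_support,max_length,min_lift FP-Growth / rule thresholds.
#' @param exact_cap Exact-MIS community size cap.
#' @param classifier `"sodae"`, `"mlp_baseline"` or `"nearest_centroid"`.
#' @param classifier_opts A [classifier_config()]; its seed is overridden by
#'   the derived stage seed.
#' @param stages Character vector of stages to run after selection:
#'   any of `"classify"`, `"mine"`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory for stage artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("mrna", "mirna"),
                            sim = NULL,
                            k = 1000L,
                            beta = NULL,
                            gamma = 0.3,
                            fractions = c(train = 0.7, validation = 0.1, test = 0.2),
                            min_support = 0.1,
                            max_length = 4L,
                            min_lift = 1.1,
                            exact_cap = 25L,
                            classifier = "sodae",
                            classifier_opts = classifier_config(),
                            stages = c("classify", "mine"),
                            seed = 1L,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  beta <- beta %||% if (mode == "mrna") 0.5 else 0.6
  stopifnot(beta > 0, beta < 1, gamma > 0, gamma < 1,
            min_support > 0, min_support <= 1, max_length >= 1, min_lift > 0)
  structure(
    list(mode = mode, sim = sim, k = as.integer(k), beta = beta, gamma = gamma,
         fractions = fractions, min_support = min_support,
         max_length = as.integer(max_length), min_lift = min_lift,
         exact_cap = as.integer(exact_cap), classifier = classifier,
         classifier_opts = classifier_opts, stages = stages,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the discovery pipeline end to end
#'
#' @param config A [pipeline_config()].
#' @param data Optional cohort tibble; when omitted, a cohort is generated
#'   from `config$sim` with the derived simulate seed.
#' @return A `pipeline_run` with the panel, partitioned data, evaluation
#'   reports, class rules, repeat-count tables and a manifest.
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(data)) {
    if (is.null(config$sim)) abort("stage simulate: no cohort and no sim_config given")
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    data <- generate_cohort(sim)
  }
  .assert_cohort(data)

  # -- preprocess -------------------------------------------------------------
  retained <- remove_redundant_features(data)
  split <- split_holdout(retained, config$fractions,
                         seed = derive_seed(config$seed, "split"))
  params <- normalization_params(split)
  scaled <- minmax_normalize(split, params)
  zscored <- zscore_normalize(split, params)

  # -- filter (mrna mode) + graph selection ----------------------------------
  # AMGM needs the bounded min-max scale (it exponentiates values); the
  # redundancy cosine runs on the z-scored data, where it equals the absolute
  # Pearson correlation between features.
  scores <- amgm_scores(scaled)
  selected <- if (config$mode == "mrna") {
    select_top_k(scores, min(config$k, nrow(scores)))
  } else {
    scores
  }
  graph <- build_feature_graph(
    zscored[c(intersect(.meta_cols, names(zscored)), selected$feature_id)],
    selected, config$beta
  )
  graph <- softmax_scale(graph)
  partition <- louvain_partition(graph, seed = derive_seed(config$seed, "louvain"))
  adjacency <- threshold_adjacency(graph, config$gamma)
  panel <- select_candidates(graph, partition, adjacency, exact_cap = config$exact_cap)

  # -- classification ---------------------------------------------------------
  reports <- NULL
  model <- NULL
  if ("classify" %in% config$stages) {
    opts <- config$classifier_opts
    opts$seed <- derive_seed(config$seed, "classifier")
    model <- fit_classifier(scaled, panel$feature_id, config$classifier, opts)
    reports <- lapply(c("train", "validation", "test"), function(part) {
      evaluate(model, dplyr::filter(scaled, .data$partition == part), part)
    })
    names(reports) <- c("train", "validation", "test")
  }

  # -- class-rule mining (pooled cohort, fresh [0,1] scaling) -----------------
  rules <- NULL
  repeat_tables <- NULL
  if ("mine" %in% config$stages) {
    pooled <- retained[c("sample_id", "subtype", panel$feature_id)]
    pool_params <- normalization_params(pooled, panel$feature_id)
    db <- discretize_panel(minmax_normalize(pooled, pool_params), panel$feature_id)
    subtypes <- sort(unique(data$subtype))
    class_items <- vapply(subtypes, class_item, character(1))
    itemsets <- mine_frequent(db, config$min_support, config$max_length,
                              focus_items = class_items)
    rules <- generate_rules(itemsets, db, config$min_lift,
                            consequent_items = class_items)
    repeat_tables <- lapply(subtypes, function(s) {
      repeat_counts(filter_class_rules(rules, s))
    })
    names(repeat_tables) <- subtypes
  }

  run <- structure(
    list(config = config, data = split, scaled = scaled, params = params,
         scores = scores, selected = selected, graph = graph,
         partition = partition, panel = panel, model = model,
         reports = reports, rules = rules, repeat_tables = repeat_tables),
    class = "pipeline_run"
  )
  run$manifest <- .build_manifest(run, t0)
  if (!is.null(config$out_dir)) .write_artifacts(run, config$out_dir)
  run
}

# Checksums of the run's deterministic tabular artifacts (serialised
# in-memory), plus config snapshot and timing.
.build_manifest <- function(run, t0) {
  chk <- function(x) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
  }
  stages <- list(
    split = run$data["partition"],
    scores = run$scores,
    panel = as.data.frame(run$panel),
    communities = as.data.frame(run$partition),
    rules = if (is.null(run$rules)) NULL else
      list(n = nrow(run$rules),
           ante = unlist(run$rules$antecedent, use.names = FALSE),
           ante_len = lengths(run$rules$antecedent),
           cons = unlist(run$rules$consequent, use.names = FALSE),
           support = run$rules$support,
           confidence = run$rules$confidence,
           lift = run$rules$lift),
    metrics = if (is.null(run$reports)) NULL else
      lapply(run$reports, function(r) r$per_class)
  )
  structure(
    list(
      config = run$config,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(utils::packageVersion("panelomics")),
      checksums = vapply(stages[!vapply(stages, is.null, logical(1))],
                         chk, character(1))
    ),
    class = "run_manifest"
  )
}

.write_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$scores, file.path(out_dir, "amgm_scores.tsv"))
  readr::write_tsv(as.data.frame(run$panel), file.path(out_dir, "candidate_panel.tsv"))
  readr::write_tsv(as.data.frame(run$partition), file.path(out_dir, "communities.tsv"))
  readr::write_tsv(run$data[c("sample_id", "partition")],
                   file.path(out_dir, "split.tsv"))
  readr::write_tsv(run$params, file.path(out_dir, "normalization_params.tsv"))
  if (!is.null(run$reports)) {
    metrics <- dplyr::bind_rows(lapply(run$reports, tidy),
                                .id = "partition")
    readr::write_tsv(metrics, file.path(out_dir, "classifier_metrics.tsv"))
    jsonlite::write_json(lapply(run$reports, function(r) as.list(glance(r))),
                         file.path(out_dir, "classifier_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(run$rules)) {
    # rules can run to millions; persist the strongest 100k by support
    top <- utils::head(dplyr::arrange(run$rules, dplyr::desc(.data$support)), 1e5)
    flat <- dplyr::mutate(
      top,
      antecedent = vapply(.data$antecedent, paste, character(1), collapse = ","),
      consequent = vapply(.data$consequent, paste, character(1), collapse = ",")
    )
    readr::write_tsv(flat, file.path(out_dir, "class_rules.tsv"))
    for (s in names(run$repeat_tables)) {
      readr::write_tsv(run$repeat_tables[[s]],
                       file.path(out_dir, paste0("repeat_counts_", s, ".tsv")))
    }
  }
  invisible(out_dir)
}

#' Export a feature graph to disk
#'
#' @param graph A `feature_graph` (scaled; see [softmax_scale()]).
#' @param path Output path.
#' @param format `"edgelist"` (TSV of upper-triangle edges) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "feature_graph"))
  if (format == "edgelist") {
    readr::write_tsv(tidy(graph), path)
  } else {
    adj <- if (is.null(graph$w_hat)) graph$w else graph$w_hat
    diag(adj) <- 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Summarise a pipeline run
#'
#' Writes (or returns) a deterministic summary: panel size, community count,
#' per-partition metrics and the top-10 repeat-count features per subtype.
#' Sections for disabled stages are marked absent.
#'
#' @param run A `pipeline_run`.
#' @param out_dir Optional directory; writes `summary.json` and `summary.txt`.
#' @return The summary list, invisibly when writing.
#' @export
report_run <- function(run, out_dir = NULL) {
  stopifnot(inherits(run, "pipeline_run"))
  summary <- list(
    mode = run$config$mode,
    n_samples = nrow(run$data),
    n_features_input = length(feature_names(run$data)),
    n_features_selected = nrow(run$selected),
    n_communities = attr(run$partition, "n_communities"),
    modularity = attr(run$partition, "modularity"),
    panel_size = nrow(run$panel),
    beta = run$config$beta,
    gamma = run$config$gamma,
    metrics = if (is.null(run$reports)) "absent" else
      lapply(run$reports, function(r) as.list(glance(r))),
    class_rules = if (is.null(run$rules)) "absent" else {
      counts <- lapply(run$repeat_tables, function(tb) sum(tb$repeat_count))
      list(
        n_rules = nrow(run$rules),
        top_features = lapply(run$repeat_tables, function(tb) {
          utils::head(as.list(stats::setNames(tb$repeat_count, tb$feature_id)), 10)
        })
      )
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(
      sprintf("pipeline mode: %s", summary$mode),
      sprintf("samples: %d | input features: %d | after filter: %d",
              summary$n_samples, summary$n_features_input, summary$n_features_selected),
      sprintf("communities: %d (modularity %.4f) | panel size: %d",
              summary$n_communities, summary$modularity, summary$panel_size),
      if (identical(summary$metrics, "absent")) "classification: absent" else
        sprintf("%s accuracy: %.1f%%", names(run$reports),
                vapply(run$reports, function(r) r$accuracy_multiclass, numeric(1))),
      if (identical(summary$class_rules, "absent")) "rule mining: absent" else
        sprintf("class rules: %d", summary$class_rules$n_rules)
    )
    writeLines(txt, file.path(out_dir, "summary.txt"))
    return(invisible(summary))
  }
  summary
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- report_run(x)
  cat(sprintf("<pipeline_run> %s mode: %d samples, %d -> %d -> %d features\n",
              s$mode, s$n_samples, s$n_features_input, s$n_features_selected,
              s$panel_size))
  if (!identical(s$metrics, "absent")) {
    cat(sprintf("test accuracy (multiclass): %.1f%%\n",
                x$reports$test$accuracy_multiclass))
  }
  if (!identical(s$class_rules, "absent")) {
    cat(sprintf("class-consequent rules: %d\n", s$class_rules$n_rules))
  }
  invisible(x)
}
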