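#' Evaluate classification methods on a collection over a network
#'
#' End-to-end driver for one network x collection combination: builds labeled
#' tasks (positives + selected negatives), restricts them to network genes,
#' constructs the validation split(s), applies the minimum-positives task
#' filter, computes the feature representations each requested method needs
#' (once, shared across tasks), runs every method on every task and returns
#' the per-(geneset, method, metric) evaluation records.
#'
#' For cross-validation, each metric is computed per fold and averaged across
#' folds; the reported prior is the mean of the fold priors and the log2
#' prior ratio is recomputed from those means.
#'
#' @param network a [gene_network].
#' @param collection a preprocessed [geneset_collection].
#' @param methods character vector among `"LP-A"`, `"LP-I"`, `"SL-A"`,
#'   `"SL-I"`, `"SL-E"`.
#' @param scheme `"cv_fold"` (default), `"temporal"` or `"study_bias"`.
#' @param k folds for cross-validation.
#' @param seed seed for fold shuffling and embeddings.
#' @param min_positives task filter threshold (default 10).
#' @param p_threshold Fisher threshold for negative selection (default 0.05).
#' @param alpha RWR restart probability (default 0.85).
#' @param C logistic-regression inverse regularization (default 1).
#' @param node2vec list of extra arguments for [embed_node2vec()].
#' @param cutoff_date temporal-split cutoff.
#' @param train_fraction study-bias training fraction.
#' @return data.frame of evaluation records (`geneset_id`, `method`,
#'   `metric`, `raw_value`, `prior`, `log2_ratio`), with attribute
#'   `"n_tasks"`.
#' @export
evaluate_collection <- function(network, collection, methods,
                                scheme = c("cv_fold", "temporal", "study_bias"),
                                k = 5, seed = 1, min_positives = 10,
                                p_threshold = 0.05, alpha = 0.85, C = 1.0,
                                node2vec = list(), cutoff_date = "2017-01-01",
                                train_fraction = 2 / 3) {
  scheme <- match.arg(scheme)
  methods <- match.arg(methods, c("LP-A", "LP-I", "SL-A", "SL-I", "SL-E"),
                       several.ok = TRUE)
  tasks <- build_tasks(collection, p_threshold)
  tasks <- lapply(tasks, function(t) {
    suppressMessages(restrict_task_to_network(t, network))
  })

  config <- list(alpha = alpha, C = C, node2vec = node2vec, seed = seed,
                 features = feature_cache(network, methods, alpha, node2vec,
                                          seed))

  if (scheme == "temporal") {
    split <- temporal_split(collection, cutoff_date)
    splits_of <- function(task) list(split)
  } else if (scheme == "study_bias") {
    genes <- intersect(annotated_genes(collection), network$nodes)
    split <- study_bias_split(genes, collection$pub_counts, train_fraction)
    splits_of <- function(task) list(split)
  } else {
    splits_of <- function(task) stratified_kfold(task, k = k, seed = seed)
  }

  records <- list()
  kept <- 0L
  for (task in tasks) {
    # For the holdout schemes the minimum-positives rule applies to both
    # sides of the split; for k-fold CV it applies to the geneset's total
    # positive count (a 1/k test fold of a qualifying set may be smaller).
    if (scheme == "cv_fold") {
      if (length(task$positives) < max(min_positives, k) ||
          length(task$negatives) < k) next
    }
    splits <- tryCatch(splits_of(task), error = function(e) NULL)
    if (is.null(splits)) next
    if (scheme != "cv_fold" &&
        length(filter_tasks(list(task), splits, min_positives)) == 0L) next
    kept <- kept + 1L
    for (method in methods) {
      fold_rows <- lapply(splits, function(split) {
        res <- run_method(method, network, task, split, config)
        evaluate_result(res, task)
      })
      merged <- fold_rows[[1L]]
      if (length(fold_rows) > 1L) {
        merged$raw_value <- rowMeans(vapply(fold_rows, `[[`,
                                            numeric(nrow(merged)),
                                            "raw_value"))
        merged$prior <- rowMeans(vapply(fold_rows, `[[`,
                                        numeric(nrow(merged)), "prior"))
        has_ratio <- !is.na(merged$log2_ratio)
        merged$log2_ratio[has_ratio] <-
          log2_prior_ratio(merged$raw_value[has_ratio],
                           merged$prior[has_ratio])
      }
      records[[length(records) + 1L]] <- merged
    }
  }
  if (kept == 0L) {
    stop("no tasks survive the minimum-positives filter under scheme '",
         scheme, "'")
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "n_tasks") <- kept
  out
}

feature_cache <- function(network, methods, alpha, node2vec, seed) {
  cache <- list()
  needs <- function(kinds) any(methods %in% kinds)
  if (needs(c("LP-A", "SL-A", "LP-I", "SL-I"))) {
    cache$adjacency <- adjacency(network)
  }
  if (needs(c("LP-I", "SL-I"))) {
    cache$influence <- suppressWarnings(
      rwr_influence(cache$adjacency, alpha = alpha))
  }
  if (needs("SL-E")) {
    cache$embedding <- do.call(
      embed_node2vec, c(list(network = network, seed = seed), node2vec))
  }
  cache
}

#' Per-geneset competition ranks and average rank from evaluation records
#'
#' @param records output of [evaluate_collection()].
#' @param metric metric used for ranking (default `"auPRC"`).
#' @return list with `per_geneset` (list of rank maps) and `average` (named
#'   numeric vector of mean ranks).
#' @export
rank_methods <- function(records, metric = "auPRC") {
  r <- records[records$metric == metric, , drop = FALSE]
  per_geneset <- lapply(split(r, r$geneset_id), function(d) {
    competition_rank(setNames(d$raw_value, d$method))
  })
  list(per_geneset = per_geneset, average = average_rank(per_geneset))
}

#' Per-method vectors of a metric, aligned by geneset
#'
#' @param records output of [evaluate_collection()].
#' @param metric metric name.
#' @param value `"raw_value"` or `"log2_ratio"`.
#' @return named list of equal-length numeric vectors, one per method.
#' @export
metric_by_method <- function(records, metric = "auPRC", value = "raw_value") {
  r <- records[records$metric == metric, , drop = FALSE]
  ids <- sort(unique(r$geneset_id))
  methods <- sort(unique(r$method))
  setNames(lapply(methods, function(m) {
    d <- r[r$method == m, , drop = FALSE]
    d[[value]][match(ids, d$geneset_id)]
  }), methods)
}

#' Run a configured benchmark and write its outputs
#'
#' Orchestrates a full benchmark run from a configuration list (or a YAML
#' file with the same fields): load or simulate the inputs, preprocess the
#' geneset collection, evaluate the requested methods under the requested
#' validation scheme, and write four artifacts to `output_dir`:
#' `metrics.tsv` (per-task evaluation records), `average_rank.tsv`,
#' `verdict.json` (cross-class significance, when all four core methods were
#' run) and `manifest.json` (config echo, seed, package version).
#'
#' Config fields: either `simulate` (a list of [sim_config()] arguments) or
#' `network_path` + `gmt_path` (+ optional `ontology_path`, `dates_path`,
#' `counts_path`); `methods`; `scheme`; `k`; `seed`; `alpha`; `C`;
#' `node2vec`; `min_positives`; `p_threshold`; `min_size`; `max_size`;
#' `jaccard_threshold`; `max_memberships`; `preprocess` (default TRUE);
#' `output_dir`.
#'
#' @param config a named list, or the path of a YAML file encoding one.
#' @return list with `records`, `ranks`, `verdict` (or NULL) and `paths`,
#'   invisibly.
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::yaml.load_file(config)
  }
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, c(config$simulate,
                                 if (is.null(config$simulate$seed))
                                   list(seed = seed)))
    sim <- generate_planted_network(cfg)
    collection <- add_annotation_artifacts(sim$collection, cfg)
    network <- sim$network
  } else {
    network <- read_edge_list(config$network_path)
    collection <- read_gmt(config$gmt_path)
    if (!is.null(config$ontology_path)) {
      collection$ontology <- read_ontology_tsv(config$ontology_path)
    }
    if (!is.null(config$dates_path)) {
      collection$dates <- read_dates_tsv(config$dates_path)
    }
    if (!is.null(config$counts_path)) {
      collection$pub_counts <- read_counts_tsv(config$counts_path)
    }
  }

  if (isTRUE(config$preprocess %||% TRUE)) {
    collection <- preprocess_collection(
      collection,
      min_size = config$min_size %||% 10,
      max_size = config$max_size %||% 200,
      jaccard_threshold = config$jaccard_threshold %||% 0.5,
      max_memberships = config$max_memberships %||% 10)
  }
  message(length(collection$sets), " geneset(s) after preprocessing")

  methods <- config$methods %||% c("SL-A", "SL-I", "LP-A", "LP-I")
  records <- evaluate_collection(
    network, collection, methods,
    scheme = config$scheme %||% "cv_fold",
    k = config$k %||% 5, seed = seed,
    min_positives = config$min_positives %||% 10,
    p_threshold = config$p_threshold %||% 0.05,
    alpha = config$alpha %||% 0.85, C = config$C %||% 1.0,
    node2vec = config$node2vec %||% list())
  message(attr(records, "n_tasks"), " task(s) evaluated")

  paths <- c(metrics = file.path(out_dir, "metrics.tsv"),
             ranks = file.path(out_dir, "average_rank.tsv"),
             verdict = file.path(out_dir, "verdict.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write.table(records, paths[["metrics"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ranks <- NULL
  if (length(unique(records$method)) >= 2L) {
    ranks <- rank_methods(records)
    write.table(data.frame(method = names(ranks$average),
                           average_rank = unname(ranks$average)),
                paths[["ranks"]], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "ranks"]
  }

  verdict <- NULL
  core <- c("SL-A", "SL-I", "LP-A", "LP-I")
  if (all(core %in% methods)) {
    verdict <- class_significance(
      metric_by_method(records)[core],
      id = paste(network$name, collection$name, sep = " x "))
    jsonlite::write_json(
      list(id = verdict$id,
           winner = if (is.na(verdict$winner)) NULL else verdict$winner,
           winner_class = if (is.na(verdict$winner_class)) NULL else
             verdict$winner_class,
           win_fraction = verdict$win_fraction,
           adjusted_p_values = as.list(verdict$adjusted_p_values)),
      paths[["verdict"]], auto_unbox = TRUE, digits = NA, null = "null")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("genenetbench")),
    r_version = R.version.string,
    seed = seed,
    methods = methods,
    config = config[setdiff(names(config), "features")])
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)

  invisible(list(records = records, ranks = ranks, verdict = verdict,
                 paths = paths))
}
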