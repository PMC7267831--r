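#' Train/test gene partition
#'
#' @param scheme one of `"temporal"`, `"study_bias"`, `"cv_fold"`.
#' @param train_genes,test_genes disjoint character vectors of gene ids.
#' @param fold_index optional fold number for cross-validation splits.
#' @return an object of class `labeled_split`.
#' @export
labeled_split <- function(scheme, train_genes, test_genes, fold_index = NULL) {
  scheme <- match.arg(scheme, c("temporal", "study_bias", "cv_fold"))
  train_genes <- sort(unique(as.character(train_genes)))
  test_genes <- sort(unique(as.character(test_genes)))
  if (length(intersect(train_genes, test_genes)) > 0L) {
    stop("train and test gene sets must be disjoint")
  }
  structure(list(scheme = scheme, train_genes = train_genes,
                 test_genes = test_genes, fold_index = fold_index),
            class = "labeled_split")
}

#' @export
print.labeled_split <- function(x, ...) {
  cat(sprintf("<labeled_split[%s%s]: %d train, %d test>\n", x$scheme,
              if (!is.null(x$fold_index)) paste0(" fold ", x$fold_index) else "",
              length(x$train_genes), length(x$test_genes)))
  invisible(x)
}

#' Temporal-holdout split
#'
#' Genes whose every annotation in the collection is dated strictly after
#' `cutoff_date` become test genes; all other annotated genes are training
#' genes. This mimics predicting the future from current knowledge: a single
#' pre-cutoff annotation keeps a gene in training.
#'
#' @param collection a [geneset_collection] whose `dates` cover every
#'   (gene, set) annotation pair.
#' @param cutoff_date cutoff (default `"2017-01-01"`).
#' @return a [labeled_split] with scheme `"temporal"`.
#' @export
temporal_split <- function(collection, cutoff_date = "2017-01-01") {
  if (is.null(collection$dates)) stop("collection has no annotation dates")
  cutoff <- as.Date(cutoff_date)
  ann <- data.frame(
    gene = unlist(collection$sets, use.names = FALSE),
    set = rep(names(collection$sets), lengths(collection$sets)),
    stringsAsFactors = FALSE)
  key <- paste(ann$gene, ann$set, sep = "\r")
  dkey <- paste(collection$dates$gene, collection$dates$set, sep = "\r")
  hit <- match(key, dkey)
  if (anyNA(hit)) {
    offenders <- unique(paste0(ann$gene[is.na(hit)], " in ",
                               ann$set[is.na(hit)]))
    stop("missing annotation dates for: ",
         paste(utils::head(offenders, 10L), collapse = ", "),
         if (length(offenders) > 10L) ", ..." else "")
  }
  ann$date <- collection$dates$date[hit]
  earliest <- tapply(ann$date, ann$gene, min)
  test <- names(earliest)[earliest > cutoff]
  train <- setdiff(unique(ann$gene), test)
  if (length(test) == 0L) {
    warning("temporal split has an empty test set (no gene first annotated ",
            "after ", format(cutoff), ")")
  }
  labeled_split("temporal", train, test)
}

#' Study-bias holdout split
#'
#' Ranks genes by publication count (descending, ties broken
#' lexicographically by gene id) and assigns the top `train_fraction` as
#' training genes (well-studied) and the remainder as test genes
#' (understudied). The training side takes the ceiling when the fraction does
#' not divide evenly.
#'
#' @param genes character vector of gene ids to split.
#' @param pubmed_counts named numeric vector of per-gene publication counts;
#'   genes missing from it count as 0 (logged).
#' @param train_fraction fraction assigned to training, in (0, 1); default 2/3.
#' @return a [labeled_split] with scheme `"study_bias"`.
#' @export
study_bias_split <- function(genes, pubmed_counts, train_fraction = 2 / 3) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  genes <- sort(unique(as.character(genes)))
  counts <- pubmed_counts[genes]
  missing <- is.na(counts)
  if (any(missing)) {
    message(sum(missing), " gene(s) without a publication count treated as 0")
    counts[missing] <- 0
  }
  o <- order(-counts, genes)
  n_train <- ceiling(train_fraction * length(genes))
  labeled_split("study_bias",
                train_genes = genes[o][seq_len(n_train)],
                test_genes = genes[o][-seq_len(n_train)])
}

#' Stratified k-fold cross-validation splits
#'
#' Shuffles positives and negatives separately (seeded) and deals them
#' round-robin into `k` folds, so each fold's class counts differ from
#' perfect proportionality by at most one.
#'
#' @param task a [labeled_task].
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return list of `k` [labeled_split] objects with scheme `"cv_fold"`; the
#'   test set of fold `i` is the i-th fold, training is the rest.
#' @export
stratified_kfold <- function(task, k = 5, seed = 1) {
  pos <- task$positives
  neg <- task$negatives
  if (length(pos) < k || length(neg) < k) {
    stop("need at least k positives and k negatives for ", k, "-fold CV")
  }
  with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
  })
  fold_of <- function(x) rep(seq_len(k), length.out = length(x))
  all_genes <- c(pos, neg)
  fold <- c(fold_of(pos), fold_of(neg))
  lapply(seq_len(k), function(i) {
    labeled_split("cv_fold",
                  train_genes = all_genes[fold != i],
                  test_genes = all_genes[fold == i],
                  fold_index = i)
  })
}

#' Keep tasks with enough positives on both sides of a split
#'
#' @param tasks list of [labeled_task] objects.
#' @param split a [labeled_split], or a list of them (e.g. CV folds), in
#'   which case every fold must satisfy the bound.
#' @param min_positives smallest acceptable positive count in train and in
#'   test (default 10).
#' @return the retained subset of `tasks`.
#' @export
filter_tasks <- function(tasks, split, min_positives = 10) {
  splits <- if (inherits(split, "labeled_split")) list(split) else split
  ok <- vapply(tasks, function(task) {
    all(vapply(splits, function(s) {
      length(intersect(task$positives, s$train_genes)) >= min_positives &&
        length(intersect(task$positives, s$test_genes)) >= min_positives
    }, TRUE))
  }, TRUE)
  tasks[ok]
}

#' Restrict a task to genes present in a network
#'
#' Genes in a task but absent from the network have no feature row and are
#' dropped before splitting, with a message.
#'
#' @param task a [labeled_task].
#' @param network a [gene_network].
#' @return the restricted [labeled_task].
#' @export
restrict_task_to_network <- function(task, network) {
  pos <- intersect(task$positives, network$nodes)
  neg <- intersect(task$negatives, network$nodes)
  dropped <- (length(task$positives) - length(pos)) +
    (length(task$negatives) - length(neg))
  if (dropped > 0L) {
    message(dropped, " task gene(s) absent from the network dropped")
  }
  labeled_task(task$geneset_id, pos, neg)
}

#' Serialize a split as JSON
#'
#' @param split a [labeled_split].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(
    list(scheme = split$scheme, fold_index = split$fold_index,
         train = split$train_genes, test = split$test_genes),
    path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

# run code under a temporary RNG state without touching the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}
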