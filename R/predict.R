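#' Label propagation scores
#'
#' Implements one-step label propagation S = M x over a feature matrix M
#' (adjacency or influence). The label vector x has 1 at each training
#' positive and 0 elsewhere, so with the adjacency matrix a gene's score is
#' the summed weight of its edges to positively labeled direct neighbors,
#' and with the influence matrix it is the summed random-walk influence
#' received from the positives. An optional signed mode additionally sets -1
#' at training negatives.
#'
#' @param features a [feature_matrix] of kind `"adjacency"` or `"influence"`.
#' @param train_positives gene ids labeled positive for training.
#' @param test_genes gene ids to score (must be nodes of the network).
#' @param use_negatives if TRUE, training negatives enter `x` as -1.
#' @param train_negatives gene ids labeled negative (signed mode only).
#' @param geneset_id label recorded in the result.
#' @return a [prediction_result].
#' @export
label_propagate <- function(features, train_positives, test_genes,
                            use_negatives = FALSE, train_negatives = NULL,
                            geneset_id = "") {
  if (!features$kind %in% c("adjacency", "influence")) {
    stop("label propagation needs adjacency or influence features")
  }
  nodes <- features$node_order
  pos <- intersect(train_positives, nodes)
  if (length(pos) < length(unique(train_positives))) {
    warning(length(unique(train_positives)) - length(pos),
            " training positive(s) absent from the network dropped")
  }
  if (length(pos) == 0L) stop("no training positives present in the network")
  missing_test <- setdiff(test_genes, nodes)
  if (length(missing_test) > 0L) {
    stop("test gene(s) absent from the network: ",
         paste(utils::head(missing_test, 5L), collapse = ", "))
  }
  x <- numeric(length(nodes))
  x[match(pos, nodes)] <- 1
  if (use_negatives) {
    neg <- intersect(train_negatives, nodes)
    x[match(neg, nodes)] <- -1
  }
  s <- drop(features$values %*% x)
  method <- if (features$kind == "adjacency") "LP-A" else "LP-I"
  prediction_result(geneset_id, method,
                    setNames(s[match(test_genes, nodes)], test_genes))
}

#' Train an L2-regularized logistic regression on gene feature rows
#'
#' Fits weights `w` and intercept `c` minimizing
#' \deqn{\tfrac12 w^\top w + C \sum_i \log(1 + e^{-y_i (x_i^\top w + c)})}
#' with labels y in \{-1, +1\}, i.e. ridge-penalized logistic regression with
#' an unpenalized intercept and inverse regularization strength `C`
#' (default 1). Features are used as-is — network rows have meaningful scale,
#' so no standardization is applied. The objective is minimized by L-BFGS
#' with an analytic gradient; the optimizer is deterministic.
#'
#' @param features a [feature_matrix].
#' @param train_positives,train_negatives disjoint, nonempty gene id sets
#'   present in the network.
#' @param C inverse regularization strength (> 0).
#' @param maxit maximum optimizer iterations.
#' @param tol relative convergence tolerance of the optimizer (`factr` scale).
#' @return an object of class `sl_model` with fields `w`, `intercept`, `C`,
#'   `kind` and `converged`.
#' @export
train_sl <- function(features, train_positives, train_negatives, C = 1.0,
                     maxit = 1000, tol = 1e-9) {
  if (C <= 0) stop("C must be positive")
  nodes <- features$node_order
  pos <- intersect(unique(train_positives), nodes)
  neg <- intersect(unique(train_negatives), nodes)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must have at least one training gene in the network")
  }
  genes <- c(pos, neg)
  y <- c(rep(1, length(pos)), rep(-1, length(neg)))
  X <- features$values[match(genes, nodes), , drop = FALSE]
  m <- ncol(X)

  # theta = (w, c); objective of the penalized logistic model above
  obj <- function(theta) {
    w <- theta[seq_len(m)]
    b <- theta[m + 1L]
    z <- -y * (drop(X %*% w) + b)
    0.5 * sum(w^2) + C * sum(log1p(exp(pmin(z, 50))) + pmax(z - 50, 0))
  }
  grad <- function(theta) {
    w <- theta[seq_len(m)]
    b <- theta[m + 1L]
    s <- plogis(-y * (drop(X %*% w) + b))  # sigmoid(z)
    gy <- -C * y * s
    c(w + drop(crossprod(X, gy)), sum(gy))
  }
  fit <- optim(numeric(m + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = tol / .Machine$double.eps))
  structure(list(w = fit$par[seq_len(m)], intercept = fit$par[m + 1L],
                 C = C, kind = features$kind,
                 converged = fit$convergence == 0L),
            class = "sl_model")
}

#' Predict class probabilities for test genes
#'
#' Applies the logistic function to `w' x + c` for each test gene's feature
#' row; scores are probabilities in (0, 1).
#'
#' @param model an [sl_model][train_sl].
#' @param features the [feature_matrix] the model was trained on (same
#'   feature dimension).
#' @param test_genes gene ids to score.
#' @param geneset_id label recorded in the result.
#' @return a [prediction_result].
#' @export
predict_sl <- function(model, features, test_genes, geneset_id = "") {
  if (length(model$w) != ncol(features$values)) {
    stop("model dimensionality does not match the feature matrix")
  }
  idx <- match(test_genes, features$node_order)
  if (anyNA(idx)) {
    stop("test gene(s) absent from the network: ",
         paste(utils::head(test_genes[is.na(idx)], 5L), collapse = ", "))
  }
  X <- features$values[idx, , drop = FALSE]
  s <- plogis(drop(X %*% model$w) + model$intercept)
  method <- c(adjacency = "SL-A", influence = "SL-I", embedding = "SL-E")[model$kind]
  prediction_result(geneset_id, unname(method), setNames(s, test_genes))
}

#' Prediction scores for the test genes of one task
#'
#' @param geneset_id task id.
#' @param method one of `"LP-A"`, `"LP-I"`, `"SL-A"`, `"SL-I"`, `"SL-E"`.
#' @param scores named numeric vector (gene id -> score).
#' @return an object of class `prediction_result`.
#' @export
prediction_result <- function(geneset_id, method, scores) {
  method <- match.arg(method, c("LP-A", "LP-I", "SL-A", "SL-I", "SL-E"))
  structure(list(geneset_id = geneset_id, method = method, scores = scores),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result '%s' %s: %d scored genes>\n",
              x$geneset_id, x$method, length(x$scores)))
  invisible(x)
}

#' Run one classification method on one task and split
#'
#' Dispatch layer tying methods to representations: LP-A / LP-I call
#' [label_propagate()] on adjacency / influence features; SL-A / SL-I / SL-E
#' call [train_sl()] + [predict_sl()] on adjacency / influence / embedding
#' rows. Training uses the task's positives (and, for SL, negatives)
#' restricted to the split's training genes; scores are returned for the
#' task's test-side positives and negatives present in the network.
#'
#' @param method method name.
#' @param network a [gene_network].
#' @param task a [labeled_task].
#' @param split a [labeled_split].
#' @param config list of options; recognized entries: `alpha` (RWR restart,
#'   default 0.85), `C` (SL regularization, default 1), `node2vec` (list of
#'   [embed_node2vec()] arguments), `seed` (embedding seed, default 1),
#'   `use_negatives` (signed LP mode, default FALSE), and `features` — an
#'   optional named list caching precomputed feature matrices under
#'   `"adjacency"`, `"influence"`, `"embedding"` to avoid recomputation
#'   across tasks.
#' @return a [prediction_result].
#' @export
run_method <- function(method, network, task, split, config = list()) {
  method <- match.arg(method, c("LP-A", "LP-I", "SL-A", "SL-I", "SL-E"))
  kind <- switch(method,
                 "LP-A" = "adjacency", "SL-A" = "adjacency",
                 "LP-I" = "influence", "SL-I" = "influence",
                 "SL-E" = "embedding")
  features <- config$features[[kind]]
  if (is.null(features)) {
    features <- switch(kind,
      adjacency = adjacency(network),
      influence = rwr_influence(adjacency(network),
                                alpha = config$alpha %||% 0.85),
      embedding = do.call(embed_node2vec,
                          c(list(network = network,
                                 seed = config$seed %||% 1),
                            config$node2vec)))
  }
  task <- suppressMessages(restrict_task_to_network(task, network))
  train_pos <- intersect(task$positives, split$train_genes)
  train_neg <- intersect(task$negatives, split$train_genes)
  test_genes <- intersect(c(task$positives, task$negatives), split$test_genes)
  if (startsWith(method, "LP")) {
    label_propagate(features, train_pos, test_genes,
                    use_negatives = isTRUE(config$use_negatives),
                    train_negatives = train_neg,
                    geneset_id = task$geneset_id)
  } else {
    model <- train_sl(features, train_pos, train_neg,
                      C = config$C %||% 1.0)
    predict_sl(model, features, test_genes, geneset_id = task$geneset_id)
  }
}

#' Write prediction results as TSV
#'
#' Columns: geneset id, method, gene id, score, label (1 for task positives,
#' 0 for negatives, NA otherwise).
#'
#' @param results list of [prediction_result] objects.
#' @param task the [labeled_task] supplying the labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(results, task, path) {
  rows <- do.call(rbind, lapply(results, function(r) {
    genes <- names(r$scores)
    data.frame(geneset_id = r$geneset_id, method = r$method, gene = genes,
               score = unname(r$scores),
               label = ifelse(genes %in% task$positives, 1L,
                              ifelse(genes %in% task$negatives, 0L, NA)),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
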