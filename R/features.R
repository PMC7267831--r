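#' Per-gene feature matrix
#'
#' Container tying a numeric matrix to the network node order it was computed
#' in. Row `i` is the feature vector of `node_order[i]`. Three kinds are used
#' throughout the package: `"adjacency"` (rows of the weighted adjacency
#' matrix), `"influence"` (rows of the random-walk-with-restart kernel) and
#' `"embedding"` (low-dimensional node2vec vectors).
#'
#' @param values numeric matrix, one row per node.
#' @param node_order character vector of gene ids, one per row.
#' @param kind one of `"adjacency"`, `"influence"`, `"embedding"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, node_order, kind) {
  kind <- match.arg(kind, c("adjacency", "influence", "embedding"))
  values <- as.matrix(values)
  if (nrow(values) != length(node_order)) {
    stop("values must have one row per node")
  }
  rownames(values) <- node_order
  structure(list(values = values, node_order = as.character(node_order),
                 kind = kind),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix[%s]: %d nodes x %d features>\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Random-walk-with-restart influence matrix
#'
#' Computes the influence matrix
#' \deqn{F = \alpha (I - (1-\alpha) W_D)^{-1}}
#' where \eqn{W_D = A D^{-1}} is the column-normalized (degree-weighted)
#' adjacency matrix and \eqn{D} is the diagonal matrix of weighted node
#' degrees. `alpha` is the restart probability: at each step the walker
#' returns to its seed with probability `alpha`, so `alpha = 1` gives the
#' identity matrix (no diffusion) and smaller values diffuse further. Each
#' column of F sums to 1 when every node has positive degree. Columns of
#' zero-degree nodes reduce to `alpha` times the corresponding unit vector and
#' are kept with a warning.
#'
#' @param A a [feature_matrix] of kind `"adjacency"` (or a plain symmetric
#'   non-negative matrix with dimnames).
#' @param alpha restart probability in (0, 1]; default 0.85.
#' @return a [feature_matrix] of kind `"influence"`, same node order as `A`.
#' @export
rwr_influence <- function(A, alpha = 0.85) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  if (inherits(A, "feature_matrix")) {
    nodes <- A$node_order
    M <- A$values
  } else {
    M <- as.matrix(A)
    nodes <- rownames(M)
    if (is.null(nodes)) nodes <- as.character(seq_len(nrow(M)))
  }
  if (nrow(M) != ncol(M)) stop("adjacency matrix must be square")
  if (any(M < 0)) stop("adjacency matrix must be non-negative")
  deg <- colSums(M)
  if (any(deg == 0)) {
    warning(sum(deg == 0), " zero-degree node(s): their influence column is ",
            "alpha times the unit vector")
  }
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  WD <- M * rep(inv_deg, each = nrow(M))  # A %*% diag(1/deg), column-normalized
  n <- nrow(M)
  FF <- alpha * solve(diag(n) - (1 - alpha) * WD)
  feature_matrix(FF, nodes, kind = "influence")
}

#' node2vec embeddings of a gene network
#'
#' Learns one d-dimensional vector per node with the node2vec algorithm:
#' second-order biased random walks (return parameter `p`, in-out parameter
#' `q`, edge weights entering transition probabilities multiplicatively)
#' followed by skip-gram with negative sampling over the walk corpus. Low
#' `p` and `q` (the defaults, 0.1) make walks revisit-averse and exploratory
#' at the same time; `p = q = 1` reduces to unbiased weighted random walks.
#'
#' Training is single-threaded and fully determined by `seed`.
#'
#' @param network a [gene_network].
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @param dim embedding dimension, must be < number of nodes.
#' @param walk_length steps per walk.
#' @param num_walks walks started per node.
#' @param window skip-gram context window.
#' @param epochs passes of skip-gram training over the walk corpus.
#' @param negative negative samples per positive pair.
#' @param learning_rate initial stochastic-gradient learning rate (decays
#'   linearly to 1/10 of the initial value).
#' @param seed integer seed controlling walks, initialization and sampling.
#' @return a [feature_matrix] of kind `"embedding"` with `dim` columns.
#' @export
embed_node2vec <- function(network, p = 0.1, q = 0.1, dim = 128,
                           walk_length = 80, num_walks = 10, window = 10,
                           epochs = 1, negative = 5, learning_rate = 0.025,
                           seed = 1) {
  stopifnot(p > 0, q > 0, walk_length >= 1, num_walks >= 1, window >= 1,
            epochs >= 1, negative >= 1)
  nodes <- network$nodes
  n <- length(nodes)
  if (dim >= n) stop("embedding dimension must be smaller than the number of nodes")
  e <- network$edges
  i <- match(e$from, nodes)
  j <- match(e$to, nodes)
  nbr <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_along(i)) {
    nbr[[i[k]]] <- c(nbr[[i[k]]], j[k])
    wts[[i[k]]] <- c(wts[[i[k]]], e$weight[k])
    nbr[[j[k]]] <- c(nbr[[j[k]]], i[k])
    wts[[j[k]]] <- c(wts[[j[k]]], e$weight[k])
  }
  deg0 <- vapply(nbr, length, 0L)
  if (any(deg0 == 0L)) {
    warning(sum(deg0 == 0L), " isolated node(s): their walks have length 1")
  }
  # sort each neighbor list so the C++ side can binary-search adjacency
  for (v in seq_len(n)) {
    if (deg0[v] > 0L) {
      o <- order(nbr[[v]])
      nbr[[v]] <- nbr[[v]][o]
      wts[[v]] <- wts[[v]][o]
    }
  }
  off <- c(0L, cumsum(deg0))
  adj <- as.integer(unlist(nbr, use.names = FALSE)) - 1L
  adj_w <- as.numeric(unlist(wts, use.names = FALSE))
  if (is.null(adj)) adj <- integer(0)
  emb <- node2vec_embed_cpp(as.integer(off), adj, adj_w, n,
                            p, q, as.integer(dim), as.integer(walk_length),
                            as.integer(num_walks), as.integer(window),
                            as.integer(epochs), as.integer(negative),
                            learning_rate, as.integer(seed))
  feature_matrix(emb, nodes, kind = "embedding")
}

#' Write node embeddings as word2vec-style text
#'
#' Format: a header line `<n> <dim>` followed by one line per node:
#' `<gene-id> v1 ... vd`.
#'
#' @param features a [feature_matrix] (typically kind `"embedding"`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embedding_text <- function(features, path) {
  v <- features$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(v), ncol(v)), con)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(features$node_order[i],
                       formatC(v[i, ], format = "g", digits = 8)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read word2vec-style text embeddings
#'
#' @param path file written by [write_embedding_text()] (or by word2vec-style
#'   tools).
#' @return a [feature_matrix] of kind `"embedding"`, rows in lexicographic
#'   node order.
#' @export
read_embedding_text <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  body <- strsplit(lines[-1L], " +")
  ids <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(hdr[2L])))
  o <- order(ids)
  feature_matrix(vals[o, , drop = FALSE], ids[o], kind = "embedding")
}

#' Write a feature matrix as TSV with a sidecar node-order file
#'
#' @param features a [feature_matrix].
#' @param path TSV path for the values; the node order is written to
#'   `paste0(path, ".nodes")`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(features$node_order, paste0(path, ".nodes"))
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @param kind feature kind of the stored matrix.
#' @return a [feature_matrix].
#' @export
read_feature_matrix <- function(path, kind) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  nodes <- readLines(paste0(path, ".nodes"))
  dimnames(vals) <- NULL
  feature_matrix(vals, nodes, kind = kind)
}
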