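#' Construct a weighted undirected gene network
#'
#' A `gene_network` stores an undirected, weighted graph over string gene
#' identifiers. Edges are canonicalized so that `(u, v)` and `(v, u)` are the
#' same edge, self-loops are disallowed, weights are strictly positive, and
#' the node order is fixed lexicographically so that matrices derived from
#' the network are reproducible across runs.
#'
#' @param edges data.frame with columns `from`, `to` (character) and
#'   optionally `weight` (positive numeric; defaults to 1).
#' @param nodes optional character vector of additional node ids that may
#'   have no incident edges (e.g. isolated genes).
#' @param name network label used in reports.
#' @param collapse how to resolve duplicate edges; only `"max"` is supported,
#'   keeping the largest weight seen for a pair.
#'
#' @return An object of class `gene_network` with components `nodes`
#'   (lexicographically sorted character vector), `edges` (data.frame
#'   `from`/`to`/`weight` with `from < to`) and `name`.
#' @export
gene_network <- function(edges, nodes = NULL, name = "network",
                         collapse = "max") {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("from", "to") %in% names(edges))) {
      stop("edges must have columns 'from' and 'to'")
    }
    if (is.null(edges$weight)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$weight <- as.numeric(edges$weight)
    if (anyNA(edges$weight) || any(edges$weight < 0)) {
      stop("edge weights must be non-negative numbers")
    }
    loops <- edges$from == edges$to
    if (any(loops)) {
      message(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    edges <- edges[edges$weight > 0, , drop = FALSE]
    if (nrow(edges) > 0L) {
      u <- pmin(edges$from, edges$to)
      v <- pmax(edges$from, edges$to)
      key <- paste(u, v, sep = "\r")
      w <- tapply(edges$weight, key, max)
      parts <- strsplit(names(w), "\r", fixed = TRUE)
      edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                          to = vapply(parts, `[`, "", 2L),
                          weight = as.numeric(w),
                          stringsAsFactors = FALSE)
    }
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = all_nodes, edges = edges, name = name),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges
#' @param network a `gene_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Load a gene network from an edge-list TSV
#'
#' Reads a tab- or whitespace-separated edge list with two columns
#' (`gene1 gene2`, all weights 1) or three columns (`gene1 gene2 weight`).
#' Lines beginning with `#` are skipped. Duplicate edges collapse keeping the
#' maximum weight; self-loops are dropped with a message.
#'
#' @param path file path.
#' @param weighted `NA` to infer from the column count, otherwise TRUE/FALSE.
#' @param min_weight optional lower weight cutoff; edges strictly below it are
#'   discarded (default 0, i.e. no filtering).
#' @param name network label; defaults to the file name.
#' @return a [gene_network].
#' @export
read_edge_list <- function(path, weighted = NA, min_weight = 0,
                           name = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge-list line %d: '%s'",
                 idx[bad[1L]], lines[idx[bad[1L]]]))
  }
  has_w <- nf == 3L
  if (is.na(weighted)) weighted <- any(has_w)
  w <- rep(1, length(fields))
  if (weighted) {
    if (any(has_w)) {
      w[has_w] <- suppressWarnings(
        as.numeric(vapply(fields[has_w], `[`, "", 3L)))
      if (anyNA(w)) {
        bad <- idx[which(is.na(w))[1L]]
        stop(sprintf("malformed weight on line %d", bad))
      }
      if (any(w < 0)) {
        bad <- idx[which(w < 0)[1L]]
        stop(sprintf("negative weight on line %d", bad))
      }
    }
  } else {
    w <- rep(1, length(fields))
  }
  edges <- data.frame(from = vapply(fields, `[`, "", 1L),
                      to = vapply(fields, `[`, "", 2L),
                      weight = w, stringsAsFactors = FALSE)
  if (min_weight > 0) edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  gene_network(edges, name = name)
}

#' Write a gene network as an edge-list TSV
#'
#' @param network a [gene_network].
#' @param path output file path.
#' @param weighted include the weight column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, weighted = TRUE) {
  e <- network$edges
  if (weighted) {
    out <- sprintf("%s\t%s\t%.10g", e$from, e$to, e$weight)
  } else {
    out <- sprintf("%s\t%s", e$from, e$to)
  }
  writeLines(out, path)
  invisible(path)
}

#' Re-map gene identifiers, expanding one-to-many mappings
#'
#' Every edge `(u, v, w)` yields edges `(u', v', w)` for all `u'` in
#' `mapping[[u]]` and `v'` in `mapping[[v]]` with `u' != v'`; duplicates
#' collapse by maximum weight. Nodes without a mapping entry are dropped with
#' a message. This mirrors the convention of adding edges between all
#' possible identifier mappings when converting a network to a common gene
#' namespace.
#'
#' @param network a [gene_network].
#' @param mapping either a named list (source id -> character vector of
#'   target ids) or a two-column data.frame (`source`, `target`) where
#'   repeated source rows express one-to-many mappings.
#' @return a re-mapped [gene_network].
#' @export
apply_id_mapping <- function(network, mapping) {
  if (is.data.frame(mapping)) {
    if (nrow(mapping) == 0L) stop("mapping is empty")
    mapping <- split(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  }
  if (!is.list(mapping) || length(mapping) == 0L) stop("mapping is empty")
  e <- network$edges
  unmapped <- setdiff(network$nodes, names(mapping))
  if (length(unmapped) > 0L) {
    message(length(unmapped), " unmapped node(s) dropped")
  }
  keep <- e$from %in% names(mapping) & e$to %in% names(mapping)
  e <- e[keep, , drop = FALSE]
  if (nrow(e) > 0L) {
    pieces <- lapply(seq_len(nrow(e)), function(i) {
      us <- mapping[[e$from[i]]]
      vs <- mapping[[e$to[i]]]
      grid <- expand.grid(from = us, to = vs, stringsAsFactors = FALSE)
      grid$weight <- e$weight[i]
      grid
    })
    e <- do.call(rbind, pieces)
  }
  mapped_nodes <- unique(unlist(mapping[intersect(network$nodes, names(mapping))],
                                use.names = FALSE))
  gene_network(e, nodes = mapped_nodes, name = network$name)
}

#' Weighted adjacency matrix of a network
#'
#' Returns the symmetric \eqn{|V| \times |V|} adjacency matrix A in the
#' network's (lexicographic) node order, wrapped as a [feature_matrix] of
#' kind `"adjacency"` so it can feed both label propagation and supervised
#' learning directly.
#'
#' @param network a nonempty [gene_network].
#' @return a [feature_matrix] of kind `"adjacency"`.
#' @export
adjacency <- function(network) {
  nodes <- network$nodes
  if (length(nodes) == 0L) stop("network has no nodes")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e) > 0L) {
    i <- match(e$from, nodes)
    j <- match(e$to, nodes)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  feature_matrix(A, nodes, kind = "adjacency")
}
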