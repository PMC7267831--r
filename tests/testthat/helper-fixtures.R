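# Shared fixture builders. Everything is generated in code; no data files.

# network from a compact edge spec: list(c("a","b",0.5), ...)
net_from <- function(..., nodes = NULL, name = "fixture") {
  specs <- list(...)
  edges <- data.frame(
    from = vapply(specs, function(e) as.character(e[[1L]]), ""),
    to = vapply(specs, function(e) as.character(e[[2L]]), ""),
    weight = vapply(specs, function(e) {
      if (length(e) >= 3L) as.numeric(e[[3L]]) else 1
    }, 0),
    stringsAsFactors = FALSE)
  gene_network(edges, nodes = nodes, name = name)
}

# path graph a - b - c with unit weights
path_network <- function() net_from(c("a", "b"), c("b", "c"))

# Erdos-Renyi fixture with unit weights, labeled g01..gNN
random_network <- function(n, p, seed, weights = FALSE) {
  withr::local_seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(genes, 2))
  hit <- runif(nrow(pairs)) < p
  w <- if (weights) runif(sum(hit), 0.1, 1) else rep(1, sum(hit))
  gene_network(data.frame(from = pairs[hit, 1L], to = pairs[hit, 2L],
                          weight = w, stringsAsFactors = FALSE),
               nodes = genes)
}

# truncated Neumann-series oracle for the RWR influence matrix
rwr_power_series <- function(A, alpha, K = 200) {
  deg <- colSums(A)
  WD <- A * rep(ifelse(deg > 0, 1 / deg, 0), each = nrow(A))
  acc <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(K)) {
    term <- term %*% ((1 - alpha) * WD)
    acc <- acc + term
  }
  alpha * acc
}

# three-set collection from the negative-selection worked example
worked_collection <- function() {
  geneset_collection(list(
    S1 = sprintf("g%02d", 1:10),
    S2 = c(sprintf("g%02d", 1:9), "g11"),
    S3 = sprintf("g%02d", 15:20)))
}

tmp_write <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}

# all n! permutations of 1..n (small n only)
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (k in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = k - 1L)
      row <- row + 1L
    }
  }
  out
}
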