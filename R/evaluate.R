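#' Ranking order used by the precision metrics
#'
#' Genes are ranked by descending score; exact score ties are broken by
#' ascending gene id so every metric is reproducible.
#' @noRd
rank_order <- function(scores) {
  order(-scores, names(scores))
}

check_two_classes <- function(labels) {
  if (all(labels == labels[1L])) {
    stop("test set must contain both positives and negatives")
  }
}

align_labels <- function(scores, labels) {
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    labels <- labels[names(scores)]
    if (anyNA(labels)) stop("every scored gene needs a label")
  }
  as.numeric(labels)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision: the sum over positive-ranked positions of
#' the precision at that position, weighted by the recall increment
#' (equivalently the mean precision at the rank of each positive). Score ties
#' are broken deterministically by gene id.
#'
#' @param scores named numeric vector of per-gene scores.
#' @param labels named vector of 0/1 labels (1 = positive) covering the
#'   scored genes.
#' @return the average precision in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- align_labels(scores, labels)
  check_two_classes(labels)
  y <- labels[rank_order(scores)]
  ranks_of_pos <- which(y == 1)
  mean(cumsum(y)[ranks_of_pos] / ranks_of_pos)
}

#' Precision among the top-K ranked genes
#'
#' By default K equals the number of test positives, so a perfect ranking
#' scores 1 and a random ranking scores the class prior in expectation.
#'
#' @inheritParams auprc
#' @param K number of top predictions to inspect (default: positive count).
#' @return fraction of the top K that are positives.
#' @export
p_at_topk <- function(scores, labels, K = NULL) {
  labels <- align_labels(scores, labels)
  if (is.null(K)) K <- sum(labels == 1)
  if (K < 1) stop("K must be >= 1")
  if (K > length(scores)) stop("K exceeds the number of scored genes")
  y <- labels[rank_order(scores)]
  mean(y[seq_len(K)] == 1)
}

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with score ties counting one half (Mann-Whitney
#' convention).
#'
#' @inheritParams auprc
#' @return the auROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- align_labels(scores, labels)
  check_two_classes(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)  # average ranks implement the half-credit tie rule
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Prior-normalized performance on the log2 scale
#'
#' Expresses a precision-driven metric relative to the prior (the fraction of
#' positives among test genes, i.e. the expected precision of a random
#' ranking): 0 means no better than chance, 1 means twice better, and a
#' perfect ranking reaches `-log2(prior)`. A raw value of 0 maps to `-Inf`.
#'
#' @param raw metric value in [0, 1].
#' @param prior class prior in (0, 1).
#' @return `log2(raw / prior)`.
#' @export
log2_prior_ratio <- function(raw, prior) {
  if (any(prior <= 0 | prior >= 1)) stop("prior must be in (0, 1)")
  ifelse(raw == 0, -Inf, log2(raw / prior))
}

#' Class prior of a labeled test set
#'
#' @param labels 0/1 labels.
#' @return positives / (positives + negatives).
#' @export
class_prior <- function(labels) {
  mean(as.numeric(labels) == 1)
}

#' Standard competition ("1224") ranking
#'
#' The highest value receives rank 1; tied values share the smallest rank of
#' their group; the next distinct value's rank is 1 plus the number of
#' strictly better entries.
#'
#' @param values named numeric vector (method -> metric value).
#' @return named integer vector of ranks.
#' @export
competition_rank <- function(values) {
  if (length(values) < 2L) stop("need at least two methods to rank")
  r <- rank(-unlist(values), ties.method = "min")
  setNames(as.integer(r), names(values))
}

#' Average rank of each method across genesets
#'
#' @param per_geneset_ranks list of rank maps as returned by
#'   [competition_rank()], one per geneset, all over the same methods.
#' @return named numeric vector of mean ranks.
#' @export
average_rank <- function(per_geneset_ranks) {
  if (length(per_geneset_ranks) == 0L) stop("no rank maps supplied")
  methods <- sort(names(per_geneset_ranks[[1L]]))
  ok <- vapply(per_geneset_ranks,
               function(r) identical(sort(names(r)), methods), TRUE)
  if (!all(ok)) stop("rank maps cover inconsistent method sets")
  out <- rowMeans(vapply(per_geneset_ranks, function(r) unlist(r)[methods],
                         numeric(length(methods))))
  setNames(out, methods)
}

#' Wilcoxon signed-rank test for paired per-geneset performance
#'
#' Two-sided paired test on `paired_a - paired_b`. Zero differences are
#' excluded (classical signed-rank procedure); the reported win counts are
#' the raw numbers of genesets where each side is strictly better, counted
#' before exclusion. The null distribution is exact (via the signed-rank
#' distribution) when n <= 25 and the absolute differences are untied,
#' otherwise a normal approximation with continuity and tie correction is
#' used.
#'
#' @param paired_a,paired_b equal-length numeric vectors of per-geneset
#'   metric values for two methods.
#' @return list with `p_value`, `n_a_wins`, `n_b_wins`, `n_used` (pairs after
#'   zero removal), `statistic` (V, the positive-rank sum) and `degenerate`
#'   (TRUE when all differences are zero; then `p_value` is 1).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop("paired vectors must have equal length")
  }
  d <- paired_a - paired_b
  n_a_wins <- sum(d > 0)
  n_b_wins <- sum(d < 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p_value = 1, n_a_wins = 0L, n_b_wins = 0L, n_used = 0L,
                statistic = NA_real_, degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- 2 * min(psignrank(V, n), psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  list(p_value = p, n_a_wins = n_a_wins, n_b_wins = n_b_wins, n_used = n,
       statistic = V, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted values (monotone, capped at 1).
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Cross-class significance verdict for SL versus LP
#'
#' Runs the four cross-class paired comparisons (SL-A vs LP-A, SL-A vs LP-I,
#' SL-I vs LP-A, SL-I vs LP-I) with [wilcoxon_signed_rank()], BH-adjusts the
#' four p-values, and declares a method significantly better than the other
#' class when it wins more genesets than each opposing method and both
#' adjusted p-values are below `alpha`. If both methods of a class win this
#' way, the whole class is the winner. Also reports the fraction of the
#' `4 * n` pairwise geneset comparisons won by the SL side.
#'
#' @param per_geneset_auprc named list of equal-length numeric vectors for
#'   methods `SL-A`, `SL-I`, `LP-A`, `LP-I` (one value per geneset, aligned).
#' @param alpha significance level on the adjusted p-values (default 0.05).
#' @param id label for the collection-network combination.
#' @return an object of class `comparison_verdict`: list with `id`, `winner`
#'   (method name, `"SL"`, `"LP"`, or `NA`), `winner_class`, `win_fraction`,
#'   `adjusted_p_values` and the per-comparison detail table.
#' @export
class_significance <- function(per_geneset_auprc, alpha = 0.05, id = "") {
  need <- c("SL-A", "SL-I", "LP-A", "LP-I")
  if (!all(need %in% names(per_geneset_auprc))) {
    stop("need per-geneset values for all of: ", paste(need, collapse = ", "))
  }
  lens <- lengths(per_geneset_auprc[need])
  if (length(unique(lens)) != 1L) stop("per-method vectors must be aligned")
  comparisons <- list(c("SL-A", "LP-A"), c("SL-A", "LP-I"),
                      c("SL-I", "LP-A"), c("SL-I", "LP-I"))
  tests <- lapply(comparisons, function(cmp) {
    wilcoxon_signed_rank(per_geneset_auprc[[cmp[1L]]],
                         per_geneset_auprc[[cmp[2L]]])
  })
  raw_p <- vapply(tests, `[[`, 0, "p_value")
  adj_p <- bh_fdr(raw_p)
  cmp_names <- vapply(comparisons, paste, "", collapse = " vs ")
  detail <- data.frame(
    comparison = cmp_names,
    sl_wins = vapply(tests, `[[`, 0L, "n_a_wins"),
    lp_wins = vapply(tests, `[[`, 0L, "n_b_wins"),
    p_value = raw_p, adjusted_p = adj_p, stringsAsFactors = FALSE)

  beats_both <- function(meth, side) {
    rows <- grepl(meth, detail$comparison, fixed = TRUE)
    if (side == "SL") {
      all(detail$sl_wins[rows] > detail$lp_wins[rows] &
            detail$adjusted_p[rows] < alpha)
    } else {
      all(detail$lp_wins[rows] > detail$sl_wins[rows] &
            detail$adjusted_p[rows] < alpha)
    }
  }
  winners <- c(
    if (beats_both("SL-A", "SL")) "SL-A",
    if (beats_both("SL-I", "SL")) "SL-I",
    if (beats_both("LP-A", "LP")) "LP-A",
    if (beats_both("LP-I", "LP")) "LP-I")
  winner_class <- NA_character_
  winner <- NA_character_
  if (all(c("SL-A", "SL-I") %in% winners)) {
    winner <- "SL"; winner_class <- "SL"
  } else if (all(c("LP-A", "LP-I") %in% winners)) {
    winner <- "LP"; winner_class <- "LP"
  } else if (length(winners) == 1L) {
    winner <- winners
    winner_class <- if (startsWith(winners, "SL")) "SL" else "LP"
  }
  n <- lens[[1L]]
  win_fraction <- sum(detail$sl_wins) / (4 * n)
  structure(list(id = id, winner = winner, winner_class = winner_class,
                 win_fraction = win_fraction,
                 adjusted_p_values = setNames(adj_p, cmp_names),
                 detail = detail),
            class = "comparison_verdict")
}

#' @export
print.comparison_verdict <- function(x, ...) {
  cat(sprintf("<comparison_verdict%s: winner = %s, SL win fraction = %.2f>\n",
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              if (is.na(x$winner)) "none" else x$winner, x$win_fraction))
  invisible(x)
}

#' Edge density of a geneset within a network
#'
#' Total within-geneset edge weight divided by the number of possible member
#' pairs `n (n - 1) / 2`, where `n` counts geneset members present in the
#' network. For an unweighted graph this is the usual density of the induced
#' subgraph.
#'
#' @param network a [gene_network].
#' @param geneset character vector of gene ids.
#' @return the edge density (>= 0; <= 1 for unit weights).
#' @export
edge_density <- function(network, geneset) {
  members <- intersect(geneset, network$nodes)
  n <- length(members)
  if (n < 2L) stop("geneset must have at least 2 members in the network")
  e <- network$edges
  within <- e$from %in% members & e$to %in% members
  sum(e$weight[within]) / (n * (n - 1) / 2)
}

#' Segregation of a geneset within a network
#'
#' Fraction of the total edge weight incident to geneset members that stays
#' inside the geneset (each within edge counted once). 1 means the set is an
#' isolated component; 0 means members only connect outward.
#'
#' @inheritParams edge_density
#' @return segregation in [0, 1].
#' @export
segregation <- function(network, geneset) {
  members <- intersect(geneset, network$nodes)
  e <- network$edges
  touch <- e$from %in% members | e$to %in% members
  if (!any(touch)) stop("geneset members have no incident edges")
  within <- e$from %in% members & e$to %in% members
  sum(e$weight[within]) / sum(e$weight[touch])
}

#' Spearman correlation between geneset properties and performance
#'
#' Rank correlation with a seeded bootstrap percentile confidence interval,
#' used to relate geneset network properties (edge density, segregation) to
#' per-geneset prediction performance.
#'
#' @param properties,performances equal-length numeric vectors (>= 10).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list with `rho`, `conf_int` (length 2), `degenerate` (TRUE when an
#'   input is constant; then `rho` is NA).
#' @export
property_performance_correlation <- function(properties, performances,
                                             n_boot = 1000, conf = 0.95,
                                             seed = 1) {
  if (length(properties) != length(performances)) {
    stop("inputs must have equal length")
  }
  if (length(properties) < 10L) stop("need at least 10 paired observations")
  if (length(unique(properties)) == 1L || length(unique(performances)) == 1L) {
    return(list(rho = NA_real_, conf_int = c(NA_real_, NA_real_),
                degenerate = TRUE))
  }
  rho <- cor(properties, performances, method = "spearman")
  n <- length(properties)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(properties[idx])) == 1L ||
          length(unique(performances[idx])) == 1L) return(NA_real_)
      cor(properties[idx], performances[idx], method = "spearman")
    }, 0)
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(rho = rho, conf_int = unname(qs), degenerate = FALSE)
}

#' Evaluate a prediction result against its task
#'
#' Computes auPRC, P@TopK (K = number of test positives) and auROC on the
#' test genes, plus the class prior and the log2 prior-normalized values of
#' the two precision metrics.
#'
#' @param result a [prediction_result].
#' @param task the [labeled_task] supplying labels.
#' @return data.frame with one row per metric: columns `geneset_id`,
#'   `method`, `metric`, `raw_value`, `prior`, `log2_ratio`.
#' @export
evaluate_result <- function(result, task) {
  genes <- names(result$scores)
  labels <- setNames(as.integer(genes %in% task$positives), genes)
  prior <- class_prior(labels)
  vals <- c(auPRC = auprc(result$scores, labels),
            `P@TopK` = p_at_topk(result$scores, labels),
            auROC = auroc(result$scores, labels))
  data.frame(geneset_id = result$geneset_id, method = result$method,
             metric = names(vals), raw_value = unname(vals), prior = prior,
             log2_ratio = c(log2_prior_ratio(vals[1L], prior),
                            log2_prior_ratio(vals[2L], prior), NA),
             stringsAsFactors = FALSE, row.names = NULL)
}
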