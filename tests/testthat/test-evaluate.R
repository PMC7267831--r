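# exhaustive-enumeration oracles for the ranking metrics
oracle_ap <- function(scores, labels) {
  o <- order(-scores, names(scores))
  y <- as.numeric(labels[names(scores)])[o]
  hits <- which(y == 1)
  mean(vapply(hits, function(k) sum(y[1:k]) / k, 0))
}
oracle_auroc <- function(scores, labels) {
  y <- as.numeric(labels[names(scores)])
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

named_scores <- function(v) setNames(v, sprintf("g%02d", seq_along(v)))

test_that("auPRC matches hand enumeration and closed forms", {
  s <- named_scores(c(0.9, 0.8, 0.7, 0.6))
  l <- setNames(c(1, 0, 1, 0), names(s))
  expect_equal(auprc(s, l), (1 + 2 / 3) / 2)
  # perfect ranking
  expect_equal(auprc(s, setNames(c(1, 1, 0, 0), names(s))), 1.0)
  # single positive ranked last among n
  n <- 7
  s2 <- named_scores(seq(1, 0.1, length.out = n))
  l2 <- setNames(c(rep(0, n - 1), 1), names(s2))
  expect_equal(auprc(s2, l2), 1 / n)
  expect_error(auprc(s, setNames(rep(1, 4), names(s))), "both positives")
})

test_that("ranking metrics match exhaustive enumeration over all 6-gene orders", {
  # all 6! orderings of distinct scores with 2 positives in fixed gene slots
  genes <- sprintf("g%02d", 1:6)
  labels <- setNames(c(1, 1, 0, 0, 0, 0), genes)
  perms <- combinat_perms(6)
  for (i in seq_len(nrow(perms))) {
    s <- setNames((7 - perms[i, ]) / 10, genes)  # distinct scores
    expect_equal(auprc(s, labels), oracle_ap(s, labels))
    expect_equal(auroc(s, labels), oracle_auroc(s, labels))
    k <- 2
    top <- names(sort(s, decreasing = TRUE))[1:k]
    expect_equal(p_at_topk(s, labels, k), mean(labels[top] == 1))
  }
})

test_that("P@TopK defaults K to the positive count and validates bounds", {
  s <- named_scores(c(0.9, 0.8, 0.7, 0.6))
  l <- setNames(c(1, 0, 1, 0), names(s))
  expect_equal(p_at_topk(s, l, 2), 0.5)
  expect_equal(p_at_topk(s, l), 0.5)  # K defaults to 2 positives
  expect_equal(p_at_topk(s, setNames(c(1, 1, 0, 0), names(s))), 1.0)
  expect_error(p_at_topk(s, l, 0), "K must be")
  expect_error(p_at_topk(s, l, 5), "exceeds")
})

test_that("random rankings average to the prior", {
  # P@TopK is exactly unbiased at any size; average precision carries a
  # small-sample upward bias that vanishes for realistic test-set sizes,
  # so the auPRC check runs at 1000 genes (see the methods vignette)
  withr::local_seed(1)
  genes <- sprintf("g%02d", 1:10)
  labels <- setNames(c(rep(1, 3), rep(0, 7)), genes)
  pk <- vapply(seq_len(2000), function(i) {
    p_at_topk(setNames(sample(10) / 10, genes), labels)
  }, 0)
  expect_lt(abs(mean(pk) - 0.3), 0.01)

  big <- sprintf("g%04d", 1:1000)
  scores <- setNames(seq(1, 0.001, length.out = 1000), big)
  base <- c(rep(1, 100), rep(0, 900))
  ap <- vapply(seq_len(2000), function(i) {
    auprc(scores, setNames(sample(base), big))
  }, 0)
  expect_lt(abs(mean(ap) - 0.1), 0.01)
})

test_that("auROC uses the half-credit tie convention", {
  s <- named_scores(c(0.9, 0.8, 0.7, 0.6))
  expect_equal(auroc(s, setNames(c(1, 0, 1, 0), names(s))), 3 / 4)
  expect_equal(auroc(s, setNames(c(1, 1, 0, 0), names(s))), 1.0)
  tied <- named_scores(rep(0.5, 6))
  expect_equal(auroc(tied, setNames(c(1, 0, 1, 0, 1, 0), names(tied))), 0.5)
})

test_that("log2 prior normalization has its fixed points and sentinel", {
  expect_equal(log2_prior_ratio(0.25, 0.25), 0)
  expect_equal(log2_prior_ratio(1, 0.25), 2)
  expect_identical(log2_prior_ratio(0, 0.25), -Inf)
  expect_error(log2_prior_ratio(0.5, 0), "prior")
  expect_error(log2_prior_ratio(0.5, 1), "prior")
  # perfect ranking reaches exactly -log2(prior)
  genes <- sprintf("g%02d", 1:8)
  labels <- setNames(c(1, 1, rep(0, 6)), genes)
  s <- setNames(seq(1, 0.3, length.out = 8), genes)
  expect_equal(log2_prior_ratio(auprc(s, labels), class_prior(labels)),
               -log2(0.25))
})

test_that("competition ranking follows the 1224 convention", {
  expect_equal(competition_rank(c(A = 0.9, B = 0.7, C = 0.7, D = 0.5)),
               c(A = 1L, B = 2L, C = 2L, D = 4L))
  expect_equal(unname(competition_rank(c(a = 1, b = 1, c = 1))),
               c(1L, 1L, 1L))
  expect_equal(unname(competition_rank(c(a = 4, b = 3, c = 2, d = 1))),
               1:4)
  expect_error(competition_rank(c(a = 1)), "at least two")
})

test_that("average ranks are per-method means over genesets", {
  r1 <- c(A = 1L, B = 2L)
  r2 <- c(A = 3L, B = 1L)
  expect_equal(average_rank(list(r1)), c(A = 1, B = 2))
  expect_equal(average_rank(list(r1, r2)), c(A = 2, B = 1.5))
  expect_error(average_rank(list(r1, c(A = 1L, C = 2L))), "inconsistent")
  expect_error(average_rank(list()), "no rank maps")
})

test_that("Wilcoxon signed-rank matches full sign enumeration at n = 6", {
  # oracle: enumerate all 2^6 sign assignments of the rank sum
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- signs %*% r
    mean(Vs <= min(V, sum(r) - V)) + mean(Vs >= max(V, sum(r) - V))
  }
  a <- c(5, 6, 7, 8, 9, 10)
  b <- c(1, 2, 3, 4, 5, 6) * 0.9  # untied all-positive differences
  out <- wilcoxon_signed_rank(a, b)
  expect_equal(out$p_value, 2 / 64)
  expect_equal(out$n_a_wins, 6L)
  expect_equal(out$n_b_wins, 0L)
  expect_equal(out$p_value, enum_p(a - b))

  # mixed-sign case against the enumeration oracle and stats::wilcox.test
  withr::local_seed(2)
  d <- c(1.3, -0.4, 2.2, -1.9, 0.7, 3.1, -0.2)
  out <- wilcoxon_signed_rank(d, rep(0, 7))
  expect_equal(out$p_value, enum_p(d))
  expect_equal(out$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value)
})

test_that("Wilcoxon handles zeros, symmetry and large-sample approximation", {
  a <- c(1, 2, 3, 4, 5, 6)
  out <- wilcoxon_signed_rank(a, a)
  expect_true(out$degenerate)
  expect_equal(out$p_value, 1)
  expect_equal(out$n_a_wins + out$n_b_wins, 0L)

  b <- a + c(0.5, -0.3, 0.8, 0, 1.2, -0.1)
  fwd <- wilcoxon_signed_rank(a, b)
  rev <- wilcoxon_signed_rank(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$n_a_wins, rev$n_b_wins)
  # zero difference excluded from the test statistic
  expect_equal(fwd$n_used, 5L)

  # n > 25 triggers the normal approximation; compare to wilcox.test
  withr::local_seed(5)
  x <- rnorm(40)
  y <- rnorm(40, 0.4)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up oracle", {
  # oracle: p * m / rank then running minimum from the largest
  oracle_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))
  withr::local_seed(8)
  p <- runif(20)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("class significance implements the cross-class winner rule", {
  n <- 20
  ones <- seq(0.8, 0.9, length.out = n)
  # both SL methods beat both LP methods on every geneset -> class winner
  vals <- list(`SL-A` = ones + 0.05, `SL-I` = ones + 0.04,
               `LP-A` = ones - 0.30, `LP-I` = ones - 0.20)
  v <- class_significance(vals)
  expect_equal(v$winner, "SL")
  expect_equal(v$winner_class, "SL")
  expect_equal(v$win_fraction, 1.0)
  expect_true(all(v$adjusted_p_values < 0.05))

  # identical methods everywhere: no winner, no wins
  same <- list(`SL-A` = ones, `SL-I` = ones, `LP-A` = ones, `LP-I` = ones)
  v0 <- class_significance(same)
  expect_true(is.na(v0$winner))
  expect_equal(v0$win_fraction, 0)

  # SL-A beats both LP methods but SL-I beats neither -> method-level winner
  mixed <- list(`SL-A` = ones + 0.2, `SL-I` = ones - 0.25,
                `LP-A` = ones - 0.20, `LP-I` = ones - 0.20 +
                  seq(-0.001, 0.001, length.out = n))
  vm <- class_significance(mixed)
  expect_equal(vm$winner, "SL-A")
  expect_equal(vm$winner_class, "SL")

  expect_error(class_significance(vals[1:3]), "need per-geneset")
  # verdicts invariant to geneset ordering
  perm <- withr::with_seed(1, sample(n))
  vperm <- class_significance(lapply(vals, `[`, perm))
  expect_equal(vperm$winner, v$winner)
  expect_equal(vperm$win_fraction, v$win_fraction)
  expect_equal(vperm$adjusted_p_values, v$adjusted_p_values)
})

test_that("edge density and segregation match their definitions", {
  # 4-node unit-weight clique
  clique <- net_from(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
                     c("b", "d"), c("c", "d"))
  expect_equal(edge_density(clique, c("a", "b", "c", "d")), 1.0)
  expect_equal(segregation(clique, c("a", "b", "c", "d")), 1.0)

  # geneset with no internal edges
  star <- net_from(c("hub", "l1"), c("hub", "l2"), c("hub", "l3"))
  expect_equal(edge_density(star, c("l1", "l2", "l3")), 0)
  expect_equal(segregation(star, c("l1", "l2", "l3")), 0)
  expect_error(edge_density(star, "l1"), "at least 2")
  expect_error(segregation(net_from(c("a", "b"), nodes = "iso"), "iso"),
               "no incident edges")

  # segregation never exceeds 1 on random fixtures
  for (s in 1:5) {
    net <- random_network(15, 0.3, seed = s, weights = TRUE)
    gs <- withr::with_seed(s, sample(net$nodes, 6))
    seg <- segregation(net, gs)
    expect_gte(seg, 0)
    expect_lte(seg, 1)
  }
})

test_that("planted-module density matches its generating probability", {
  dens <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 120, n_modules = 1,
                      module_size_range = c(30, 30), p_within = 0.3,
                      p_between = 0.005, seed = s)
    sim <- generate_planted_network(cfg)
    edge_density(sim$network, sim$modules[[1L]])
  }, 0)
  expect_true(all(abs(dens - 0.3) < 0.05))
})

test_that("property-performance correlation has its fixed points", {
  x <- 1:12
  mono <- property_performance_correlation(x, x^2, seed = 1)
  expect_equal(mono$rho, 1.0)
  anti <- property_performance_correlation(x, -x, seed = 1)
  expect_equal(anti$rho, -1.0)
  flat <- property_performance_correlation(rep(1, 12), x, seed = 1)
  expect_true(flat$degenerate)

  # independent pairs: |rho| < 0.2 in at least 95% of seeds (null behavior)
  hits <- vapply(1:40, function(s) {
    a <- withr::with_seed(s, list(rnorm(200), rnorm(200)))
    r <- property_performance_correlation(a[[1L]], a[[2L]], n_boot = 10,
                                          seed = s)
    abs(r$rho) < 0.2
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  expect_error(property_performance_correlation(1:5, 1:5), "at least 10")
})

test_that("evaluate_result assembles per-metric records with the prior", {
  genes <- sprintf("g%02d", 1:10)
  task <- labeled_task("set1", genes[1:3], genes[4:10])
  scores <- setNames(seq(1, 0.1, length.out = 10), genes)
  res <- prediction_result("set1", "SL-A", scores)
  rec <- evaluate_result(res, task)
  expect_equal(rec$metric, c("auPRC", "P@TopK", "auROC"))
  expect_equal(unique(rec$prior), 0.3)
  expect_equal(rec$raw_value, c(1, 1, 1))
  expect_equal(rec$log2_ratio[1:2], rep(-log2(0.3), 2))
  expect_true(is.na(rec$log2_ratio[3]))
})
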