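test_that("GMT files round-trip", {
  col <- worked_collection()
  tf <- tempfile(fileext = ".gmt")
  write_gmt(col, tf)
  back <- read_gmt(tf)
  expect_equal(back$sets, col$sets)
  expect_error(read_gmt(tmp_write("only_id\tdesc")), "malformed GMT line 1")
})

test_that("annotation propagation follows ancestors and is idempotent", {
  col <- geneset_collection(list(child = "g1"),
                            ontology = data.frame(child = "child",
                                                  parent = "parent"))
  out <- propagate_annotations(col)
  expect_equal(out$sets$parent, "g1")

  # chain child -> mid -> root: transitive closure
  col <- geneset_collection(
    list(child = "g1", mid = "g2", root = "g3"),
    ontology = data.frame(child = c("child", "mid"),
                          parent = c("mid", "root")))
  out <- propagate_annotations(col)
  expect_setequal(out$sets$mid, c("g1", "g2"))
  expect_setequal(out$sets$root, c("g1", "g2", "g3"))
  expect_identical(propagate_annotations(out)$sets, out$sets)

  # no ontology edges relating the sets leaves annotations unchanged
  col2 <- geneset_collection(list(a = "g1", b = "g2"),
                             ontology = data.frame(child = "x", parent = "y"))
  expect_equal(propagate_annotations(col2)$sets[c("a", "b")],
               col2$sets[c("a", "b")])

  # cycles are rejected naming a member
  expect_error(
    geneset_collection(list(a = "g1"),
                       ontology = data.frame(child = c("a", "b"),
                                             parent = c("b", "a"))),
    "cycle")
})

test_that("size filtering keeps the inclusive range", {
  col <- geneset_collection(list(small = sprintf("a%d", 1:5),
                                 mid = sprintf("b%d", 1:50),
                                 big = sprintf("c%d", 1:500)))
  out <- filter_by_size(col, 10, 200)
  expect_equal(names(out$sets), "mid")
  expect_equal(names(filter_by_size(col, 10, Inf)$sets), c("big", "mid"))
  expect_equal(filter_by_size(col, 1, Inf)$sets, col$sets)
  expect_error(filter_by_size(col, 20, 10), "max_size")
  expect_error(filter_by_size(col, 0, 10), ">= 1")
})

test_that("redundancy removal is greedy by size then id", {
  # identical sets: one kept (at equal size the lexicographically first)
  col <- geneset_collection(list(B = c("g1", "g2"), A = c("g1", "g2")))
  expect_equal(names(remove_redundant(col, 0.5)$sets), "A")

  # disjoint sets all survive any threshold
  col <- geneset_collection(list(A = c("g1", "g2"), B = c("g3", "g4")))
  expect_equal(length(remove_redundant(col, 0.01)$sets), 2L)

  # Jaccard 9/11 > 0.5 drops the (smaller-or-equal, later) set
  col <- geneset_collection(list(A = sprintf("g%02d", 1:10),
                                 B = c(sprintf("g%02d", 1:9), "g11")))
  expect_equal(names(remove_redundant(col, 0.5)$sets), "A")
  # ... but survives a threshold above 9/11
  expect_equal(length(remove_redundant(col, 0.9)$sets), 2L)
})

test_that("multi-attribute gene removal uses a strict membership bound", {
  mk <- function(n_sets, gene = "hub") {
    sets <- lapply(seq_len(20), function(i) sprintf("s%02d_g%d", i, 1:3))
    names(sets) <- sprintf("s%02d", seq_len(20))
    for (i in seq_len(n_sets)) sets[[i]] <- c(sets[[i]], gene)
    geneset_collection(sets)
  }
  # in 11 of 20 sets -> removed everywhere
  out <- remove_multi_attribute_genes(mk(11), 10)
  expect_false("hub" %in% unlist(out$sets))
  # in exactly 10 sets -> retained ("more than 10" is strict)
  out <- remove_multi_attribute_genes(mk(10), 10)
  expect_equal(sum(vapply(out$sets, function(s) "hub" %in% s, TRUE)), 10L)
  # singleton memberships are untouched
  col <- geneset_collection(list(a = "g1", b = "g2"))
  expect_equal(remove_multi_attribute_genes(col, 10)$sets, col$sets)
  # membership counts never increase (property)
  col <- worked_collection()
  before <- table(unlist(col$sets))
  after <- table(unlist(remove_multi_attribute_genes(col, 1)$sets))
  expect_true(all(after[names(after)] <= before[names(after)]))
})

test_that("one-sided Fisher test equals hypergeometric enumeration", {
  # full-pmf enumeration oracle: P(X >= a), X ~ Hypergeom(N, K, n)
  enum <- function(a, b, c2, d) {
    N <- a + b + c2 + d; K <- a + b; n <- a + c2
    sum(vapply(0:min(K, n), function(x) {
      if (x < a) return(0)
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, 0))
  }
  expect_equal(fisher_exact_one_sided(0, 2, 2, 2), 1.0)
  expect_equal(fisher_exact_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  # strong overlap: exact enumeration gives 71 / C(17,10) = 0.00365
  expect_equal(fisher_exact_one_sided(9, 1, 1, 6), 71 / choose(17, 10),
               tolerance = 1e-12)
  expect_lt(fisher_exact_one_sided(9, 1, 1, 6), 0.01)
  for (case in list(c(2, 0, 0, 2), c(9, 1, 1, 6), c(3, 4, 5, 6), c(0, 5, 5, 5))) {
    expect_equal(do.call(fisher_exact_one_sided, as.list(case)),
                 do.call(enum, as.list(case)), tolerance = 1e-12)
  }
  # independent cross-check against stats::fisher.test upper tail
  m <- matrix(c(3, 4, 5, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact_one_sided(3, 4, 5, 6),
               stats::fisher.test(m, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("negative selection excludes significantly overlapping sets", {
  col <- worked_collection()
  # S2 overlaps S1 in 9/10 genes (p < 0.05 over the 17-gene universe),
  # S3 is disjoint (p = 1): negatives(S1) are exactly the S3 genes
  expect_equal(select_negatives(col, "S1"), sprintf("g%02d", 15:20))
  expect_error(select_negatives(col, "nope"), "unknown geneset")

  # pairwise-disjoint sets: negatives are all annotated genes outside the set
  disj <- geneset_collection(list(A = c("g1", "g2"), B = c("g3", "g4"),
                                  C = c("g5", "g6")))
  expect_equal(select_negatives(disj, "A"), c("g3", "g4", "g5", "g6"))

  # a duplicated set is always excluded (its overlap p is minimal)
  dup <- geneset_collection(list(S = sprintf("g%02d", 1:10),
                                 Sdup = sprintf("g%02d", 1:10),
                                 other = sprintf("h%02d", 1:10)))
  expect_false(any(sprintf("g%02d", 1:10) %in% select_negatives(dup, "S")))
})

test_that("negative-set size is monotone in the significance threshold", {
  col <- worked_collection()
  negs <- lapply(c(0.001, 0.01, 0.05, 0.2, 1), function(p) {
    select_negatives(col, "S1", p_threshold = p)
  })
  for (i in seq_len(length(negs) - 1L)) {
    expect_true(all(negs[[i + 1L]] %in% negs[[i]]))
  }
  # negatives never intersect the target
  for (id in names(col$sets)) {
    expect_length(intersect(select_negatives(col, id), col$sets[[id]]), 0L)
  }
})

test_that("the preprocessing pipeline runs in the documented order", {
  base <- lapply(1:12, function(i) sprintf("m%02d_g%02d", i, 1:15))
  names(base) <- sprintf("m%02d", 1:12)
  base$tiny <- c("t1", "t2")
  base$near_dup <- c(base$m01[-1], "extra")
  col <- geneset_collection(base)
  out <- preprocess_collection(col, min_size = 10, max_size = 200,
                               jaccard_threshold = 0.5)
  expect_false("tiny" %in% names(out$sets))      # size filter
  expect_false("near_dup" %in% names(out$sets))  # redundancy filter
  expect_equal(length(out$sets), 12L)
})
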