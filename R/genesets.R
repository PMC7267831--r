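#' Geneset collection
#'
#' A named family of gene sets from one annotation source (functions,
#' diseases, traits), optionally accompanied by an ontology (parent-child
#' DAG over geneset ids), per-annotation dates and per-gene publication
#' counts. These optional attributes drive annotation propagation, the
#' temporal-holdout split and the study-bias split respectively.
#'
#' @param sets named list of character vectors (geneset id -> gene ids).
#'   Empty sets are dropped.
#' @param ontology optional data.frame with columns `child`, `parent`
#'   (geneset ids); must be acyclic.
#' @param dates optional data.frame with columns `gene`, `set`, `date`
#'   (coercible via [as.Date()]).
#' @param pub_counts optional named numeric vector of per-gene publication
#'   counts.
#' @param name collection label.
#' @return an object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, ontology = NULL, dates = NULL,
                               pub_counts = NULL, name = "collection") {
  stopifnot(is.list(sets))
  if (length(sets) > 0L && is.null(names(sets))) stop("sets must be named")
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  sets <- sets[lengths(sets) > 0L]
  sets <- sets[order(names(sets))]
  if (!is.null(ontology)) {
    ontology <- data.frame(child = as.character(ontology[[1L]]),
                           parent = as.character(ontology[[2L]]),
                           stringsAsFactors = FALSE)
    check_acyclic(ontology)
  }
  if (!is.null(dates)) {
    dates <- data.frame(gene = as.character(dates[[1L]]),
                        set = as.character(dates[[2L]]),
                        date = as.Date(dates[[3L]]),
                        stringsAsFactors = FALSE)
  }
  structure(list(sets = sets, ontology = ontology, dates = dates,
                 pub_counts = pub_counts, name = name),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection '%s': %d sets, %d genes%s%s>\n",
              x$name, length(x$sets),
              length(unique(unlist(x$sets, use.names = FALSE))),
              if (!is.null(x$ontology)) ", ontology" else "",
              if (!is.null(x$dates)) ", dates" else ""))
  invisible(x)
}

#' All genes annotated anywhere in a collection
#' @param collection a [geneset_collection].
#' @return sorted character vector of gene ids.
#' @export
annotated_genes <- function(collection) {
  sort(unique(unlist(collection$sets, use.names = FALSE)))
}

check_acyclic <- function(ontology) {
  # Kahn topological sort over geneset ids; leftovers are on a cycle.
  ids <- unique(c(ontology$child, ontology$parent))
  indeg <- setNames(integer(length(ids)), ids)  # edges child -> parent
  tab <- table(ontology$parent)
  indeg[names(tab)] <- as.integer(tab)
  children <- split(ontology$parent, ontology$child)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (u in children[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) queue <- c(queue, u)
    }
  }
  if (seen < length(ids)) {
    member <- names(indeg)[indeg > 0L][1L]
    stop("ontology contains a cycle involving '", member, "'")
  }
  invisible(TRUE)
}

#' Read a geneset collection from GMT
#'
#' GMT format: one set per line, `<set-id>\t<description>\t<gene1>\t<gene2>...`.
#'
#' @param path GMT file.
#' @param name collection label; defaults to the file name.
#' @return a [geneset_collection].
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("malformed GMT line %d (need id, description, >=1 gene)",
                 short[1L]))
  }
  sets <- lapply(fields, function(x) x[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  geneset_collection(sets, name = name)
}

#' Write a geneset collection as GMT
#'
#' @param collection a [geneset_collection].
#' @param path output file.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to the set id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  ids <- names(collection$sets)
  desc <- if (is.null(descriptions)) ids else descriptions[ids]
  out <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(out, path)
  invisible(path)
}

#' Read an ontology parent-child TSV
#'
#' Format: `<child-id>\t<parent-id>`, one edge per line; `#` comments skipped.
#'
#' @param path TSV file.
#' @return data.frame with columns `child`, `parent`.
#' @export
read_ontology_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  colClasses = "character")
  data.frame(child = d[[1L]], parent = d[[2L]], stringsAsFactors = FALSE)
}

#' Read an annotation-date TSV
#'
#' Format: `<gene-id>\t<set-id>\t<YYYY-MM-DD>`.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene`, `set`, `date` (Date).
#' @export
read_dates_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  colClasses = "character")
  data.frame(gene = d[[1L]], set = d[[2L]], date = as.Date(d[[3L]]),
             stringsAsFactors = FALSE)
}

#' Read a per-gene publication-count TSV
#'
#' Format: `<gene-id>\t<count>`.
#'
#' @param path TSV file.
#' @return named numeric vector.
#' @export
read_counts_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  colClasses = c("character", "numeric"))
  setNames(d[[2L]], d[[1L]])
}

ontology_ancestors <- function(ontology) {
  # memoized transitive closure: set id -> all ancestors
  parents <- split(ontology$parent, ontology$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- parents[[id]]
    out <- if (is.null(ps)) character(0) else {
      unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    }
    memo[[id]] <- out
    out
  }
  ids <- unique(ontology$child)
  setNames(lapply(ids, anc), ids)
}

#' Propagate annotations up an ontology
#'
#' Every gene annotated to a set becomes annotated to all ontology ancestors
#' of that set, yielding the complete ("true-path") annotation of each term.
#' The operation is idempotent. Ancestor sets absent from the collection are
#' created.
#'
#' @param collection a [geneset_collection] with a non-NULL ontology.
#' @return the propagated [geneset_collection].
#' @export
propagate_annotations <- function(collection) {
  if (is.null(collection$ontology)) stop("collection has no ontology")
  anc <- ontology_ancestors(collection$ontology)
  sets <- collection$sets
  for (id in names(collection$sets)) {
    for (a in anc[[id]]) {
      sets[[a]] <- union(sets[[a]], collection$sets[[id]])
    }
  }
  geneset_collection(sets, ontology = collection$ontology,
                     dates = collection$dates,
                     pub_counts = collection$pub_counts,
                     name = collection$name)
}

#' Keep genesets within a size range
#'
#' @param collection a [geneset_collection].
#' @param min_size smallest retained size (inclusive, >= 1).
#' @param max_size largest retained size (inclusive; may be `Inf`).
#' @return the filtered [geneset_collection].
#' @export
filter_by_size <- function(collection, min_size = 10, max_size = 200) {
  if (min_size < 1) stop("min_size must be >= 1")
  if (min_size > max_size) stop("min_size must not exceed max_size")
  n <- lengths(collection$sets)
  keep <- n >= min_size & n <= max_size
  geneset_collection(collection$sets[keep], ontology = collection$ontology,
                     dates = collection$dates,
                     pub_counts = collection$pub_counts,
                     name = collection$name)
}

#' Drop genesets highly overlapping with larger ones
#'
#' Greedy scan over sets ordered by decreasing size (ties broken
#' lexicographically by id): a set is dropped when its Jaccard index with any
#' already-kept set strictly exceeds `jaccard_threshold`. The survivors form
#' a specific, largely non-redundant collection.
#'
#' @param collection a [geneset_collection].
#' @param jaccard_threshold maximum tolerated Jaccard index, in (0, 1].
#' @return the filtered [geneset_collection].
#' @export
remove_redundant <- function(collection, jaccard_threshold = 0.5) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1) {
    stop("jaccard_threshold must be in (0, 1]")
  }
  ids <- names(collection$sets)
  o <- order(-lengths(collection$sets), ids)
  kept <- character(0)
  for (id in ids[o]) {
    s <- collection$sets[[id]]
    redundant <- FALSE
    for (k in kept) {
      t <- collection$sets[[k]]
      jac <- length(intersect(s, t)) / length(union(s, t))
      if (jac > jaccard_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, id)
  }
  geneset_collection(collection$sets[sort(kept)],
                     ontology = collection$ontology,
                     dates = collection$dates,
                     pub_counts = collection$pub_counts,
                     name = collection$name)
}

#' Remove multi-attribute genes
#'
#' Genes appearing in strictly more than `max_memberships` genesets of the
#' collection are removed from every set (such genes are trivially
#' predictable and would inflate apparent performance). Sets left empty are
#' dropped.
#'
#' @param collection a [geneset_collection], usually already size- and
#'   redundancy-filtered.
#' @param max_memberships largest tolerated number of memberships (default 10).
#' @return the filtered [geneset_collection].
#' @export
remove_multi_attribute_genes <- function(collection, max_memberships = 10) {
  counts <- table(unlist(collection$sets, use.names = FALSE))
  multi <- names(counts)[counts > max_memberships]
  sets <- lapply(collection$sets, function(g) setdiff(g, multi))
  geneset_collection(sets, ontology = collection$ontology,
                     dates = collection$dates,
                     pub_counts = collection$pub_counts,
                     name = collection$name)
}

#' One-sided Fisher's exact test (upper tail)
#'
#' For the 2x2 table `[[a, b], [c2, d]]` with `a` the overlap count, returns
#' the upper-tail hypergeometric probability P(X >= a) with
#' X ~ Hypergeometric(N = a+b+c2+d, K = a+b, n = a+c2), i.e. the probability
#' of an overlap at least as large under independent draws.
#'
#' @param a,b,c2,d non-negative counts.
#' @return the one-sided p-value.
#' @export
fisher_exact_one_sided <- function(a, b, c2, d) {
  stopifnot(a >= 0, b >= 0, c2 >= 0, d >= 0)
  phyper(a - 1, a + b, c2 + d, a + c2, lower.tail = FALSE)
}

#' Select negative example genes for a geneset
#'
#' Negatives are drawn from the union of all genes annotated anywhere in the
#' collection, excluding (i) genes in the target set and (ii) genes in any
#' other set whose overlap with the target is significant at `p_threshold`
#' under the one-sided Fisher's exact test over that same universe. This
#' avoids labeling genes as negative when they belong to a closely related
#' geneset.
#'
#' @param collection a preprocessed [geneset_collection].
#' @param geneset_id target set id.
#' @param p_threshold Fisher p-value below which an overlapping set's genes
#'   are excluded (default 0.05).
#' @return sorted character vector of negative gene ids.
#' @export
select_negatives <- function(collection, geneset_id, p_threshold = 0.05) {
  if (!geneset_id %in% names(collection$sets)) {
    stop("unknown geneset id '", geneset_id, "'")
  }
  universe <- annotated_genes(collection)
  target <- collection$sets[[geneset_id]]
  N <- length(universe)
  K <- length(target)
  excluded <- character(0)
  for (id in setdiff(names(collection$sets), geneset_id)) {
    other <- collection$sets[[id]]
    a <- length(intersect(target, other))
    n <- length(other)
    p <- fisher_exact_one_sided(a, K - a, n - a, N - K - n + a)
    if (p < p_threshold) excluded <- c(excluded, other)
  }
  sort(setdiff(universe, c(target, excluded)))
}

#' Labeled classification task for one geneset
#'
#' @param geneset_id target set id.
#' @param positives gene ids annotated to the set.
#' @param negatives gene ids selected as negatives; must not intersect
#'   `positives`.
#' @return an object of class `labeled_task`.
#' @export
labeled_task <- function(geneset_id, positives, negatives) {
  positives <- sort(unique(as.character(positives)))
  negatives <- sort(unique(as.character(negatives)))
  if (length(intersect(positives, negatives)) > 0L) {
    stop("positives and negatives must be disjoint")
  }
  structure(list(geneset_id = geneset_id, positives = positives,
                 negatives = negatives),
            class = "labeled_task")
}

#' @export
print.labeled_task <- function(x, ...) {
  cat(sprintf("<labeled_task '%s': %d positives, %d negatives>\n",
              x$geneset_id, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Build labeled tasks for every geneset in a collection
#'
#' Convenience wrapper combining each set's members (positives) with
#' [select_negatives()].
#'
#' @inheritParams select_negatives
#' @return named list of [labeled_task] objects.
#' @export
build_tasks <- function(collection, p_threshold = 0.05) {
  ids <- names(collection$sets)
  setNames(lapply(ids, function(id) {
    labeled_task(id, collection$sets[[id]],
                 select_negatives(collection, id, p_threshold))
  }), ids)
}

#' Standard geneset preprocessing pipeline
#'
#' Applies, in order: ontology propagation (when an ontology is present),
#' size filtering, redundancy removal and multi-attribute gene removal.
#'
#' @param collection a [geneset_collection].
#' @param min_size,max_size size bounds passed to [filter_by_size()].
#' @param jaccard_threshold passed to [remove_redundant()].
#' @param max_memberships passed to [remove_multi_attribute_genes()].
#' @return the preprocessed [geneset_collection].
#' @export
preprocess_collection <- function(collection, min_size = 10, max_size = 200,
                                  jaccard_threshold = 0.5,
                                  max_memberships = 10) {
  if (!is.null(collection$ontology)) {
    collection <- propagate_annotations(collection)
  }
  collection <- filter_by_size(collection, min_size, max_size)
  collection <- remove_redundant(collection, jaccard_threshold)
  remove_multi_attribute_genes(collection, max_memberships)
}
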