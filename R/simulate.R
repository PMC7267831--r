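#' Configuration for the planted-module simulator
#'
#' Describes a planted-partition (stochastic block) network: `n_modules`
#' dense gene modules embedded in an `n_genes` background, with independent
#' within-module edge probability `p_within` and background edge probability
#' `p_between`. One geneset per module provides ground truth, and
#' [add_annotation_artifacts()] decorates the collection with the redundancy,
#' multi-attribute, annotation-date and study-bias structure that real
#' geneset collections exhibit. All generators are pure functions of the
#' config (same seed, byte-identical outputs).
#'
#' @param n_genes total number of genes (default 500).
#' @param n_modules number of planted modules (default 10).
#' @param module_size_range inclusive `(min, max)` module size; sizes are
#'   drawn uniformly (default `c(30, 30)`, i.e. fixed size 30).
#' @param p_within within-module edge probability, scalar or one value per
#'   module (recycled); default 0.3.
#' @param p_between background edge probability; must be smaller than every
#'   `p_within` (default 0.01).
#' @param weight_distribution `"unit"` for weight 1 edges, or
#'   `list("uniform", lo, hi)` for i.i.d. uniform weights.
#' @param n_redundant_pairs number of near-duplicate genesets to add
#'   (Jaccard > 0.8 with their source set); default 0.
#' @param multi_attribute_genes number of genes to inject into more than 10
#'   genesets each; default 0.
#' @param date_cutoff_fraction fraction of annotated genes whose every
#'   annotation is dated after the temporal cutoff (default 0.25).
#' @param study_bias_shape power-law exponent of the simulated per-gene
#'   publication counts (default 1.5; smaller = heavier tail).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_modules = 10,
                       module_size_range = c(30, 30), p_within = 0.3,
                       p_between = 0.01, weight_distribution = "unit",
                       n_redundant_pairs = 0, multi_attribute_genes = 0,
                       date_cutoff_fraction = 0.25, study_bias_shape = 1.5,
                       seed = 1) {
  if (any(p_between < 0) || any(p_within > 1) || any(p_between >= p_within)) {
    stop("need 0 <= p_between < p_within <= 1")
  }
  if (module_size_range[1L] > module_size_range[2L]) {
    stop("module_size_range must be non-decreasing")
  }
  if (n_modules * module_size_range[2L] > n_genes) {
    stop("modules cannot fit in n_genes (modules are disjoint)")
  }
  structure(list(n_genes = n_genes, n_modules = n_modules,
                 module_size_range = module_size_range, p_within = p_within,
                 p_between = p_between,
                 weight_distribution = weight_distribution,
                 n_redundant_pairs = n_redundant_pairs,
                 multi_attribute_genes = multi_attribute_genes,
                 date_cutoff_fraction = date_cutoff_fraction,
                 study_bias_shape = study_bias_shape, seed = seed),
            class = "sim_config")
}

#' Generate a planted-module network and its ground-truth genesets
#'
#' Samples a planted-partition graph: module members are connected i.i.d.
#' with their module's `p_within`, all other gene pairs with `p_between`.
#' Modules are disjoint and their members are drawn uniformly from the gene
#' universe; each module becomes one geneset named `moduleNN`.
#'
#' @param cfg a [sim_config].
#' @return list with components `network` (a [gene_network]) and `collection`
#'   (a [geneset_collection]), plus `modules` (named list of member vectors,
#'   identical to the collection's sets).
#' @export
generate_planted_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    width <- nchar(as.character(cfg$n_genes))
    genes <- sprintf(paste0("g%0", width, "d"), seq_len(cfg$n_genes))
    lo <- cfg$module_size_range[1L]
    hi <- cfg$module_size_range[2L]
    sizes <- lo + sample.int(hi - lo + 1L, cfg$n_modules, replace = TRUE) - 1L
    pool <- sample(genes, sum(sizes))
    modules <- split(pool, rep(seq_len(cfg$n_modules), times = sizes))
    names(modules) <- sprintf("module%02d", seq_len(cfg$n_modules))
    modules <- lapply(modules, sort)
    p_within <- rep_len(cfg$p_within, cfg$n_modules)

    # background edges over all pairs, then overwrite within-module pairs
    module_of <- setNames(rep(0L, cfg$n_genes), genes)
    for (m in seq_along(modules)) module_of[modules[[m]]] <- m
    pair_i <- rep(seq_len(cfg$n_genes - 1L),
                  times = (cfg$n_genes - 1L):1L)
    pair_j <- unlist(lapply(seq_len(cfg$n_genes - 1L),
                            function(i) (i + 1L):cfg$n_genes),
                     use.names = FALSE)
    mi <- module_of[pair_i]
    mj <- module_of[pair_j]
    same <- mi > 0L & mi == mj
    prob <- rep(cfg$p_between, length(pair_i))
    prob[same] <- p_within[mi[same]]
    hit <- runif(length(prob)) < prob
    from <- genes[pair_i[hit]]
    to <- genes[pair_j[hit]]
    w <- if (identical(cfg$weight_distribution, "unit")) {
      rep(1, length(from))
    } else {
      runif(length(from), cfg$weight_distribution[[2L]],
            cfg$weight_distribution[[3L]])
    }
    network <- gene_network(data.frame(from = from, to = to, weight = w,
                                       stringsAsFactors = FALSE),
                            nodes = genes,
                            name = sprintf("planted(seed=%d)", cfg$seed))
    collection <- geneset_collection(modules,
                                     name = sprintf("planted(seed=%d)",
                                                    cfg$seed))
    list(network = network, collection = collection, modules = modules)
  })
}

#' Decorate a simulated collection with realistic annotation artifacts
#'
#' Adds, in order: (i) `n_redundant_pairs` near-duplicate genesets (each a
#' copy of an existing set with two members swapped out, giving Jaccard
#' > 0.8); (ii) `multi_attribute_genes` genes injected into more than 10
#' genesets each; (iii) per-(gene, set) annotation dates, with a
#' `date_cutoff_fraction` of the annotated genes dated entirely after
#' 2017-01-01 (uniform in 2017-2018) and the rest before it (uniform in
#' 2010-2016); and (iv) per-gene publication counts drawn from a discrete
#' power law with exponent `study_bias_shape`, emulating the heavy-tailed
#' distribution of literature attention.
#'
#' @param collection a [geneset_collection] from [generate_planted_network()].
#' @param cfg the same [sim_config].
#' @return the decorated [geneset_collection] (with `dates` and `pub_counts`
#'   populated).
#' @export
add_annotation_artifacts <- function(collection, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    sets <- collection$sets
    universe <- sort(unique(unlist(sets, use.names = FALSE)))

    if (cfg$n_redundant_pairs > 0) {
      src <- names(sets)[seq_len(min(cfg$n_redundant_pairs, length(sets)))]
      for (id in src) {
        s <- sets[[id]]
        outside <- setdiff(universe, s)
        k <- min(2L, length(s) - 1L, length(outside))
        dup <- sort(c(setdiff(s, sample(s, k)), sample(outside, k)))
        sets[[paste0(id, "_dup")]] <- dup
      }
    }

    if (cfg$multi_attribute_genes > 0) {
      promiscuous <- sample(universe, cfg$multi_attribute_genes)
      for (g in promiscuous) {
        # ensure strictly more than 10 memberships
        need <- 11L - sum(vapply(sets, function(s) g %in% s, TRUE))
        eligible <- names(sets)[!vapply(sets, function(s) g %in% s, TRUE)]
        if (need > length(eligible)) {
          warning("too few genesets to make '", g, "' a multi-attribute gene")
        }
        if (need > 0) {
          hosts <- sample(eligible, min(need, length(eligible)))
          for (id in hosts) sets[[id]] <- sort(c(sets[[id]], g))
        }
      }
    }

    ann_genes <- sort(unique(unlist(sets, use.names = FALSE)))
    n_new <- round(cfg$date_cutoff_fraction * length(ann_genes))
    new_genes <- if (n_new > 0) sample(ann_genes, n_new) else character(0)
    ann <- data.frame(
      gene = unlist(sets, use.names = FALSE),
      set = rep(names(sets), lengths(sets)), stringsAsFactors = FALSE)
    is_new <- ann$gene %in% new_genes
    pre <- as.Date("2010-01-01") +
      sample.int(as.integer(as.Date("2016-12-31") - as.Date("2010-01-01")),
                 nrow(ann), replace = TRUE)
    post <- as.Date("2017-01-02") +
      sample.int(as.integer(as.Date("2018-12-31") - as.Date("2017-01-02")),
                 nrow(ann), replace = TRUE)
    ann$date <- as.Date(ifelse(is_new, post, pre), origin = "1970-01-01")

    # discrete power law: P(X >= x) ~ x^(1 - shape), via inverse transform
    u <- runif(length(ann_genes))
    counts <- floor(u^(-1 / (cfg$study_bias_shape - 1)))
    counts <- pmin(counts, 1e6)
    pub_counts <- setNames(as.numeric(counts), ann_genes)

    geneset_collection(sets, ontology = collection$ontology, dates = ann,
                       pub_counts = pub_counts, name = collection$name)
  })
}

#' Write a simulated benchmark to disk in the package's text formats
#'
#' Emits the edge-list TSV, GMT, annotation-date TSV and publication-count
#' TSV that the corresponding readers load, so simulated fixtures round-trip
#' through the same code paths as real data.
#'
#' @param sim output of [generate_planted_network()], optionally with its
#'   collection passed through [add_annotation_artifacts()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             gmt = file.path(dir, "collection.gmt"),
             dates = file.path(dir, "dates.tsv"),
             counts = file.path(dir, "pubmed_counts.tsv"))
  write_edge_list(sim$network, paths[["network"]])
  write_gmt(sim$collection, paths[["gmt"]])
  d <- sim$collection$dates
  if (!is.null(d)) {
    writeLines(sprintf("%s\t%s\t%s", d$gene, d$set, format(d$date)),
               paths[["dates"]])
  }
  pc <- sim$collection$pub_counts
  if (!is.null(pc)) {
    writeLines(sprintf("%s\t%g", names(pc), pc), paths[["counts"]])
  }
  invisible(paths)
}
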