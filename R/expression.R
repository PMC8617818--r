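#' Construct a gene x mutant expression profile
#'
#' Container for log2 fold-change (and optional p-value) matrices from a
#' deletion-mutant expression compendium. Missing values stay `NA`; they
#' are never silently treated as zero.
#'
#' @param log2fc numeric matrix, genes in rows, mutants in columns, with
#'   dimnames.
#' @param pvals optional matching p-value matrix.
#' @return list of class `expression_profile` with `genes`, `mutants`,
#'   `log2fc`, `pvals`.
#' @export
expression_profile <- function(log2fc, pvals = NULL) {
  stopifnot(is.matrix(log2fc), !is.null(rownames(log2fc)),
            !is.null(colnames(log2fc)))
  if (!is.null(pvals)) {
    stopifnot(is.matrix(pvals), all(dim(pvals) == dim(log2fc)))
    dimnames(pvals) <- dimnames(log2fc)
    stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  }
  structure(list(genes = rownames(log2fc), mutants = colnames(log2fc),
                 log2fc = log2fc, pvals = pvals),
            class = "expression_profile")
}

#' Rank genes by their mean log2 fold change across mutants
#'
#' The prioritisation statistic: because the recycling phenotype is shared
#' across complex-subunit mutants, shared transcriptional targets should
#' change coherently, so the per-gene mean log2FC across mutants
#' concentrates signal and averages out mutant-specific noise. Means are
#' over non-missing entries; genes missing in every selected mutant are
#' excluded (with a message). Ranking is ascending for
#' `direction = "down"` (most repressed first) and descending for `"up"`;
#' ties are broken by input gene order.
#'
#' @param profile an [expression_profile()].
#' @param mutants subset of mutant names to average over; `NULL` = all.
#' @param direction `"down"` or `"up"`.
#' @return data.frame sorted by rank with `gene`, `mean_log2fc`, `sd`,
#'   `n_nonmissing`, `rank`; attribute `direction`.
#' @export
average_across_mutants <- function(profile, mutants = NULL,
                                   direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(inherits(profile, "expression_profile"))
  if (is.null(mutants)) mutants <- profile$mutants
  if (length(mutants) == 0) stop("mutant subset is empty")
  bad <- setdiff(mutants, profile$mutants)
  if (length(bad)) stop("unknown mutants: ", paste(bad, collapse = ", "))
  m <- profile$log2fc[, mutants, drop = FALSE]
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok == 0)) {
    message("excluding ", sum(n_ok == 0), " gene(s) with all-missing values")
    m <- m[n_ok > 0, , drop = FALSE]
    n_ok <- n_ok[n_ok > 0]
  }
  mu <- rowMeans(m, na.rm = TRUE)
  sds <- apply(m, 1, sd, na.rm = TRUE)
  ord <- if (direction == "down") order(mu) else order(-mu)
  out <- data.frame(gene = rownames(m), mean_log2fc = mu, sd = sds,
                    n_nonmissing = n_ok, row.names = NULL)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  out
}

#' Select significantly repressed candidates plus a ranked extension
#'
#' A gene is called significantly reduced when its cross-mutant mean
#' log2FC is negative and Fisher's combined probability over its
#' per-mutant p-values is below `alpha`. The significant genes are
#' returned in rank order, followed by the next `extension_n` genes by
#' mean regardless of significance — a guard against targets repressed
#' strongly in only some mutants.
#'
#' @param ranking output of [average_across_mutants()] with
#'   `direction = "down"`.
#' @param pvals gene x mutant p-value matrix (rownames covering the
#'   ranked genes).
#' @param alpha significance level for the combined p (default 0.05).
#' @param extension_n how many next-best genes to append (default 10).
#' @return data.frame in rank order with `gene`, `mean_log2fc`,
#'   `fisher_p`, `tag` (`"significant"` or `"extension"`).
#' @export
select_candidates <- function(ranking, pvals, alpha = 0.05,
                              extension_n = 10L) {
  stopifnot(is.data.frame(ranking), all(c("gene", "mean_log2fc") %in%
                                          names(ranking)),
            is.matrix(pvals), alpha > 0, alpha < 1, extension_n >= 0)
  if (!all(ranking$gene %in% rownames(pvals)))
    stop("p-value matrix does not cover all ranked genes")
  fisher_p <- vapply(ranking$gene, function(g) {
    p <- pvals[g, ]
    p <- p[!is.na(p)]
    if (length(p) == 0) return(NA_real_)
    p <- pmax(p, .Machine$double.xmin)
    pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  }, numeric(1))
  sig <- !is.na(fisher_p) & fisher_p < alpha & ranking$mean_log2fc < 0
  out <- data.frame(gene = ranking$gene, mean_log2fc = ranking$mean_log2fc,
                    fisher_p = fisher_p,
                    tag = ifelse(sig, "significant", "extension"),
                    stringsAsFactors = FALSE)
  ext_pool <- which(!sig)
  if (extension_n > length(ext_pool)) {
    warning("extension_n exceeds remaining genes; truncating to ",
            length(ext_pool))
    extension_n <- length(ext_pool)
  }
  keep <- sort(c(which(sig), ext_pool[seq_len(extension_n)]))
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

#' Restrict a profile to essential genes
#'
#' Keeps only genes on the supplied essential-for-viability list (e.g.
#' the ~1290 ORFs absent from a viable haploid deletion library),
#' preserving the original row order.
#'
#' @param profile an [expression_profile()].
#' @param essential_list character vector of gene names.
#' @return an [expression_profile()] over the intersection.
#' @export
subset_essential <- function(profile, essential_list) {
  stopifnot(inherits(profile, "expression_profile"),
            length(essential_list) > 0)
  keep <- profile$genes %in% essential_list
  if (!any(keep)) stop("no essential genes present in the profile")
  expression_profile(profile$log2fc[keep, , drop = FALSE],
                     if (is.null(profile$pvals)) NULL
                     else profile$pvals[keep, , drop = FALSE])
}

#' Genes repressed by at least a given fold change
#'
#' Selects genes whose cross-mutant mean corresponds to a reduction of at
#' least `fold_threshold`-fold, i.e. mean log2FC <= -log2(fold_threshold).
#'
#' @param ranking output of [average_across_mutants()].
#' @param fold_threshold fold-reduction threshold (> 1), default 5.
#' @return character vector of gene names (in rank order).
#' @export
threshold_repressed <- function(ranking, fold_threshold = 5) {
  stopifnot(fold_threshold > 1)
  ranking$gene[ranking$mean_log2fc <= -log2(fold_threshold)]
}

#' Hierarchically cluster mutant expression profiles
#'
#' Agglomerative clustering of the mutant columns (Euclidean distance on
#' pairwise-complete entries, complete linkage by default). Determinism:
#' `hclust` merge order and tie-breaking follow input column order.
#'
#' @param profile an [expression_profile()] with >= 2 mutants.
#' @param distance distance measure for [stats::dist()].
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `hclust` (the tree), `order` (leaf order, integer),
#'   `labels` (leaf labels in dendrogram order), `newick` (the tree in
#'   newick notation).
#' @export
cluster_mutants <- function(profile, distance = "euclidean",
                            linkage = "complete") {
  stopifnot(inherits(profile, "expression_profile"))
  if (length(profile$mutants) < 2) stop("need at least 2 mutants to cluster")
  d <- dist(t(profile$log2fc), method = distance)
  if (any(is.na(d))) stop("distances undefined: mutant pairs share no genes")
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$order, labels = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Hypergeometric annotation enrichment
#'
#' For each annotation term, tests over-representation of the query set in
#' the term with the hypergeometric upper tail P(X >= k), where k = hits
#' in query, K = term size in the universe, n = query size, N = universe
#' size; Benjamini-Hochberg adjustment across tested terms. Terms with no
#' query hit are skipped.
#'
#' @param query character gene set, must be contained in `universe`.
#' @param annotations named list mapping term -> character gene set; each
#'   is intersected with the universe.
#' @param universe character vector, the gene universe.
#' @return data.frame ordered by p with `term`, `k`, `K`, `n`, `N`, `p`,
#'   `q`.
#' @export
enrich <- function(query, annotations, universe) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query genes outside universe: ", paste(outside, collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    term_genes <- intersect(annotations[[term]], universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, query))
    if (k == 0) return(NULL)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0)))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Overlap counts between top annotation term gene sets
#'
#' Computes the count of genes in every exclusive intersection region of
#' the first `limit` term sets (Venn-diagram regions).
#'
#' @param term_sets named list of character gene sets (>= 2).
#' @param limit how many leading sets to compare (default 3).
#' @return data.frame with `region` (term names joined by `&` for the
#'   sets a gene belongs to) and `count`, one row per non-empty pattern,
#'   plus zero rows for empty regions.
#' @export
annotation_overlap <- function(term_sets, limit = 3L) {
  stopifnot(is.list(term_sets), length(term_sets) >= 2,
            !is.null(names(term_sets)))
  sets <- term_sets[seq_len(min(limit, length(term_sets)))]
  nm <- names(sets)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, nm))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                   drop = FALSE]
  names(patterns) <- nm
  counts <- apply(patterns, 1, function(pt) {
    sum(apply(member, 1, function(row) all(row == pt)))
  })
  region <- apply(patterns, 1, function(pt) paste(nm[as.logical(pt)],
                                                  collapse = "&"))
  data.frame(region = region, count = as.integer(counts), row.names = NULL)
}
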