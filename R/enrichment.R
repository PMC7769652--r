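#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided (over-representation) Fisher's exact test of a differential
#' expression gene list against each gene set, on the 2x2 table
#' (c, n - c; K - c, N - K - n + c) where N is the universe size, K the set
#' size within the universe, n the DE list size and c the overlap. P values
#' are the hypergeometric upper tail Pr(X >= c). BH-FDR is applied within
#' each category (BP, CC, MF separately, pathway separately). The
#' enrichment score is -log10(P).
#'
#' @param de_genes character vector of DE gene symbols, a subset of
#'   `universe`.
#' @param universe character vector of all assayable genes (the array).
#' @param sets a [gene_set_collection()].
#' @param alpha significance threshold on raw P for the `significant` flag.
#' @return data.frame sorted by `enrichment_score` descending with columns
#'   set_id, category, description, c, n, K, N, p_value, fdr,
#'   enrichment_score, significant. Sets disjoint from the universe are
#'   skipped with a warning.
#' @export
fisher_enrichment <- function(de_genes, universe, sets, alpha = 0.05) {
  tab <- enrichment_counts(de_genes, universe, sets)
  tab$p_value <- stats::phyper(tab$c - 1, tab$K, tab$N - tab$K, tab$n,
                               lower.tail = FALSE)
  finish_enrichment(tab, alpha)
}

#' Gene-set over-representation by Pearson chi-square
#'
#' Pearson chi-square (1 df, no continuity correction) on the same 2x2 table
#' as [fisher_enrichment()]. Results where any expected cell count is below
#' 5 carry `unreliable = TRUE`.
#'
#' @inheritParams fisher_enrichment
#' @return as [fisher_enrichment()], plus `statistic` and `unreliable`.
#' @export
chi_square_enrichment <- function(de_genes, universe, sets, alpha = 0.05) {
  tab <- enrichment_counts(de_genes, universe, sets)
  if (!nrow(tab) || any(tab$n == 0))
    stop("value error: empty DE list", call. = FALSE)
  stat <- p <- unrel <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    o <- matrix(c(tab$c[i], tab$n[i] - tab$c[i],
                  tab$K[i] - tab$c[i],
                  tab$N[i] - tab$K[i] - tab$n[i] + tab$c[i]), 2L)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    if (any(e == 0))
      stop("value error: degenerate margins for set ", tab$set_id[i],
           call. = FALSE)
    stat[i] <- sum((o - e)^2 / e)
    p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
    unrel[i] <- any(e < 5)
  }
  tab$statistic <- stat
  tab$p_value <- p
  tab$unreliable <- as.logical(unrel)
  finish_enrichment(tab, alpha)
}

enrichment_counts <- function(de_genes, universe, sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("value error: empty universe", call. = FALSE)
  outside <- setdiff(de_genes, universe)
  if (length(outside))
    stop("containment error: DE gene(s) not in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  de_genes <- unique(de_genes)
  members <- lapply(sets$sets, intersect, universe)
  empty <- lengths(members) == 0L
  if (any(empty))
    warning("skipping ", sum(empty),
            " set(s) disjoint from the universe: ",
            paste(utils::head(sets$info$set_id[empty], 5L), collapse = ", "))
  keep <- which(!empty)
  data.frame(
    set_id = sets$info$set_id[keep],
    category = sets$info$category[keep],
    description = sets$info$description[keep],
    c = vapply(members[keep], function(m) length(intersect(m, de_genes)), 0L),
    n = length(de_genes),
    K = lengths(members[keep]),
    N = length(universe),
    stringsAsFactors = FALSE)
}

finish_enrichment <- function(tab, alpha) {
  tab$fdr <- stats::ave(tab$p_value, tab$category, FUN = bh_fdr)
  tab$enrichment_score <- -log10(tab$p_value)
  tab$significant <- tab$p_value < alpha
  tab <- tab[order(-tab$enrichment_score, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Top enriched terms per category
#'
#' @param results data.frame from [fisher_enrichment()] or
#'   [chi_square_enrichment()].
#' @param k terms per category (default 10, the published figure depth);
#'   ties on score break by set_id ascending.
#' @return data.frame of at most `k` rows per category.
#' @export
top_terms <- function(results, k = 10) {
  if (k == 0) return(results[0, , drop = FALSE])
  out <- do.call(rbind, lapply(split(results, results$category), function(d) {
    d <- d[order(-d$enrichment_score, d$set_id), , drop = FALSE]
    utils::head(d, k)
  }))
  rownames(out) <- NULL
  out
}
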