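#' Pearson correlation with P value
#'
#' Sample Pearson r with a two-sided P from the t transform
#' t = r * sqrt(m - 2) / sqrt(1 - r^2) on m - 2 degrees of freedom; |r| = 1
#' returns P = 0. A zero-variance vector yields r = NA with a warning (the
#' pair is skipped by [build_cnc()]).
#'
#' @param x,y numeric vectors of equal length m >= 3 (log2 intensities in
#'   the coexpression setting).
#' @return list with `r` and `p_value`.
#' @export
pearson_with_p <- function(x, y) {
  m <- length(x)
  if (m != length(y) || m < 3L)
    stop("value error: vectors must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined, pair skipped")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, p_value = cor_p(r, m))
}

cor_p <- function(r, m) {
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt(m - 2) / sqrt(pmax(1 - r^2, 0)),
                            m - 2))
  p
}

#' Build the coding-noncoding coexpression (CNC) network
#'
#' All lncRNA x mRNA pairs are scored by Pearson correlation of their log2
#' intensity profiles across all samples (case and control pooled). An edge
#' is retained when |r| >= `r_cut` (non-strict), P <= `p_cut`, and BH-FDR
#' over the full tested grid <= `fdr_cut` (the published FDR <= 1 gate is
#' vacuous and kept only for fidelity). The magnitude reading of the
#' correlation gate admits negative edges, which are reported with
#' `sign = "negative"`.
#'
#' @param x an `ExpressionMatrix` containing all ids.
#' @param lnc_ids,mrna_ids disjoint probe id sets.
#' @param r_cut,p_cut,fdr_cut gate thresholds (defaults 0.97, 0.05, 1).
#' @return data.frame of edges (lnc_id, mrna_id, r, p_value, fdr, sign)
#'   sorted by |r| descending. Zero-variance probes are skipped with a
#'   warning.
#' @export
build_cnc <- function(x, lnc_ids, mrna_ids, r_cut = 0.97, p_cut = 0.05,
                      fdr_cut = 1.0) {
  if (length(intersect(lnc_ids, mrna_ids)))
    stop("design error: lnc and mRNA id sets must be disjoint", call. = FALSE)
  missing <- setdiff(c(lnc_ids, mrna_ids), probe_ids(x))
  if (length(missing))
    stop("value error: ids absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  lv <- log2(x$values)
  m <- ncol(lv)
  sds <- apply(lv[c(lnc_ids, mrna_ids), , drop = FALSE], 1L, stats::sd)
  dead <- names(sds)[sds == 0]
  if (length(dead)) {
    warning("zero-variance probe(s) skipped: ",
            paste(utils::head(dead, 5L), collapse = ", "))
    lnc_ids <- setdiff(lnc_ids, dead)
    mrna_ids <- setdiff(mrna_ids, dead)
  }
  if (!length(lnc_ids) || !length(mrna_ids))
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      r = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), sign = character(0)))
  rmat <- stats::cor(t(lv[lnc_ids, , drop = FALSE]),
                     t(lv[mrna_ids, , drop = FALSE]))
  grid <- expand.grid(lnc_id = lnc_ids, mrna_id = mrna_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$r <- as.vector(rmat)
  grid$p_value <- cor_p(grid$r, m)
  grid$fdr <- bh_fdr(grid$p_value)
  grid$sign <- ifelse(grid$r > 0, "positive", "negative")
  edges <- grid[abs(grid$r) >= r_cut & grid$p_value <= p_cut &
                  grid$fdr <= fdr_cut, , drop = FALSE]
  edges <- edges[order(-abs(edges$r)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Node degrees of a network
#'
#' Degree = number of incident edges per node (the "link numbers of the
#' node" used for node sizing in network figures).
#'
#' @param edges data.frame with `source`/`target` columns, or a CNC edge
#'   table with `lnc_id`/`mrna_id`.
#' @return data.frame (node, degree) sorted by degree descending.
#' @export
degree_table <- function(edges) {
  ends <- if (all(c("source", "target") %in% names(edges)))
    c(edges$source, edges$target) else c(edges$lnc_id, edges$mrna_id)
  if (!length(ends))
    return(data.frame(node = character(0), degree = integer(0)))
  tab <- sort(table(ends), decreasing = TRUE)
  data.frame(node = names(tab), degree = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a CNC network for Cytoscape
#'
#' @param edges CNC edge table from [build_cnc()].
#' @param path_prefix output prefix for the node/edge/SIF files.
#' @return the written file paths, invisibly.
#' @export
write_cnc_network <- function(edges, path_prefix) {
  nodes <- data.frame(
    id = c(unique(edges$lnc_id), unique(edges$mrna_id)),
    biotype = rep(c("lncRNA", "mRNA"),
                  c(length(unique(edges$lnc_id)),
                    length(unique(edges$mrna_id)))),
    stringsAsFactors = FALSE)
  e <- data.frame(source = edges$lnc_id, target = edges$mrna_id,
                  weight = edges$r, sign = edges$sign,
                  stringsAsFactors = FALSE)
  write_network_tables(nodes, e, path_prefix)
}
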