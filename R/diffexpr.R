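#' Quantile normalization across samples
#'
#' Maps every sample (column) onto the across-sample mean sorted intensity
#' vector: after normalization each column's sorted values equal the
#' reference quantiles; tied intensities within a column receive the mean of
#' their tied target values. Operates and returns on the linear scale.
#'
#' @param x an [expression_matrix()].
#' @return a quantile-normalized `ExpressionMatrix`.
#' @export
normalize_quantile <- function(x) {
  v <- x$values
  if (ncol(v) < 2L)
    stop("design error: quantile normalization needs >= 2 samples",
         call. = FALSE)
  ref <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(col) {
    mapped <- numeric(length(col))
    mapped[order(col)] <- ref
    # ties within a column share the mean of their assigned quantiles
    stats::ave(mapped, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, x$groups)
}

#' Per-probe unpaired t-test on log2 intensities
#'
#' Pooled-variance two-sample t-test (case vs control) computed on log2
#' intensities, df = n1 + n2 - 2, two-sided P. Shares its kernel with
#' [t_test_from_summary()].
#'
#' @param x an `ExpressionMatrix` with >= 2 samples per group.
#' @param probe probe id.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
t_test_unpaired <- function(x, probe) {
  if (min(table(x$groups)) < 2L)
    stop("design error: t-test needs >= 2 samples per group", call. = FALSE)
  lv <- log2(x$values[probe, , drop = TRUE])
  t_test_pooled(lv[x$groups == "case"], lv[x$groups == "control"])
}

#' Fold change as the absolute ratio of group mean intensities
#'
#' Linear-scale ratio r = mean(case) / mean(control); returns (r, "Up") when
#' r >= 1 and (1/r, "Down") otherwise, so the reported fold change is always
#' >= 1 with direction carried separately. Equal means tie-break to "Up".
#'
#' @inheritParams t_test_unpaired
#' @return list with `fc` (>= 1) and `regulation` (`"Up"`/`"Down"`).
#' @export
fold_change <- function(x, probe) {
  v <- x$values[probe, , drop = TRUE]
  r <- mean(v[x$groups == "case"]) / mean(v[x$groups == "control"])
  if (r >= 1) list(fc = r, regulation = "Up")
  else list(fc = 1 / r, regulation = "Down")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted P values: monotone in rank, capped at 1, returned in the
#' original order. Thin validated wrapper over `stats::p.adjust(method =
#' "BH")`; the test suite checks it against a brute-force implementation of
#' the step-up definition.
#'
#' @param p numeric vector of P values in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("value error: p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

diffexpr_stats <- function(x) {
  lv <- log2(x$values)
  case <- x$groups == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L)
    stop("design error: t-test needs >= 2 samples per group", call. = FALSE)
  m1 <- rowMeans(lv[, case, drop = FALSE])
  m2 <- rowMeans(lv[, !case, drop = FALSE])
  v1 <- rowSums((lv[, case, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((lv[, !case, drop = FALSE] - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- ifelse(sp2 == 0, ifelse(m1 == m2, 1, 0), 2 * stats::pt(-abs(tt), df))
  ratio <- rowMeans(x$values[, case, drop = FALSE]) /
    rowMeans(x$values[, !case, drop = FALSE])
  data.frame(probe_name = probe_ids(x),
             p_value = p,
             fc = ifelse(ratio >= 1, ratio, 1 / ratio),
             regulation = ifelse(ratio >= 1, "Up", "Down"),
             stringsAsFactors = FALSE)
}

#' Differential expression screen
#'
#' The screening gate: probes with fold change strictly greater than
#' `fc_cut` AND raw P strictly below `p_cut` (the published gate uses raw P,
#' not FDR; FDR is still reported). Records carry transcript id, chromosome
#' and strand from the annotation and are partitioned by regulation
#' direction.
#'
#' @param x an `ExpressionMatrix` (linear scale; tests run on log2).
#' @param annotation a [probe_annotation()] covering every probe.
#' @param fc_cut,p_cut gate thresholds (strict inequalities); defaults 2 and
#'   0.05.
#' @return list with data.frames `up`, `down` (columns seqname, probe_name,
#'   p_value, fdr, fc, regulation, chrom, strand, biotype, gene_symbol,
#'   sorted by fc descending) and `all` (every probe, unsorted).
#' @export
screen_de <- function(x, annotation, fc_cut = 2, p_cut = 0.05) {
  annotation <- probe_annotation(annotation)
  unk <- setdiff(probe_ids(x), annotation$probe_name)
  if (length(unk))
    stop("annotation error: unannotated probe(s): ",
         paste(utils::head(unk, 5L), collapse = ", "), call. = FALSE)
  res <- diffexpr_stats(x)
  res$fdr <- bh_fdr(res$p_value)
  idx <- match(res$probe_name, annotation$probe_name)
  res <- cbind(annotation[idx, c("seqname", "chrom", "strand", "biotype",
                                 "gene_symbol")], res)
  res <- res[, c("seqname", "probe_name", "p_value", "fdr", "fc",
                 "regulation", "chrom", "strand", "biotype", "gene_symbol")]
  rownames(res) <- NULL
  hit <- res$fc > fc_cut & res$p_value < p_cut
  ord <- function(d) d[order(-d$fc, d$p_value, d$seqname), , drop = FALSE]
  list(up = ord(res[hit & res$regulation == "Up", , drop = FALSE]),
       down = ord(res[hit & res$regulation == "Down", , drop = FALSE]),
       all = res)
}

#' Top-k table of screened records
#'
#' Ranked as in published top-20 tables: fold change descending, ties broken
#' by ascending P then by seqname.
#'
#' @param records data.frame of screened records (one direction).
#' @param k number of records to keep; `k > 0`.
#' @return the first `k` records after sorting (all of them if fewer).
#' @export
top_table <- function(records, k = 20) {
  if (k <= 0) stop("value error: k must be > 0", call. = FALSE)
  records <- records[order(-records$fc, records$p_value, records$seqname), ,
                     drop = FALSE]
  utils::head(records, k)
}

#' @rdname screen_de
#' @param de result of [screen_de()].
#' @param path_prefix output prefix; writes `<prefix>_up.tsv` and
#'   `<prefix>_down.tsv` shaped like the published top tables.
#' @export
write_de_tables <- function(de, path_prefix) {
  cols <- c("seqname", "probe_name", "p_value", "fc", "regulation",
            "chrom", "strand")
  for (dir in c("up", "down"))
    utils::write.table(de[[dir]][cols], paste0(path_prefix, "_", dir, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_prefix)
}
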