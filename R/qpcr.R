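#' 2^-ddCt relative quantification
#'
#' Replicate Ct values are averaged per sample and gene; the delta-Ct is
#' target mean Ct minus reference mean Ct; the delta-delta-Ct subtracts the
#' MEAN delta-Ct of the calibrator group (so the calibrator group is
#' centered as a group, not on a single reference sample); the relative
#' quantity is rq = 2^(-ddCt). By construction the calibrator group's
#' geometric mean rq is 1.
#'
#' @param ct_table long-format data.frame with columns `sample_id`, `group`
#'   (`case`/`control`), `gene_id`, `ct` (and optionally `replicate`), as
#'   produced by [simulate_ct_table()] or read from a TSV.
#' @param target_gene,reference_gene gene ids; every sample must carry both,
#'   otherwise a pairing error is raised.
#' @param calibrator_group group whose mean delta-Ct anchors the ddCt
#'   (default `"control"`).
#' @return data.frame with sample_id, group, delta_ct, delta_delta_ct, rq.
#' @export
ddct <- function(ct_table, target_gene, reference_gene,
                 calibrator_group = "control") {
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(ct_table)))
    stop("schema error: Ct table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0))
    stop("value error: Ct values must be finite and > 0", call. = FALSE)
  mean_ct <- stats::aggregate(ct ~ sample_id + group + gene_id,
                              ct_table, mean)
  tgt <- mean_ct[mean_ct$gene_id == target_gene, ]
  ref <- mean_ct[mean_ct$gene_id == reference_gene, ]
  samples <- unique(ct_table$sample_id)
  miss <- setdiff(samples, intersect(tgt$sample_id, ref$sample_id))
  if (length(miss))
    stop("pairing error: sample(s) missing target or reference Ct: ",
         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(samples, tgt$sample_id)
  out <- data.frame(sample_id = samples,
                    group = tgt$group[idx],
                    delta_ct = tgt$ct[idx] -
                      ref$ct[match(samples, ref$sample_id)],
                    stringsAsFactors = FALSE)
  cal <- out$delta_ct[out$group == calibrator_group]
  if (!length(cal))
    stop("design error: calibrator group '", calibrator_group,
         "' is empty", call. = FALSE)
  out$delta_delta_ct <- out$delta_ct - mean(cal)
  out$rq <- 2^(-out$delta_delta_ct)
  out
}

#' Case-control comparison of relative expression
#'
#' Pooled-variance two-sided t-test (shared kernel with the differential
#' expression module) on per-sample relative quantities; with
#' `log_scale = TRUE` the test runs on -ddCt (the log2 relative quantity)
#' instead.
#'
#' @param rel output of [ddct()]; both groups need >= 2 samples.
#' @param alpha significance threshold for the flag (default 0.05).
#' @param log_scale test on -ddCt instead of rq.
#' @return list with `t`, `df`, `p_value`, `mean_case`, `mean_control`
#'   (always rq means), `significant`.
#' @export
compare_groups <- function(rel, alpha = 0.05, log_scale = FALSE) {
  v <- if (log_scale) -rel$delta_delta_ct else rel$rq
  res <- t_test_pooled(v[rel$group == "case"], v[rel$group == "control"])
  list(t = res$t, df = res$df, p_value = res$p_value,
       mean_case = mean(rel$rq[rel$group == "case"]),
       mean_control = mean(rel$rq[rel$group == "control"]),
       significant = res$p_value < alpha)
}
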