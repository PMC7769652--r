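#' Shared targeting miRNAs of a gene pair
#'
#' @param targets a [mirna_target_table()] data.frame.
#' @param gene_a,gene_b gene ids; both must appear as targets of >= 1 miRNA.
#' @return list with `K` (miRNAs targeting `gene_a`), `n` (targeting
#'   `gene_b`), `c` (targeting both) and `shared` (the common miRNA ids).
#' @export
shared_mirnas <- function(targets, gene_a, gene_b) {
  ma <- targets$mirna_id[targets$target_id == gene_a]
  mb <- targets$mirna_id[targets$target_id == gene_b]
  if (!length(ma) || !length(mb))
    stop("lookup miss: gene absent from target table: ",
         if (!length(ma)) gene_a else gene_b, call. = FALSE)
  shared <- intersect(ma, mb)
  list(K = length(unique(ma)), n = length(unique(mb)),
       c = length(shared), shared = shared)
}

#' Hypergeometric ceRNA pair P value
#'
#' Upper-tail probability that two genes share at least `c` targeting miRNAs
#' by chance, given `N` miRNAs in total, `K` targeting the first gene and
#' `n` targeting the second:
#' \deqn{P = \sum_{i=c}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} \Big/ \binom{N}{n}}
#' The tail includes i = c. Terms are accumulated from log-space binomial
#' coefficients for overflow safety at array-scale N; `c = 0` returns
#' exactly 1 (the full support).
#'
#' @param N total miRNAs used for target prediction.
#' @param K,n miRNAs targeting each gene of the pair.
#' @param c shared miRNA count, `0 <= c <= min(K, n)`.
#' @return the tail probability, in (0, 1].
#' @examples
#' cerna_p(20, 5, 6, 2)  # 18740/38760
#' @export
cerna_p <- function(N, K, n, c) {
  if (K > N) stop("value error: K <= N violated", call. = FALSE)
  if (n > N) stop("value error: n <= N violated", call. = FALSE)
  if (c < 0) stop("value error: c >= 0 violated", call. = FALSE)
  if (c > min(K, n)) stop("value error: c <= min(K, n) violated", call. = FALSE)
  if (c == 0) return(1)
  i <- c:min(K, n)
  terms <- exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  min(sum(terms), 1)
}

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' Candidate pairs are the differentially expressed lncRNAs crossed with the
#' differentially expressed mRNAs (the expression-level filtering standing in
#' for the ceRNA concentration condition). Each pair is scored by
#' [cerna_p()] with N = number of distinct miRNAs in the target table, and
#' retained iff its shared-miRNA count `c >= min_shared` (the sponge-count
#' condition) and P < `p_cut`. With `weight_mre = TRUE` the shared count is
#' weighted by the pair's minimum MRE count per shared miRNA (the MRE
#' inequality condition) when gating on `min_shared`; the hypergeometric
#' test itself always uses plain counts.
#'
#' @param targets a [mirna_target_table()] data.frame.
#' @param de_lnc,de_mrna differentially expressed gene ids.
#' @param min_shared minimum shared miRNA count (default 3).
#' @param p_cut P threshold (strict <; default 0.05).
#' @param weight_mre use MRE-weighted shared counts for the `min_shared`
#'   gate.
#' @param n_mirna the hypergeometric N ("total miRNAs used to predict
#'   targets"). Defaults to the number of distinct miRNAs in `targets`,
#'   appropriate when the table covers the full prediction run; supply the
#'   true universe size when the table is a sparse excerpt.
#' @return list with `pairs` (data.frame gene_a, gene_b, N, K, n, c,
#'   p_value for retained pairs), `tested` (all scored pairs), `nodes` and
#'   `edges` (tripartite tables: undirected `cerna` edges between the pair
#'   genes, directed `targets` edges from each shared miRNA to both genes).
#'   Genes absent from the target table are skipped with a message; an empty
#'   candidate set yields an empty network.
#' @export
build_cerna <- function(targets, de_lnc, de_mrna, min_shared = 3,
                        p_cut = 0.05, weight_mre = FALSE, n_mirna = NULL) {
  targets <- mirna_target_table(targets)
  N <- if (is.null(n_mirna)) length(unique(targets$mirna_id))
       else as.integer(n_mirna)
  if (N < length(unique(targets$mirna_id)))
    stop("value error: n_mirna smaller than the distinct miRNAs observed",
         call. = FALSE)
  present <- unique(targets$target_id)
  drop_l <- setdiff(de_lnc, present); drop_m <- setdiff(de_mrna, present)
  if (length(drop_l) || length(drop_m))
    message("skipping ", length(drop_l) + length(drop_m),
            " gene(s) absent from the target table")
  de_lnc <- intersect(de_lnc, present)
  de_mrna <- intersect(de_mrna, present)
  reg <- split(targets$mirna_id, targets$target_id)
  mre <- split(targets$mre_count,
               paste(targets$target_id, targets$mirna_id))
  cand <- expand.grid(gene_a = de_lnc, gene_b = de_mrna,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cand <- cand[cand$gene_a != cand$gene_b, , drop = FALSE]
  if (!nrow(cand)) {
    message("empty candidate set: returning empty network")
    empty <- data.frame(gene_a = character(0), gene_b = character(0),
                        N = integer(0), K = integer(0), n = integer(0),
                        c = integer(0), p_value = numeric(0))
    return(list(pairs = empty, tested = empty,
                nodes = data.frame(id = character(0), biotype = character(0)),
                edges = data.frame(source = character(0),
                                   target = character(0),
                                   type = character(0))))
  }
  score <- lapply(seq_len(nrow(cand)), function(i) {
    a <- cand$gene_a[i]; b <- cand$gene_b[i]
    sm <- shared_mirnas(targets, a, b)
    gate_c <- if (weight_mre && length(sm$shared)) {
      sum(vapply(sm$shared, function(m)
        min(mre[[paste(a, m)]], mre[[paste(b, m)]]), 0))
    } else sm$c
    data.frame(gene_a = a, gene_b = b, N = N, K = sm$K, n = sm$n, c = sm$c,
               gate_c = gate_c, p_value = cerna_p(N, sm$K, sm$n, sm$c),
               stringsAsFactors = FALSE)
  })
  tested <- do.call(rbind, score)
  keep <- tested[tested$gate_c >= min_shared & tested$p_value < p_cut, ,
                 drop = FALSE]
  keep <- keep[order(keep$p_value), , drop = FALSE]
  rownames(keep) <- rownames(tested) <- NULL
  pairs <- keep[setdiff(names(keep), "gate_c")]

  # tripartite export: ceRNA edges (undirected) + miRNA->target edges (directed)
  edges <- data.frame(source = pairs$gene_a, target = pairs$gene_b,
                      type = rep("cerna", nrow(pairs)),
                      stringsAsFactors = FALSE)
  mir_nodes <- character(0)
  for (i in seq_len(nrow(pairs))) {
    sh <- intersect(reg[[pairs$gene_a[i]]], reg[[pairs$gene_b[i]]])
    mir_nodes <- union(mir_nodes, sh)
    edges <- rbind(edges,
                   data.frame(source = rep(sh, 2L),
                              target = rep(c(pairs$gene_a[i],
                                             pairs$gene_b[i]), each = length(sh)),
                              type = "targets", stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  nodes <- data.frame(
    id = c(unique(pairs$gene_a), unique(pairs$gene_b), mir_nodes),
    biotype = rep(c("lncRNA", "mRNA", "miRNA"),
                  c(length(unique(pairs$gene_a)),
                    length(unique(pairs$gene_b)), length(mir_nodes))),
    stringsAsFactors = FALSE)
  list(pairs = pairs, tested = tested[setdiff(names(tested), "gate_c")],
       nodes = nodes, edges = edges)
}
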