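# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the library calls backing them).

# Brute-force Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, original order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- vapply(seq_len(m), function(i) min(m * sp[i:m] / (i:m)), 0)
  res <- numeric(m)
  res[o] <- pmin(adj, 1)
  res
}

# Exact hypergeometric upper tail from integer binomial coefficients.
exact_hyper_tail <- function(N, K, n, c) {
  if (c == 0) return(1)
  i <- c:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# True exhaustive enumeration over all C(N, n) draws (small N only).
enum_hyper_tail <- function(N, K, n, c) {
  if (n == 0) return(as.numeric(c == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "successes"
  mean(hits >= c)
}

# Two-sided Fisher P by enumerating all 2x2 tables with the observed margins.
enum_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(N - r1, c1 - xs) / choose(N, c1)
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled two-sample t by direct formula evaluation.
brute_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# Pearson r and the t-transform P by direct covariance-formula evaluation.
brute_pearson <- function(x, y) {
  m <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(m - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(tt), m - 2))
}

# Small fixture: 4-probe matrix with known group means.
tiny_matrix <- function() {
  v <- rbind(p1 = c(8, 8, 8, 2, 2),     # case mean 8, ctrl mean 2
             p2 = c(2, 2, 2, 8, 8),     # case mean 2, ctrl mean 8
             p3 = c(5, 5, 5, 5, 5),     # equal
             p4 = c(4, 6, 5, 3, 7))
  colnames(v) <- paste0("s", 1:5)
  expression_matrix(v, c(s1 = "case", s2 = "case", s3 = "case",
                         s4 = "control", s5 = "control"))
}

tiny_annotation <- function(x) {
  probe_annotation(data.frame(
    seqname = paste0("T", probe_ids(x)), probe_name = probe_ids(x),
    chrom = "chr1", strand = "+",
    biotype = rep_len(c("lncRNA", "mRNA"), length(probe_ids(x))),
    gene_symbol = paste0("G", probe_ids(x)), stringsAsFactors = FALSE))
}
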