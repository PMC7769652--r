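#' Simulate a two-group lncRNA/mRNA microarray experiment
#'
#' Generates a linear-scale intensity matrix under a log-normal model:
#' per-probe baseline log2 mean drawn from N(8, 1.5^2), a group shift of
#' +/- log2FC added to case samples for planted differentially expressed
#' probes, and Gaussian noise with standard deviation `sigma_log2` in log2
#' space, then exponentiated. Defaults emulate a 5-vs-3 tissue design at a
#' desk-scale probe count (2000 lncRNA + 1200 mRNA; the full-array scale of
#' ~35k lncRNA / ~20k mRNA probes is reachable by raising `n_lnc`/`n_mrna`).
#' Planted fold changes default to log2FC in [1, 5.46] (up to ~44x, the
#' largest effect the assay design contemplates).
#'
#' All generators in this module are deterministic given `seed` and restore
#' the caller's RNG state.
#'
#' @param seed integer seed.
#' @param n_case,n_ctrl samples per group (each >= 2).
#' @param n_lnc,n_mrna probe counts per biotype.
#' @param frac_de fraction of probes planted as differentially expressed,
#'   in (0, 0.5]; applied to each biotype (count rounded down).
#' @param fc_log2_range length-2 interval from which planted |log2FC| is
#'   drawn uniformly (a degenerate interval plants a fixed effect).
#' @param sigma_log2 log2-scale noise SD (0 gives the noiseless limit).
#' @return list with `matrix` (an [expression_matrix()]), `annotation`
#'   (a [probe_annotation()] data.frame) and `truth` (list with `de_probes`:
#'   data.frame probe_name, seqname, biotype, direction, log2fc).
#' @export
simulate_expression <- function(seed, n_case = 5, n_ctrl = 3,
                                n_lnc = 2000, n_mrna = 1200,
                                frac_de = 0.05,
                                fc_log2_range = c(1, 5.46),
                                sigma_log2 = 0.25) {
  if (n_case < 2 || n_ctrl < 2)
    stop("design error: need >= 2 samples per group (t-test undefined)",
         call. = FALSE)
  if (frac_de < 0 || frac_de > 0.5)
    stop("value error: frac_de must lie in [0, 0.5]", call. = FALSE)
  with_seed(seed, {
    n_probe <- n_lnc + n_mrna
    biotype <- rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna))
    probe <- sprintf("ASHGV%05d", seq_len(n_probe))
    seqname <- ifelse(biotype == "lncRNA",
                      sprintf("SYNLNC%05d", seq_len(n_probe)),
                      sprintf("SYNM%05d", seq_len(n_probe)))
    samples <- c(sprintf("AAA_%d", seq_len(n_case)),
                 sprintf("CTRL_%d", seq_len(n_ctrl)))
    groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                              samples)

    n_de <- floor(frac_de * n_lnc) + floor(frac_de * n_mrna)
    de_idx <- c(sample.int(n_lnc, floor(frac_de * n_lnc)),
                n_lnc + sample.int(n_mrna, floor(frac_de * n_mrna)))
    direction <- sample(c(1, -1), n_de, replace = TRUE)
    log2fc <- stats::runif(n_de, fc_log2_range[1L], fc_log2_range[2L])

    base <- stats::rnorm(n_probe, mean = 8, sd = 1.5)
    mu <- matrix(base, n_probe, n_case + n_ctrl)
    mu[de_idx, seq_len(n_case)] <- mu[de_idx, seq_len(n_case)] +
      direction * log2fc
    lv <- mu + stats::rnorm(length(mu), sd = sigma_log2)
    values <- 2^lv
    dimnames(values) <- list(probe, samples)

    annotation <- probe_annotation(data.frame(
      seqname = seqname, probe_name = probe,
      chrom = paste0("chr", 1 + (seq_len(n_probe) - 1) %% 22),
      strand = rep_len(c("+", "-"), n_probe),
      biotype = biotype,
      gene_symbol = ifelse(biotype == "mRNA",
                           sprintf("GENE%05d", seq_len(n_probe)),
                           NA_character_),
      stringsAsFactors = FALSE))
    truth <- list(de_probes = data.frame(
      probe_name = probe[de_idx], seqname = seqname[de_idx],
      biotype = biotype[de_idx],
      direction = ifelse(direction > 0, "Up", "Down"),
      log2fc = log2fc, stringsAsFactors = FALSE))
    list(matrix = expression_matrix(values, groups),
         annotation = annotation, truth = truth)
  })
}

#' Plant correlated lncRNA-mRNA pairs into an expression matrix
#'
#' For each planted pair the mRNA log2 profile is rewritten as a
#' `rho`-weighted copy of the (standardized) lncRNA profile plus independent
#' Gaussian noise scaled by sqrt(1 - rho^2), so the expected sample Pearson
#' correlation is approximately `rho`. The rewritten profile keeps the
#' mRNA's original log2 mean and unit-SD scale times the lncRNA profile SD.
#'
#' @param seed integer seed.
#' @param x an `ExpressionMatrix` whose probes carry biotypes via
#'   `annotation`.
#' @param annotation the matching [probe_annotation()].
#' @param pairs number of pairs to plant (<= available lnc x mRNA probes).
#' @param rho target correlation, |rho| < 1.
#' @return list with `matrix` (modified copy) and `truth` (data.frame
#'   lnc_probe, mrna_probe, rho, sign).
#' @export
simulate_coexpression <- function(seed, x, annotation, pairs = 10,
                                  rho = 0.99) {
  if (abs(rho) >= 1)
    stop("value error: rho must lie strictly inside (-1, 1)", call. = FALSE)
  lnc <- annotation$probe_name[annotation$biotype == "lncRNA"]
  mrna <- annotation$probe_name[annotation$biotype == "mRNA"]
  if (pairs > min(length(lnc), length(mrna)))
    stop("value error: more pairs requested than disjoint probes available",
         call. = FALSE)
  with_seed(seed, {
    v <- log2(x$values)
    li <- sample(lnc, pairs)
    mi <- sample(mrna, pairs)
    m <- ncol(v)
    for (k in seq_len(pairs)) {
      z <- as.numeric(scale(v[li[k], ]))
      y <- rho * z + sqrt(1 - rho^2) * stats::rnorm(m)
      v[mi[k], ] <- mean(v[mi[k], ]) + stats::sd(v[li[k], ]) * y
    }
    out <- 2^v
    dimnames(out) <- dimnames(x$values)
    list(matrix = expression_matrix(out, x$groups),
         truth = data.frame(lnc_probe = li, mrna_probe = mi, rho = rho,
                            sign = ifelse(rho >= 0, "positive", "negative"),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a miRNA target table with planted sponge pairs
#'
#' Background interactions are Bernoulli(`background_rate`) over the
#' miRNA x gene grid. Each planted (lncRNA, mRNA) sponge pair is then forced
#' to share exactly `shared_per_pair` miRNAs: a dedicated miRNA subset is
#' added to both genes and any other accidentally shared miRNA is removed
#' from the mRNA side.
#'
#' @param seed integer seed.
#' @param n_mirna number of distinct miRNAs (the hypergeometric N).
#' @param lnc_ids,mrna_ids gene universes for the two biotypes.
#' @param sponge_pairs number of planted pairs.
#' @param shared_per_pair shared-miRNA count per planted pair
#'   (<= `n_mirna`).
#' @param background_rate Bernoulli rate for background interactions.
#' @return list with `targets` (a [mirna_target_table()] data.frame) and
#'   `truth` (data.frame lnc, mrna, shared).
#' @export
simulate_mirna_targets <- function(seed, n_mirna = 200, lnc_ids, mrna_ids,
                                   sponge_pairs = 5, shared_per_pair = 5,
                                   background_rate = 0.02) {
  if (shared_per_pair > n_mirna)
    stop("infeasible error: shared_per_pair > n_mirna", call. = FALSE)
  if (sponge_pairs > min(length(lnc_ids), length(mrna_ids)))
    stop("value error: not enough genes for the requested pairs", call. = FALSE)
  with_seed(seed, {
    mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
    genes <- c(lnc_ids, mrna_ids)
    reg <- lapply(stats::setNames(genes, genes), function(g)
      mirnas[stats::runif(n_mirna) < background_rate])
    pl <- sample(lnc_ids, sponge_pairs)
    pm <- sample(mrna_ids, sponge_pairs)
    for (k in seq_len(sponge_pairs)) {
      shared <- sample(mirnas, shared_per_pair)
      reg[[pl[k]]] <- union(reg[[pl[k]]], shared)
      reg[[pm[k]]] <- union(setdiff(reg[[pm[k]]], reg[[pl[k]]]), shared)
    }
    tab <- do.call(rbind, lapply(genes, function(g) {
      if (!length(reg[[g]])) return(NULL)
      data.frame(mirna_id = reg[[g]], target_id = g,
                 mre_count = 1L + stats::rpois(length(reg[[g]]), 1),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(tab))
      tab <- data.frame(mirna_id = character(0), target_id = character(0),
                        mre_count = integer(0))
    list(targets = mirna_target_table(tab),
         truth = data.frame(lnc = pl, mrna = pm, shared = shared_per_pair,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate lncRNA and coding loci covering all six positional classes
#'
#' Lays out `per_class` independent cassettes per category along one
#' synthetic chromosome (one coding gene of three exons plus one lncRNA per
#' cassette, 40 kb apart so cassettes never interact within the 1 kb
#' bidirectional window) such that each lncRNA satisfies exactly its
#' intended classification rule.
#'
#' @param seed integer seed (cassette order is shuffled).
#' @param per_class lncRNA loci per category (>= 1).
#' @param genome_length chromosome length in bp; a placement error is raised
#'   when the cassettes do not fit.
#' @return list with `lnc` and `genes` loci `GRanges` and `truth`
#'   (data.frame lnc, class).
#' @export
simulate_loci <- function(seed, per_class = 10, genome_length = 3e7) {
  if (per_class < 1) stop("value error: per_class >= 1", call. = FALSE)
  classes <- c("intergenic", "natural_antisense", "intronic_antisense",
               "exon_sense_overlapping", "bidirectional",
               "intron_sense_overlapping")
  n <- 6L * per_class
  cassette <- 40000L
  if (1000L + n * cassette > genome_length)
    stop("placement error: genome too short for ", n, " cassettes",
         call. = FALSE)
  with_seed(seed, {
    cls <- sample(rep(classes, per_class))
    offs <- 1000L + (seq_len(n) - 1L) * cassette  # headroom for upstream lnc
    gname <- sprintf("SYNGENE%04d", seq_len(n))
    lname <- sprintf("SYNLNC%04d", seq_len(n))
    # gene template (relative, 0-based half-open): exons [0,1000), [3000,4000), [6000,7000)
    genes <- loci(gname, "chrS", offs, offs + 7000L, rep("+", n),
                  block_starts = rep(list(c(0L, 3000L, 6000L)), n),
                  block_sizes = rep(list(c(1000L, 1000L, 1000L)), n))
    ls <- le <- integer(n)
    lstrand <- character(n)
    for (i in seq_len(n)) {
      o <- offs[i]
      switch(cls[i],
        exon_sense_overlapping = { ls[i] <- o + 500L; le[i] <- o + 1500L
                                   lstrand[i] <- "+" },
        intron_sense_overlapping = { ls[i] <- o + 1200L; le[i] <- o + 1800L
                                     lstrand[i] <- "+" },
        intronic_antisense = { ls[i] <- o + 4200L; le[i] <- o + 4800L
                               lstrand[i] <- "-" },
        natural_antisense = { ls[i] <- o + 800L; le[i] <- o + 1400L
                              lstrand[i] <- "-" },
        bidirectional = { ls[i] <- o - 800L; le[i] <- o - 200L
                          lstrand[i] <- "-" },
        intergenic = { ls[i] <- o + 20000L; le[i] <- o + 20500L
                       lstrand[i] <- "+" })
    }
    lnc <- loci(lname, "chrS", ls, le, lstrand)
    list(lnc = lnc, genes = genes,
         truth = data.frame(lnc = lname, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a triplicate qPCR Ct table
#'
#' One target gene and one reference gene (beta-actin-style) per sample,
#' three replicate Ct values each. A sample-specific RNA-input effect is
#' shared by target and reference (it cancels in the delta-Ct), and case
#' samples carry a planted target shift of `-true_log2_ratio` cycles so that
#' the planted delta-delta-Ct equals `-true_log2_ratio` and the expected
#' relative quantity is `2^true_log2_ratio`.
#'
#' @param seed integer seed.
#' @param n_case,n_ctrl samples per group (each >= 2).
#' @param true_log2_ratio planted case/control log2 expression ratio.
#' @param ct_sd per-replicate technical noise SD, cycles (>= 0).
#' @param target_gene,reference_gene gene ids written into the table.
#' @return data.frame with columns sample_id, group, gene_id, replicate, ct.
#' @export
simulate_ct_table <- function(seed, n_case = 11, n_ctrl = 12,
                              true_log2_ratio = -1, ct_sd = 0.2,
                              target_gene = "T181556",
                              reference_gene = "ACTB") {
  if (n_case < 2 || n_ctrl < 2)
    stop("design error: need >= 2 samples per group", call. = FALSE)
  if (ct_sd < 0) stop("value error: ct_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    samples <- c(sprintf("AAA_%02d", seq_len(n_case)),
                 sprintf("CTRL_%02d", seq_len(n_ctrl)))
    group <- rep(c("case", "control"), c(n_case, n_ctrl))
    loading <- stats::rnorm(length(samples), 0, 0.5)
    ref_base <- 20; target_base <- 25
    rows <- lapply(seq_along(samples), function(i) {
      shift <- if (group[i] == "case") -true_log2_ratio else 0
      data.frame(
        sample_id = samples[i], group = group[i],
        gene_id = rep(c(target_gene, reference_gene), each = 3L),
        replicate = rep(1:3, 2L),
        ct = c(target_base + loading[i] + shift +
                 stats::rnorm(3, 0, ct_sd),
               ref_base + loading[i] + stats::rnorm(3, 0, ct_sd)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate gene sets with one planted enriched set
#'
#' Builds `n_sets` random gene sets from the universe; the first set
#' (`SET001`) is loaded with DE genes at `enrich_factor` times the
#' background inclusion rate, giving a positive control for
#' over-representation analysis.
#'
#' @param seed integer seed.
#' @param universe gene universe.
#' @param de_genes DE gene list (subset of universe).
#' @param n_sets number of sets.
#' @param set_size members per set.
#' @param enrich_factor DE-gene over-sampling factor for the planted set.
#' @param category category label for all sets.
#' @return a [gene_set_collection()]; the planted set is `SET001`.
#' @export
simulate_gene_sets <- function(seed, universe, de_genes, n_sets = 20,
                               set_size = 50, enrich_factor = 5,
                               category = "BP") {
  with_seed(seed, {
    bg <- setdiff(universe, de_genes)
    members <- vector("list", n_sets)
    n_de_in <- min(length(de_genes),
                   round(set_size * enrich_factor *
                           length(de_genes) / length(universe)))
    members[[1L]] <- c(sample(de_genes, n_de_in),
                       sample(bg, set_size - n_de_in))
    for (i in seq_len(n_sets - 1L) + 1L)
      members[[i]] <- sample(universe, set_size)
    gene_set_collection(sprintf("SET%03d", seq_len(n_sets)),
                        rep(category, n_sets),
                        sprintf("synthetic set %d", seq_len(n_sets)),
                        members)
  })
}

# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("value error: seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
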