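#' Six-way positional classification of a lncRNA locus
#'
#' Assigns a lncRNA to exactly one positional category relative to a coding
#' annotation, by strand and overlap geometry. The array-annotation
#' convention gives no formal rule set, so the rules are fixed here with an
#' explicit precedence; the first matching rule over any gene wins:
#'
#' 1. `exon_sense_overlapping` - same strand, >= 1 bp overlap between lnc
#'    exons and gene exons;
#' 2. `intron_sense_overlapping` - same strand, lnc span overlaps the gene
#'    span but with no exon-exon overlap;
#' 3. `intronic_antisense` - opposite strand, lnc span fully inside one
#'    intron of the gene;
#' 4. `natural_antisense` - opposite strand, >= 1 bp span overlap, not
#'    rule 3;
#' 5. `bidirectional` - no span overlap, opposite strands, TSS-to-TSS
#'    distance <= `bidir_window` with divergent (head-to-head) orientation;
#' 6. `intergenic` - none of the above.
#'
#' A lncRNA overlapping several genes takes the highest-precedence class over
#' any of them; remaining ties break by nearest TSS for the reported matched
#' gene.
#'
#' @param lnc single-locus `GRanges` (see [loci()]).
#' @param genes coding loci `GRanges` (may be empty).
#' @param bidir_window maximum TSS-to-TSS distance, bp, for the bidirectional
#'   call (default 1000, the conventional bidirectional-promoter window).
#' @return list with `class` (one of the six labels) and `gene` (matched
#'   gene name or `NA`).
#' @export
classify_lnc <- function(lnc, genes, bidir_window = 1000) {
  if (length(lnc) != 1L)
    stop("validation error: classify_lnc expects a single locus", call. = FALSE)
  lnc_chr <- as.character(GenomicRanges::seqnames(lnc))
  genes <- genes[as.character(GenomicRanges::seqnames(genes)) == lnc_chr]
  if (!length(genes)) return(list(class = "intergenic", gene = NA_character_))

  lnc_strand <- as.character(GenomicRanges::strand(lnc))
  g_strand <- as.character(GenomicRanges::strand(genes))
  same <- g_strand == lnc_strand
  ls <- GenomicRanges::start(lnc); le <- GenomicRanges::end(lnc)
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  span_ovl <- gs <= le & ge >= ls
  lnc_blocks <- S4Vectors::mcols(lnc)$blocks[[1L]]
  gene_blocks <- S4Vectors::mcols(genes)$blocks

  exon_ovl <- vapply(seq_along(genes), function(i) {
    if (!span_ovl[i]) return(FALSE)
    length(IRanges::findOverlaps(lnc_blocks, gene_blocks[[i]])) > 0L
  }, logical(1))
  in_intron <- vapply(seq_along(genes), function(i) {
    if (!span_ovl[i]) return(FALSE)
    introns <- IRanges::setdiff(IRanges::IRanges(gs[i], ge[i]),
                                gene_blocks[[i]])
    any(IRanges::start(introns) <= ls & IRanges::end(introns) >= le)
  }, logical(1))

  cls <- rep(NA_character_, length(genes))
  cls[same & exon_ovl] <- "exon_sense_overlapping"
  cls[same & span_ovl & !exon_ovl] <- "intron_sense_overlapping"
  cls[!same & span_ovl & in_intron] <- "intronic_antisense"
  cls[!same & span_ovl & !in_intron] <- "natural_antisense"

  lnc_tss <- tss(lnc)
  g_tss <- tss(genes)
  divergent <- if (lnc_strand == "+") lnc_tss >= g_tss else lnc_tss <= g_tss
  bidir <- !span_ovl & !same & abs(g_tss - lnc_tss) <= bidir_window & divergent
  cls[is.na(cls) & bidir] <- "bidirectional"

  order_cls <- c("exon_sense_overlapping", "intron_sense_overlapping",
                 "intronic_antisense", "natural_antisense", "bidirectional")
  rank <- match(cls, order_cls)
  if (all(is.na(rank))) return(list(class = "intergenic", gene = NA_character_))
  best <- which(rank == min(rank, na.rm = TRUE))
  if (length(best) > 1L)
    best <- best[which.min(abs(g_tss[best] - lnc_tss))]
  list(class = cls[best], gene = S4Vectors::mcols(genes)$name[best])
}

#' Classify every lncRNA locus and tally categories
#'
#' @param lncs lncRNA loci `GRanges`.
#' @param genes coding loci `GRanges`.
#' @inheritParams classify_lnc
#' @return list with `table` (data.frame lnc, class, matched_gene) and
#'   `counts` (named integer over the six classes, summing to
#'   `length(lncs)`).
#' @export
classify_all <- function(lncs, genes, bidir_window = 1000) {
  labels <- c("intergenic", "natural_antisense", "intronic_antisense",
              "exon_sense_overlapping", "bidirectional",
              "intron_sense_overlapping")
  res <- lapply(seq_along(lncs), function(i)
    classify_lnc(lncs[i], genes, bidir_window))
  tab <- data.frame(
    lnc = if (length(lncs)) S4Vectors::mcols(lncs)$name else character(0),
    class = vapply(res, `[[`, "", "class"),
    matched_gene = vapply(res, `[[`, "", "gene"),
    stringsAsFactors = FALSE)
  counts <- table(factor(tab$class, levels = labels))
  list(table = tab, counts = stats::setNames(as.integer(counts), labels))
}
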