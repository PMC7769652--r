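#' Stranded loci with exon blocks
#'
#' Loci (lncRNA or coding-gene models) are held as a
#' [GenomicRanges::GRanges] with metadata columns `name` and `blocks`
#' (an [IRanges::IRangesList] of exon ranges in absolute chromosome
#' coordinates). GRanges is 1-based closed, the Bioconductor convention;
#' the BED12 reader/writer perform the explicit conversion from/to BED's
#' 0-based half-open coordinates at the file boundary.
#'
#' @param name locus identifiers (unique).
#' @param chrom,start,end,strand locus spans, 0-based half-open `start`/`end`
#'   as in BED; strand `+` or `-`.
#' @param block_starts,block_sizes lists (or comma strings) of exon block
#'   offsets relative to `start` and block sizes, BED12-style. Defaults to a
#'   single block covering the span.
#' @return a `GRanges` with `name` and `blocks` metadata columns.
#' @export
loci <- function(name, chrom, start, end, strand,
                 block_starts = NULL, block_sizes = NULL) {
  n <- length(name)
  if (anyDuplicated(name))
    stop("validation error: duplicate locus name", call. = FALSE)
  if (any(end <= start))
    stop("validation error: end <= start for ",
         paste(name[end <= start], collapse = ", "), call. = FALSE)
  if (is.null(block_starts)) {
    block_starts <- as.list(rep(0L, n))
    block_sizes <- as.list(end - start)
  }
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    bs <- as.integer(block_starts[[i]])
    bl <- as.integer(block_sizes[[i]])
    o <- order(bs)
    bs <- bs[o]; bl <- bl[o]
    if (any(bl <= 0))
      stop("validation error: nonpositive block size in ", name[i], call. = FALSE)
    abs_start <- start[i] + bs          # 0-based
    abs_end <- abs_start + bl           # half-open
    if (abs_start[1L] < start[i] || abs_end[length(abs_end)] > end[i])
      stop("validation error: blocks outside span in ", name[i], call. = FALSE)
    if (length(bs) > 1L && any(abs_start[-1L] < abs_end[-length(abs_end)]))
      stop("validation error: overlapping blocks in ", name[i], call. = FALSE)
    blocks[[i]] <- IRanges::IRanges(start = abs_start + 1L, end = abs_end)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$blocks <- methods::as(blocks, "IRangesList")
  names(gr) <- name
  gr
}

#' Transcription start sites of loci
#'
#' Strand-aware: the leftmost base on `+`, the rightmost base on `-`
#' (1-based coordinates).
#'
#' @param gr loci as returned by [loci()] or [read_loci()].
#' @return integer vector of TSS positions.
#' @export
tss <- function(gr) {
  ifelse(as.character(GenomicRanges::strand(gr)) == "+",
         GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Read / write loci in BED12 format
#'
#' BED12 dialect: chrom, chromStart, chromEnd, name, score, strand,
#' thickStart, thickEnd, itemRgb, blockCount, blockSizes, blockStarts,
#' 0-based half-open. Blocks must lie within the span, sorted and
#' non-overlapping, or a validation error is raised.
#'
#' @param path BED file path.
#' @return [read_loci()]: loci `GRanges`; [write_loci()]: `path`, invisibly.
#' @export
read_loci <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L)
    stop("parse error: expected >= 6 BED columns", call. = FALSE)
  if (ncol(df) >= 12L) {
    bsz <- strsplit(sub(",$", "", df[[11L]]), ",", fixed = TRUE)
    bst <- strsplit(sub(",$", "", df[[12L]]), ",", fixed = TRUE)
    if (any(lengths(bsz) != df[[10L]]))
      stop("validation error: blockCount mismatch", call. = FALSE)
  } else {
    bst <- as.list(rep("0", nrow(df)))
    bsz <- as.list(as.character(df[[3L]] - df[[2L]]))
  }
  loci(name = df[[4L]], chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
       strand = df[[6L]], block_starts = lapply(bst, as.integer),
       block_sizes = lapply(bsz, as.integer))
}

#' @rdname read_loci
#' @param gr loci `GRanges`.
#' @export
write_loci <- function(gr, path) {
  start0 <- GenomicRanges::start(gr) - 1L        # back to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  blocks <- S4Vectors::mcols(gr)$blocks
  lines <- vapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    paste(as.character(GenomicRanges::seqnames(gr)[i]), start0[i], end0[i],
          S4Vectors::mcols(gr)$name[i], 0L,
          as.character(GenomicRanges::strand(gr)[i]),
          start0[i], end0[i], "0", length(b),
          paste0(paste(IRanges::width(b), collapse = ","), ","),
          paste0(paste(IRanges::start(b) - 1L - start0[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
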