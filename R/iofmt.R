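#' Gene set collections and GMT files
#'
#' A `GeneSetCollection` holds named gene sets with a category used for
#' over-representation analysis: GO categories `BP`, `CC`, `MF`, or
#' `pathway` for KEGG-style sets. GMT lines are
#' `set_id TAB description TAB member...`; the category is encoded as a
#' `"<category>|"` prefix on the description (written by [write_gmt()]) and
#' falls back to `default_category` when the prefix is absent.
#'
#' @param set_id,category,description,members parallel set definitions;
#'   `members` is a list of nonempty character vectors.
#' @return A `GeneSetCollection`: list with `info` (data.frame of set_id,
#'   category, description) and `sets` (named list of member vectors).
#' @export
gene_set_collection <- function(set_id, category, description, members) {
  if (anyDuplicated(set_id))
    stop("schema error: duplicate set_id", call. = FALSE)
  if (!all(category %in% c("BP", "CC", "MF", "pathway")))
    stop("schema error: category must be BP, CC, MF or pathway", call. = FALSE)
  if (any(!lengths(members)))
    stop("schema error: empty member list", call. = FALSE)
  names(members) <- set_id
  structure(list(
    info = data.frame(set_id = set_id, category = category,
                      description = description, stringsAsFactors = FALSE),
    sets = members), class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) nrow(x$info)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets (",
      paste(names(table(x$info$category)), table(x$info$category),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @param default_category category assigned to sets whose description lacks
#'   a `"<category>|"` prefix.
#' @export
read_gmt <- function(path, default_category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("parse error: GMT line ", short[1L], " has fewer than 3 fields",
         call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  cat_rx <- "^(BP|CC|MF|pathway)\\|"
  has_cat <- grepl(cat_rx, desc)
  category <- ifelse(has_cat, sub("\\|.*$", "", desc), default_category)
  desc <- ifelse(has_cat, sub(cat_rx, "", desc), desc)
  gene_set_collection(ids, category, desc, members)
}

#' @rdname gene_set_collection
#' @param x a `GeneSetCollection`.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_len(length(x)), function(i) {
    paste(c(x$info$set_id[i],
            paste0(x$info$category[i], "|", x$info$description[i]),
            x$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Probe annotation table
#'
#' Validates the per-probe annotation used to decorate differential
#' expression records: transcript `seqname`, array `probe_name`, chromosome,
#' strand (`+` sense / `-` antisense), `biotype` (`lncRNA` or `mRNA`) and an
#' optional `gene_symbol`.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame.
#' @export
probe_annotation <- function(df) {
  need <- c("seqname", "probe_name", "chrom", "strand", "biotype")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: annotation missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("schema error: strand must be '+' or '-'", call. = FALSE)
  if (!all(df$biotype %in% c("lncRNA", "mRNA")))
    stop("schema error: biotype must be 'lncRNA' or 'mRNA'", call. = FALSE)
  if (anyDuplicated(df[c("seqname", "probe_name")]))
    stop("schema error: duplicate (seqname, probe_name)", call. = FALSE)
  if (is.null(df$gene_symbol)) df$gene_symbol <- NA_character_
  df
}

#' miRNA target table
#'
#' Pairs of (miRNA, target gene) with the number of miRNA response elements
#' (MREs) supporting the interaction. Consumed by the ceRNA module; target
#' prediction itself is out of scope (tables come from e.g. TargetScan or
#' miRanda runs).
#'
#' @param df data.frame with columns `mirna_id`, `target_id`, `mre_count`.
#' @return the validated data.frame.
#' @export
mirna_target_table <- function(df) {
  need <- c("mirna_id", "target_id", "mre_count")
  if (!all(need %in% names(df)))
    stop("schema error: target table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("mirna_id", "target_id")]))
    stop("schema error: duplicate (mirna_id, target_id)", call. = FALSE)
  if (any(df$mre_count < 1 | df$mre_count != round(df$mre_count)))
    stop("value error: mre_count must be a positive integer", call. = FALSE)
  df
}

#' @rdname mirna_target_table
#' @param path TSV path with a header row.
#' @export
read_mirna_targets <- function(path) {
  mirna_target_table(utils::read.table(path, header = TRUE, sep = "\t",
                                       quote = "", stringsAsFactors = FALSE))
}

#' @rdname mirna_target_table
#' @param x a validated target table.
#' @export
write_mirna_targets <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cytoscape-compatible network export
#'
#' Writes a node attribute table (`<prefix>_nodes.tsv`), an edge attribute
#' table (`<prefix>_edges.tsv`) and a SIF file (`<prefix>.sif`). SIF
#' interaction types: `pp` for positive-sign edges, `nn` for negative-sign
#' edges, or the `type` column verbatim when `edges` carries one (ceRNA
#' tripartite export).
#'
#' @param nodes data.frame with columns `id` and `biotype` (plus any extra
#'   attribute columns, written verbatim).
#' @param edges data.frame with columns `source`, `target` and either `sign`
#'   (`"positive"`/`"negative"`) or `type`; extra columns (e.g. `weight`)
#'   are written to the edge table.
#' @param path_prefix output path prefix.
#' @return character vector of the three file paths, invisibly.
#' @export
write_network_tables <- function(nodes, edges, path_prefix) {
  if (!all(c("id", "biotype") %in% names(nodes)))
    stop("schema error: nodes need columns id, biotype", call. = FALSE)
  if (nrow(edges)) {
    dangling <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(dangling))
      stop("referential error: edge endpoint(s) absent from nodes: ",
           paste(dangling, collapse = ", "), call. = FALSE)
  }
  paths <- paste0(path_prefix, c("_nodes.tsv", "_edges.tsv", ".sif"))
  utils::write.table(nodes, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(edges)) {
    itype <- if ("type" %in% names(edges)) edges$type
             else ifelse(edges$sign == "negative", "nn", "pp")
    writeLines(paste(edges$source, itype, edges$target), paths[3L])
  } else writeLines(character(0), paths[3L])
  invisible(paths)
}
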