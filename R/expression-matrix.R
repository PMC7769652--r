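#' Expression matrix for a two-group microarray design
#'
#' Container for normalized, linear-scale probe intensities of a case-control
#' experiment. Intensities are always stored on the linear scale; taking log2
#' is an explicit operation ([log2_values()]), never implicit, because the
#' fold change used downstream is the absolute ratio of group mean
#' intensities (a linear-scale quantity) while t-tests run on log2 values.
#'
#' @param values numeric matrix, probes in rows (unique rownames), samples in
#'   columns (unique colnames); all entries finite and strictly positive.
#' @param groups character or factor of `"case"`/`"control"`, one per sample,
#'   named by sample id or in column order. Both groups must be nonempty;
#'   any variance-based statistic additionally requires >= 2 per group.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `groups` (factor named by sample id).
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c(s1 = "case", s2 = "case",
#'                              s3 = "control", s4 = "control"))
#' dim(em)
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames", call. = FALSE)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("mapping error: samples without a group label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("mapping error: `groups` length (", length(groups),
         ") != sample count (", ncol(values), ")", call. = FALSE)
  }
  groups <- factor(as.character(groups), levels = c("case", "control"))
  names(groups) <- colnames(values)
  x <- structure(list(values = values, groups = groups),
                 class = "ExpressionMatrix")
  validate_expression_matrix(x)
}

validate_expression_matrix <- function(x) {
  v <- x$values
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("schema error: duplicate probe id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(v)))
    stop("schema error: duplicate sample ids", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("value error: intensities must be finite and > 0 (linear scale)",
         call. = FALSE)
  if (any(is.na(x$groups)))
    stop("mapping error: group labels must be 'case' or 'control'",
         call. = FALSE)
  if (!all(c("case", "control") %in% x$groups))
    stop("design error: both groups must be nonempty", call. = FALSE)
  x
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples (", sum(x$groups == "case"), "case /",
      sum(x$groups == "control"), "control )\n")
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
group_labels <- function(x) x$groups

#' @rdname expression_matrix
#' @export
log2_values <- function(x) log2(x$values)

#' Read / write an expression matrix as TSV
#'
#' The file is a tab-separated table: header row of sample ids, first column
#' of probe ids, linear-scale intensities. Group labels are not stored in the
#' file; they come from `group_map`. Row and column order is preserved.
#'
#' @param path TSV file path.
#' @param group_map named character vector, sample id -> `"case"`/`"control"`.
#' @return [read_expression_matrix()]: a validated `ExpressionMatrix`;
#'   [write_expression_matrix()]: `path`, invisibly.
#' @export
read_expression_matrix <- function(path, group_map) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L)
    stop("schema error: expected probe id column plus >= 2 samples", call. = FALSE)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("schema error: duplicate probe id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df),
                                       dimnames = list(NULL, colnames(df)[-1L]))
  if (anyNA(vals))
    stop("value error: non-numeric intensity in ", basename(path), call. = FALSE)
  rownames(vals) <- ids
  expression_matrix(vals, group_map)
}

#' @rdname read_expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = probe_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
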