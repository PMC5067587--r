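#' Construct a grouped log2 expression matrix
#'
#' Container for microarray-style expression data: a complete genes x arrays
#' grid of log2 intensities plus a condition label per array. If the values
#' look unlogged (maximum above 30) they are log2-transformed with a warning,
#' mirroring the auto-detection of common GEO analysis front-ends.
#'
#' @param y numeric matrix, genes in rows, arrays in columns (dimnames
#'   required).
#' @param group_of named character vector mapping every array id to its
#'   condition label.
#' @return List of class `expr_matrix` with `y`, `genes`, `arrays`,
#'   `group_of`.
#' @export
expression_matrix <- function(y, group_of) {
  stopifnot(is.matrix(y), !is.null(rownames(y)), !is.null(colnames(y)))
  if (anyNA(y)) stop("expression matrix contains missing values")
  miss <- setdiff(colnames(y), names(group_of))
  if (length(miss)) {
    stop("group_of does not cover array(s): ", paste(miss, collapse = ", "))
  }
  if (max(y) > 30) {
    if (any(y <= 0)) {
      stop("values look unlogged (max > 30) but are not all positive; ",
           "cannot auto-transform")
    }
    warning("values look unlogged (max > 30); applying log2")
    y <- log2(y)
  }
  structure(list(y = y, genes = rownames(y), arrays = colnames(y),
                 group_of = group_of[colnames(y)]),
            class = "expr_matrix")
}

#' Read an expression matrix TSV plus design CSV
#'
#' The matrix TSV has a first column `ID` (probe or gene identifiers) and
#' one column per array; the design CSV has columns `array_id,condition`.
#'
#' @param matrix_file path to the TSV.
#' @param design path to the design CSV, or a data frame with columns
#'   `array_id` and `condition`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_file, design) {
  raw <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "ID") stop("malformed header: first column must be 'ID'")
  y <- as.matrix(raw[, -1, drop = FALSE])
  rownames(y) <- as.character(raw$ID)
  expression_matrix(y, read_design(design))
}

read_design <- function(design) {
  if (is.character(design)) {
    design <- utils::read.csv(design, stringsAsFactors = FALSE)
  }
  need <- c("array_id", "condition")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("malformed design: missing column(s) ",
         paste(sQuote(miss), collapse = ", "))
  }
  stats::setNames(as.character(design$condition),
                  as.character(design$array_id))
}

#' Minimal reader for GEO series-matrix files
#'
#' Parses only the data block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` as a TSV; every other `!`-prefixed line is
#' ignored except `!Sample_geo_accession`, which (when present) supplies
#' the array identifiers. This is a deliberately small stand-in for full
#' SOFT parsing, sufficient for logFC-window mining.
#'
#' @param file path to an (uncompressed) series-matrix text file.
#' @param design design CSV path or data frame, see
#'   [read_expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(file, design) {
  lines <- readLines(file)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg) {
    stop("no series-matrix table block found in ", file)
  }
  block <- lines[(beg + 1):(end - 1)]
  tab <- utils::read.delim(text = block, check.names = FALSE,
                           stringsAsFactors = FALSE)
  y <- as.matrix(tab[, -1, drop = FALSE])
  rownames(y) <- as.character(tab[[1]])
  acc <- grep("^!Sample_geo_accession", lines, value = TRUE)
  if (length(acc)) {
    ids <- strsplit(acc[1], "\t")[[1]][-1]
    ids <- gsub('"', "", ids)
    if (length(ids) == ncol(y)) colnames(y) <- ids
  }
  expression_matrix(y, read_design(design))
}

#' Collapse probes to gene symbols
#'
#' Microarray platforms carry several probes per gene. Either the probe
#' with the highest mean log2 expression over all arrays is kept
#' (`"highest_mean"`, default) or probes are averaged (`"mean"`).
#'
#' @param matrix an [expression_matrix()] whose rows are probes.
#' @param symbols named character vector, probe id -> gene symbol; probes
#'   absent from `symbols` are dropped.
#' @param method `"highest_mean"` or `"mean"`.
#' @return An [expression_matrix()] with gene-symbol rows.
#' @export
collapse_probes <- function(matrix, symbols,
                            method = c("highest_mean", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expr_matrix"))
  keep <- intersect(matrix$genes, names(symbols))
  y <- matrix$y[keep, , drop = FALSE]
  sym <- normalize_gene(symbols[keep])
  if (method == "highest_mean") {
    a <- rowMeans(y)
    pick <- tapply(seq_along(sym), sym, function(i) i[which.max(a[i])])
    out <- y[unlist(pick), , drop = FALSE]
    rownames(out) <- names(pick)
  } else {
    out <- apply(y, 2, function(col) tapply(col, sym, mean))
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, matrix$group_of)
}

#' Per-gene log2 fold change between two conditions
#'
#' For every gene, logFC is the mean log2 expression over the arrays of
#' `condition_a` minus the mean over those of `condition_b` — identical to
#' the two-group linear-model coefficient reported by GEO2R-style analyses
#' (moderation alters p-values, not the coefficient). `A` is the mean log2
#' expression over both conditions' arrays (the MA-plot abscissa).
#'
#' @param matrix an [expression_matrix()].
#' @param condition_a,condition_b condition labels present in the matrix.
#' @return Data frame of class `comparison_result` with columns `gene`,
#'   `logFC`, `A`; attribute `comparison_name` is
#'   `"<condition_a>_vs_<condition_b>"`.
#' @export
log_fold_change <- function(matrix, condition_a, condition_b) {
  stopifnot(inherits(matrix, "expr_matrix"))
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% matrix$group_of) stop("unknown condition label: ", cond)
  }
  a_arr <- matrix$arrays[matrix$group_of == condition_a]
  b_arr <- matrix$arrays[matrix$group_of == condition_b]
  both <- c(a_arr, b_arr)
  res <- data.frame(
    gene  = matrix$genes,
    logFC = rowMeans(matrix$y[, a_arr, drop = FALSE]) -
            rowMeans(matrix$y[, b_arr, drop = FALSE]),
    A     = rowMeans(matrix$y[, both, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "comparison_name") <- paste0(condition_a, "_vs_", condition_b)
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Select stably expressed genes by a logFC window
#'
#' Keeps genes whose logFC lies strictly inside `(window[1], window[2])`.
#' The default window (-0.1, 0.1) captures genes with essentially no fold
#' change between the two conditions. Bounds are open: a gene at exactly
#' 0.1 is excluded.
#'
#' @param result a [log_fold_change()] result.
#' @param window numeric length-2, `low < high`.
#' @return List of class `stable_gene_set` with `comparison_name`, `window`
#'   and `genes` (character).
#' @export
stable_gene_filter <- function(result, window = c(-0.1, 0.1)) {
  stopifnot(inherits(result, "comparison_result"),
            length(window) == 2, window[1] < window[2])
  keep <- result$gene[result$logFC > window[1] & result$logFC < window[2]]
  if (!length(keep)) {
    warning("no gene falls inside the logFC window (",
            window[1], ", ", window[2], ")")
  }
  structure(list(comparison_name = attr(result, "comparison_name"),
                 window = window, genes = keep),
            class = "stable_gene_set")
}

#' Intersect stable-gene sets across comparisons
#'
#' Computes the core set of genes stable in every comparison, plus the size
#' of each exclusive Venn region over the input sets (a region is keyed by
#' the `&`-joined names of the sets containing its genes; regions with no
#' genes are reported as 0, and the counts sum to the size of the union).
#'
#' @param sets list of [stable_gene_filter()] results (at least two).
#' @param names optional set names; defaults to the comparison names.
#' @return List with `core` (character) and `venn_counts` (named integer).
#' @export
intersect_stable_sets <- function(sets, names = NULL) {
  stopifnot(length(sets) >= 2)
  gene_sets <- lapply(sets, function(s) {
    if (inherits(s, "stable_gene_set")) s$genes else as.character(s)
  })
  nm <- names %||% vapply(seq_along(sets), function(i) {
    if (inherits(sets[[i]], "stable_gene_set")) {
      sets[[i]]$comparison_name %||% paste0("set", i)
    } else paste0("set", i)
  }, character(1))
  names(gene_sets) <- nm
  core <- Reduce(intersect, gene_sets)
  universe <- unique(unlist(gene_sets))
  member <- vapply(gene_sets, function(g) universe %in% g,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  k <- length(gene_sets)
  regions <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(nm, sz, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(regions)), regions)
  key <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  list(core = core, venn_counts = counts)
}

#' Rank genes by average expression level
#'
#' Orders a gene set by its mean log2 expression over all arrays,
#' descending; ties are broken lexicographically. Used to check that a
#' candidate set spans low, medium and high expression levels.
#'
#' @param genes character vector, all present in `matrix`.
#' @param matrix an [expression_matrix()].
#' @return Data frame with columns `gene`, `mean_expr`, ordered.
#' @export
rank_by_expression <- function(genes, matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  miss <- setdiff(genes, matrix$genes)
  if (length(miss)) {
    stop("gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  }
  m <- rowMeans(matrix$y[genes, , drop = FALSE])
  ord <- order(-m, names(m), method = "radix")
  data.frame(gene = names(m)[ord], mean_expr = unname(m)[ord],
             stringsAsFactors = FALSE)
}

#' Top regulated genes of a comparison
#'
#' The `n` genes with the largest (`"up"`) or smallest (`"down"`) logFC,
#' ordered by absolute logFC descending (ties lexicographic).
#'
#' @param result a [log_fold_change()] result.
#' @param n number of genes, at least 1.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene names.
#' @export
top_regulated <- function(result, n, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(result, "comparison_result"), n >= 1)
  if (n > nrow(result)) {
    warning("n exceeds gene count; returning all ", nrow(result), " genes")
    n <- nrow(result)
  }
  sgn <- if (direction == "up") -1 else 1
  sel <- order(sgn * result$logFC, result$gene, method = "radix")[seq_len(n)]
  sel <- sel[order(-abs(result$logFC[sel]), result$gene[sel],
                   method = "radix")]
  result$gene[sel]
}
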