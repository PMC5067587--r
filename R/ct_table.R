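#' Construct a validated Ct table
#'
#' A `ct_table` holds raw technical-replicate cycle-threshold (Ct)
#' measurements in long form: one row per (sample, gene, replicate) reaction,
#' with the developmental stage (or other grouping) of each sample and a flag
#' for no-reverse-transcriptase control reactions. No-RT rows are carried
#' through parsing but are never mixed into analysis.
#'
#' @param sample_id character, biological sample identifiers.
#' @param group character, stage/condition label per row.
#' @param gene character, gene symbols (opaque; internal whitespace is
#'   stripped so that e.g. `"Phf 7"` and `"Phf7"` are the same gene).
#' @param replicate positive integer technical-replicate index.
#' @param ct numeric Ct values in PCR cycles, `NA` for failed reactions.
#'   Non-missing values must lie in `(0, ct_max]`.
#' @param is_noRT logical, `TRUE` for no-RT control reactions.
#' @param ct_max upper bound of the Ct validity window in cycles. The default
#'   45 covers a 40-45-cycle run with headroom.
#' @return A data frame of class `ct_table` with the six columns above.
#' @seealso [read_ct_table()], [collapse_replicates()]
#' @export
ct_table <- function(sample_id, group, gene, replicate, ct,
                     is_noRT = FALSE, ct_max = 45) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    group     = as.character(group),
    gene      = normalize_gene(as.character(gene)),
    replicate = as.integer(replicate),
    ct        = as.numeric(ct),
    is_noRT   = rep_len(as.logical(is_noRT), length(sample_id)),
    stringsAsFactors = FALSE
  )
  validate_ct_table(df, ct_max = ct_max)
  class(df) <- c("ct_table", "data.frame")
  df
}

validate_ct_table <- function(df, ct_max = 45) {
  if (any(df$replicate < 1L, na.rm = TRUE)) {
    stop("replicate indices must be positive integers")
  }
  bad <- which(!is.na(df$ct) & (df$ct <= 0 | df$ct > ct_max))
  if (length(bad)) {
    stop(sprintf("ct outside (0, %g] at row(s) %s (first offending value %g)",
                 ct_max, paste(utils::head(bad, 5), collapse = ", "),
                 df$ct[bad[1]]))
  }
  key <- paste(df$sample_id, df$gene, df$replicate, df$is_noRT, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sample_id, gene, replicate, is_noRT) tuple: ",
         gsub("\r", " / ", dup))
  }
  grp <- tapply(df$group, df$sample_id, function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop("sample(s) mapped to more than one group: ",
         paste(names(grp)[grp > 1], collapse = ", "))
  }
  invisible(df)
}

#' Read a Ct table from CSV
#'
#' Two dialects are supported. The canonical long dialect has the header
#' `sample_id,group,gene,replicate,ct,is_noRT` (the `is_noRT` column is
#' optional and defaults to 0); an empty `ct` field denotes a missing
#' measurement. The wide dialect has columns
#' `sample_id,group,replicate,<gene1>,<gene2>,...` with one row per
#' (sample, replicate) and is converted to the equivalent long form.
#'
#' @param source a file path or connection readable by [utils::read.csv()].
#' @param dialect `"long"` (default) or `"wide"`.
#' @param ct_max Ct validity bound, see [ct_table()].
#' @return A [ct_table()].
#' @export
read_ct_table <- function(source, dialect = c("long", "wide"), ct_max = 45) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(source, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("sample_id", "group", "gene", "replicate", "ct")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("malformed header: missing column(s) ",
           paste(sQuote(miss), collapse = ", "))
    }
    noRT <- if ("is_noRT" %in% names(raw)) as.integer(raw$is_noRT) else 0L
    ct_table(raw$sample_id, raw$group, raw$gene, raw$replicate,
             as.numeric(raw$ct), is_noRT = noRT == 1L, ct_max = ct_max)
  } else {
    need <- c("sample_id", "group", "replicate")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("malformed header: missing column(s) ",
           paste(sQuote(miss), collapse = ", "))
    }
    genes <- setdiff(names(raw), need)
    if (!length(genes)) stop("wide dialect has no gene columns")
    long <- do.call(rbind, lapply(genes, function(g) {
      data.frame(sample_id = raw$sample_id, group = raw$group,
                 gene = g, replicate = raw$replicate,
                 ct = as.numeric(raw[[g]]), stringsAsFactors = FALSE)
    }))
    ct_table(long$sample_id, long$group, long$gene, long$replicate,
             long$ct, ct_max = ct_max)
  }
}

#' Collapse technical replicates to one Ct per gene and sample
#'
#' Collapses the technical replicates of each (gene, sample) cell with the
#' median (default, robust to a single aberrant replicate) or the mean.
#' No-RT control rows are excluded. A cell whose replicates are all missing
#' becomes `NA` with a warning; a gene missing in more than half of the
#' samples triggers a warning, since it cannot enter stability analysis.
#'
#' @param table a [ct_table()].
#' @param method `"median"` (default) or `"mean"`.
#' @return A `ct_matrix`: list with `ct` (genes x samples numeric matrix),
#'   `genes`, `samples` (orders follow first appearance in `table`) and
#'   `group_of` (named character, sample -> group).
#' @export
collapse_replicates <- function(table, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "ct_table"))
  tab <- table[!table$is_noRT, , drop = FALSE]
  if (!nrow(tab)) stop("no analysis rows (all rows are no-RT controls)")
  genes <- unique(tab$gene)
  samples <- unique(tab$sample_id)
  fun <- if (method == "median") stats::median else mean
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  cell <- split(tab$ct, list(factor(tab$gene, genes),
                             factor(tab$sample_id, samples)), sep = "\r")
  for (nm in names(cell)) {
    v <- cell[[nm]]
    if (!length(v)) next
    gs <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    v <- v[!is.na(v)]
    m[gs[1], gs[2]] <- if (length(v)) fun(v) else NA_real_
  }
  empty <- which(is.na(m), arr.ind = TRUE)
  if (nrow(empty)) {
    warning(sprintf("%d cell(s) have no non-missing replicate, e.g. (%s, %s)",
                    nrow(empty), genes[empty[1, 1]], samples[empty[1, 2]]))
  }
  frac_missing <- rowMeans(is.na(m))
  if (any(frac_missing > 0.5)) {
    warning("gene(s) missing in >50% of samples: ",
            paste(genes[frac_missing > 0.5], collapse = ", "))
  }
  group_of <- stats::setNames(tab$group[match(samples, tab$sample_id)], samples)
  structure(list(ct = m, genes = genes, samples = samples,
                 group_of = group_of),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Collapsed Ct matrix: %d genes x %d samples, %d group(s)\n",
              length(x$genes), length(x$samples),
              length(unique(x$group_of))))
  invisible(x)
}

#' Restrict a collapsed Ct matrix to a gene subset
#'
#' Used to separate the reference-candidate panel from target genes
#' before stability scoring.
#'
#' @param matrix a `ct_matrix`.
#' @param genes genes to keep, in the order given.
#' @return A `ct_matrix` over `genes`.
#' @export
subset_genes <- function(matrix, genes) {
  stopifnot(inherits(matrix, "ct_matrix"))
  miss <- setdiff(genes, matrix$genes)
  if (length(miss)) stop("gene(s) not present: ", paste(miss, collapse = ", "))
  structure(list(ct = matrix$ct[genes, , drop = FALSE], genes = genes,
                 samples = matrix$samples, group_of = matrix$group_of),
            class = "ct_matrix")
}

#' Total Ct spread of one gene across all samples
#'
#' The spread is max minus min of the collapsed Ct over every sample,
#' all groups pooled — the per-gene "total spread in cycles" used to
#' eyeball reference-gene stability before formal scoring.
#'
#' @param matrix a `ct_matrix` from [collapse_replicates()].
#' @param gene gene name.
#' @return Spread in cycles (numeric scalar).
#' @export
ct_spread <- function(matrix, gene) {
  stopifnot(inherits(matrix, "ct_matrix"))
  if (!gene %in% matrix$genes) stop("gene not present: ", gene)
  v <- matrix$ct[gene, ]
  v <- v[!is.na(v)]
  if (length(v) < 2) {
    stop("spread undefined for ", gene, ": fewer than 2 non-missing samples")
  }
  max(v) - min(v)
}

#' Write / read a collapsed Ct matrix as TSV
#'
#' Long TSV with columns `gene, sample, group, ct`; row order is
#' gene-major in the matrix's own gene and sample order, so a write/read
#' round trip reproduces the object.
#'
#' @param matrix a `ct_matrix`.
#' @param path file path.
#' @return `write_ct_matrix` returns `path` invisibly; `read_ct_matrix`
#'   returns a `ct_matrix`.
#' @export
write_ct_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "ct_matrix"))
  df <- data.frame(
    gene   = rep(matrix$genes, times = length(matrix$samples)),
    sample = rep(matrix$samples, each = length(matrix$genes)),
    group  = rep(unname(matrix$group_of[matrix$samples]),
                 each = length(matrix$genes)),
    ct     = as.vector(matrix$ct)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_matrix
#' @export
read_ct_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "group", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed header: missing column(s) ",
         paste(sQuote(miss), collapse = ", "))
  }
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$gene, genes), match(df$sample, samples))] <- df$ct
  group_of <- stats::setNames(df$group[match(samples, df$sample)], samples)
  structure(list(ct = m, genes = genes, samples = samples,
                 group_of = group_of),
            class = "ct_matrix")
}
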