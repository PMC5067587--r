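#' Primer metadata and amplification efficiencies
#'
#' A `primer_info` table carries, per gene, the per-cycle amplification
#' factor E of its primer pair (E = 2 is perfect doubling), and optionally
#' the amplicon length and primer sequences. Efficiencies must lie in
#' (1, 2.2]; an unspecified efficiency defaults to 2.
#'
#' @param gene character gene symbols.
#' @param efficiency numeric amplification factors, `NA` for unknown
#'   (replaced by 2).
#' @param amplicon_length optional integer base-pair lengths.
#' @param fwd,rev optional primer sequences.
#' @return A data frame of class `primer_info`.
#' @export
primer_info <- function(gene, efficiency = NA_real_,
                        amplicon_length = NA_integer_,
                        fwd = NA_character_, rev = NA_character_) {
  gene <- normalize_gene(as.character(gene))
  efficiency <- rep_len(as.numeric(efficiency), length(gene))
  efficiency[is.na(efficiency)] <- 2
  bad <- efficiency <= 1 | efficiency > 2.2
  if (any(bad)) {
    stop("amplification efficiency outside (1, 2.2] for gene(s): ",
         paste(gene[bad], collapse = ", "))
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene in primer table: ", gene[duplicated(gene)][1])
  }
  df <- data.frame(gene = gene, efficiency = efficiency,
                   amplicon_length = rep_len(as.integer(amplicon_length),
                                             length(gene)),
                   fwd = rep_len(as.character(fwd), length(gene)),
                   rev = rep_len(as.character(rev), length(gene)),
                   stringsAsFactors = FALSE)
  class(df) <- c("primer_info", "data.frame")
  df
}

#' Read a primer table CSV
#'
#' Expected columns: `gene,efficiency,amplicon_length,fwd,rev`; the last
#' three are optional. An empty efficiency field defaults to 2.
#'
#' @param source file path or connection.
#' @return A [primer_info()].
#' @export
read_primer_table <- function(source) {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  if (!"gene" %in% names(raw)) {
    stop("malformed header: missing column 'gene'")
  }
  primer_info(raw$gene,
              efficiency      = raw$efficiency %||% NA_real_,
              amplicon_length = raw$amplicon_length %||% NA_integer_,
              fwd = raw$fwd %||% NA_character_,
              rev = raw$rev %||% NA_character_)
}

# Efficiency lookup for a gene vector: primer table where available,
# `default` elsewhere.
efficiencies_for <- function(genes, primers = NULL, default = 2) {
  e <- stats::setNames(rep(default, length(genes)), genes)
  if (!is.null(primers)) {
    stopifnot(inherits(primers, "primer_info") || is.data.frame(primers))
    hit <- intersect(genes, primers$gene)
    e[hit] <- primers$efficiency[match(hit, primers$gene)]
  }
  if (any(e <= 1)) {
    stop("amplification efficiency must exceed 1; offending gene(s): ",
         paste(genes[e <= 1], collapse = ", "))
  }
  e
}

#' Convert collapsed Ct values to relative quantities
#'
#' Applies the exponential PCR model per gene: the sample with the lowest
#' Ct (most template) is set to quantity 1 and every other sample is scaled
#' down by the gene's amplification factor per extra cycle,
#' \eqn{q_{gs} = E_g^{\,Ct^{min}_g - Ct_{gs}}}. These efficiency-corrected
#' quantities are the input scale for GeNorm and for normalization factors.
#'
#' @param matrix a `ct_matrix` from [collapse_replicates()].
#' @param primers optional [primer_info()] supplying per-gene efficiencies.
#' @param efficiency_default efficiency for genes absent from `primers`.
#' @return An `rq_matrix`: list with `q` (genes x samples, strictly positive,
#'   per-gene maximum exactly 1), `genes`, `samples`, `group_of`.
#' @export
to_relative_quantities <- function(matrix, primers = NULL,
                                   efficiency_default = 2) {
  stopifnot(inherits(matrix, "ct_matrix"))
  ct <- matrix$ct
  if (anyNA(ct)) {
    bad <- which(is.na(ct), arr.ind = TRUE)
    pairs <- apply(utils::head(bad, 5), 1, function(ij) {
      paste0("(", rownames(ct)[ij[1]], ", ", colnames(ct)[ij[2]], ")")
    })
    stop("missing Ct cell(s): ", paste(pairs, collapse = ", "))
  }
  e <- efficiencies_for(rownames(ct), primers, efficiency_default)
  q <- e ^ (apply(ct, 1, min) - ct)   # rows recycle: e and minCt are per gene
  dimnames(q) <- dimnames(ct)
  structure(list(q = q, genes = matrix$genes, samples = matrix$samples,
                 group_of = matrix$group_of, efficiency = e),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("Relative-quantity matrix: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  invisible(x)
}
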