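# GeNorm: gene-stability measure M and stepwise exclusion.
#
# The stability of gene j is the average, over every other candidate k, of
# the sample standard deviation of the pairwise log2 expression ratio
# log2(q_j / q_k). A gene that covaries with the pool (i.e. tracks the true
# per-sample loading) has small M; a gene with idiosyncratic variation has
# large M. Ranking proceeds by repeatedly excluding the worst (highest-M)
# gene and recomputing M on the remainder.

as_quantity_matrix <- function(q) {
  if (inherits(q, "rq_matrix")) q <- q$q
  stopifnot(is.matrix(q))
  if (any(q <= 0)) stop("relative quantities must be strictly positive")
  if (is.null(rownames(q))) stop("quantity matrix needs gene rownames")
  q
}

#' GeNorm M-values
#'
#' Computes the GeNorm stability measure for every gene in a relative
#' quantity matrix: \eqn{M_j = \mathrm{mean}_{k \ne j}\,
#' \mathrm{sd}_s(\log_2 q_{js}/q_{ks})} with the n-1 standard deviation
#' over samples.
#'
#' @param q an `rq_matrix` from [to_relative_quantities()], or a bare
#'   strictly positive genes x samples matrix.
#' @return Named numeric vector of M-values (cycles-equivalent log2 units).
#' @export
genorm_m_values <- function(q) {
  q <- as_quantity_matrix(q)
  g <- nrow(q)
  if (g < 2) stop("pairwise measure undefined for a single gene")
  if (ncol(q) < 2) stop("at least 2 samples required")
  z <- log2(q)
  v <- matrix(0, g, g, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      v[j, k] <- v[k, j] <- stats::sd(z[j, ] - z[k, ])
    }
  }
  stats::setNames(rowSums(v) / (g - 1), rownames(q))
}

#' GeNorm ranking by stepwise exclusion
#'
#' Iteratively removes the gene with the highest M-value and recomputes M
#' on the remaining candidates until two genes are left. Within the final
#' pair both M-values are equal by construction, so the pair is ordered by
#' each gene's mean M across all rounds in which both survived (ties
#' lexicographic). When genes tie for worst in a round, the
#' lexicographically greatest is removed, so a fully degenerate (constant)
#' matrix yields a lexicographically ascending ranking.
#'
#' @param q as in [genorm_m_values()].
#' @return List of class `genorm_result`:
#'   \describe{
#'     \item{m_values}{per-gene M at the round of its exclusion (final two:
#'       last-round M).}
#'     \item{rounds}{list of named per-round M vectors.}
#'     \item{exclusion_order}{genes removed, worst first.}
#'     \item{ranking}{all genes, best to worst.}
#'     \item{pairwise_v}{V(n,n+1) series, see
#'       [genorm_pairwise_variation()].}
#'   }
#' @export
genorm_ranking <- function(q) {
  q <- as_quantity_matrix(q)
  genes <- rownames(q)
  if (nrow(q) == 2) {
    m <- genorm_m_values(q)
    ranking <- rank_genes(m)
    return(structure(list(m_values = m, rounds = list(m),
                          exclusion_order = character(0),
                          ranking = ranking,
                          pairwise_v = numeric(0)),
                     class = "genorm_result"))
  }
  rounds <- list()
  removed <- character(0)
  final_m <- stats::setNames(numeric(length(genes)), genes)
  cur <- q
  while (nrow(cur) > 2) {
    m <- genorm_m_values(cur)
    rounds[[length(rounds) + 1]] <- m
    worst_m <- max(m)
    cand <- names(m)[m == worst_m]
    worst <- cand[order(cand, method = "radix")][length(cand)]
    final_m[worst] <- m[worst]
    removed <- c(removed, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  m_last <- genorm_m_values(cur)
  rounds[[length(rounds) + 1]] <- m_last
  final_m[names(m_last)] <- m_last
  pair <- rownames(cur)
  mean_m <- vapply(pair, function(g) {
    mean(vapply(rounds, function(r) r[[g]], numeric(1)))
  }, numeric(1))
  pair <- pair[order(mean_m, pair, method = "radix")]
  ranking <- c(pair, rev(removed))
  res <- structure(list(m_values = final_m[genes], rounds = rounds,
                        exclusion_order = removed, ranking = ranking,
                        pairwise_v = numeric(0)),
                   class = "genorm_result")
  res$pairwise_v <- genorm_pairwise_variation(q, ranking)
  res
}

#' Pairwise variation V(n, n+1) of normalization factors
#'
#' For n = 2 .. G-1, builds the normalization factor NF_n (per-sample
#' geometric mean of the n best-ranked genes' quantities) and reports the
#' sample standard deviation of log2(NF_n / NF_{n+1}). A small V(n,n+1)
#' means adding the (n+1)-th gene barely changes normalization, so n
#' references suffice.
#'
#' @param q as in [genorm_m_values()].
#' @param ranking ordered gene list, best first (e.g. from
#'   [genorm_ranking()]).
#' @return Named numeric vector (`"V2_3"`, `"V3_4"`, ...); empty for fewer
#'   than 3 genes.
#' @export
genorm_pairwise_variation <- function(q, ranking) {
  q <- as_quantity_matrix(q)
  ranking <- intersect(ranking, rownames(q))
  g <- length(ranking)
  if (g < 3) return(numeric(0))
  nf <- function(n) apply(q[ranking[seq_len(n)], , drop = FALSE], 2, geo_mean)
  v <- vapply(2:(g - 1), function(n) {
    stats::sd(log2(nf(n) / nf(n + 1)))
  }, numeric(1))
  stats::setNames(v, paste0("V", 2:(g - 1), "_", 3:g))
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("GeNorm stability ranking (best first):\n ",
      paste(x$ranking, collapse = ", "), "\n")
  cat("M-values at exclusion:\n")
  print(round(x$m_values[x$ranking], 4))
  if (length(x$pairwise_v)) {
    cat("Pairwise variation:\n")
    print(round(x$pairwise_v, 4))
  }
  invisible(x)
}
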