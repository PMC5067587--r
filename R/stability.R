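# DeltaCt, BestKeeper and NormFinder stability scores, plus the
# geometric-mean rank aggregation that produces the overall ordering.

as_ct_grid <- function(m) {
  if (inherits(m, "ct_matrix")) {
    ct <- m$ct
  } else {
    stopifnot(is.matrix(m))
    ct <- m
  }
  if (anyNA(ct)) stop("complete gene x sample grid required (missing Ct)")
  if (is.null(rownames(ct))) stop("Ct matrix needs gene rownames")
  ct
}

new_stability_result <- function(algorithm, score, detail = list()) {
  structure(list(algorithm = algorithm, score = score,
                 ranking = rank_genes(score), detail = detail),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("%s stability (best first):\n", x$algorithm))
  print(round(x$score[x$ranking], 4))
  invisible(x)
}

#' Comparative DeltaCt stability
#'
#' The comparative-pair method: for each candidate, the score is the mean
#' over all other candidates of the sample standard deviation of the
#' pairwise Ct difference. A gene whose Ct differences with every partner
#' are constant across samples scores 0. With all amplification
#' efficiencies equal to 2 this is algebraically identical to the GeNorm
#' M-value on the corresponding relative quantities.
#'
#' @param m a `ct_matrix` (complete grid) or bare Ct matrix.
#' @return A `stability_result` (`detail$pair_sd` holds the pairwise SD
#'   matrix).
#' @export
deltact_stability <- function(m) {
  ct <- as_ct_grid(m)
  g <- nrow(ct)
  if (g < 2) stop("pairwise measure undefined for a single gene")
  v <- matrix(0, g, g, dimnames = list(rownames(ct), rownames(ct)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      v[j, k] <- v[k, j] <- stats::sd(ct[j, ] - ct[k, ])
    }
  }
  score <- stats::setNames(rowSums(v) / (g - 1), rownames(ct))
  new_stability_result("deltact", score, detail = list(pair_sd = v))
}

#' BestKeeper descriptive stability
#'
#' Per gene: sample standard deviation of Ct (the score; optionally the
#' mean absolute deviation from the mean, the original tool's variant),
#' coefficient of variation (percent of arithmetic mean Ct), geometric and
#' arithmetic mean Ct, and the Pearson correlation of the gene's Ct with
#' the BestKeeper index — the per-sample geometric mean of all candidates'
#' Ct values. A zero-variance gene has an undefined correlation (`NA`) but
#' is still ranked by its SD. Note that unlike the ratio-based scores,
#' raw-Ct SD is sensitive to sample-loading differences.
#'
#' @param m a `ct_matrix` (complete, strictly positive Ct) or bare matrix.
#' @param use_mad use mean absolute deviation instead of SD as the score.
#' @return A `stability_result`; `detail$summary` is a per-gene data frame
#'   (`sd_ct`, `mad_ct`, `cv_pct`, `mean_ct`, `geomean_ct`, `r`) and
#'   `detail$index` the per-sample index.
#' @export
bestkeeper <- function(m, use_mad = FALSE) {
  ct <- as_ct_grid(m)
  if (any(ct <= 0)) stop("BestKeeper requires strictly positive Ct values")
  if (nrow(ct) < 2) stop("at least 2 genes required")
  sd_ct  <- apply(ct, 1, stats::sd)
  mad_ct <- apply(ct, 1, function(x) mean(abs(x - mean(x))))
  mean_ct <- rowMeans(ct)
  geo_ct  <- apply(ct, 1, geo_mean)
  index <- apply(ct, 2, geo_mean)
  r <- apply(ct, 1, function(x) {
    if (stats::sd(x) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(x, index)
  })
  score <- if (use_mad) mad_ct else sd_ct
  summary <- data.frame(gene = rownames(ct), sd_ct = sd_ct, mad_ct = mad_ct,
                        cv_pct = 100 * sd_ct / mean_ct,
                        mean_ct = mean_ct, geomean_ct = geo_ct, r = r,
                        row.names = NULL, stringsAsFactors = FALSE)
  new_stability_result("bestkeeper", score,
                       detail = list(summary = summary, index = index,
                                     use_mad = use_mad))
}

#' NormFinder model-based stability
#'
#' Works on log2 relative quantities \eqn{z_{gs}}, sample-centered to
#' remove the common loading component:
#' \eqn{r_{gs} = z_{gs} - \bar z_{\cdot s}}. Without groups the score is
#' simply the sample SD of \eqn{r_{gs}}. With groups, the per-group
#' within-gene variance is bias-corrected by the gene-averaged variance of
#' its group (floored at zero) and combined with the absolute intergroup
#' deviation: \eqn{\mathrm{score}_g = \mathrm{mean}_k(|d_{gk}| +
#' \sqrt{\hat s^2_{gk}/n_k})}, where \eqn{d_{gk}} is the group mean of
#' \eqn{r_{gs}} centered across groups. This deterministic estimator keeps
#' the variance-decomposition structure of the original model without its
#' Bayesian shrinkage step.
#'
#' @param m a `ct_matrix` (complete grid).
#' @param primers optional [primer_info()] with per-gene efficiencies.
#' @param use_groups use the grouped (intergroup + intragroup) estimator;
#'   requires every group to have at least 2 samples.
#' @param efficiency_default efficiency for genes without a primer entry.
#' @return A `stability_result`; in grouped mode `detail$d` and `detail$s`
#'   hold the per-(gene, group) intergroup deviations and intragroup SDs.
#' @export
normfinder_stability <- function(m, primers = NULL, use_groups = FALSE,
                                 efficiency_default = 2) {
  stopifnot(inherits(m, "ct_matrix"))
  q <- to_relative_quantities(m, primers, efficiency_default)
  z <- log2(q$q)
  g <- nrow(z)
  if (g < 2) stop("at least 2 genes required")
  r <- sweep(z, 2, colMeans(z))
  if (!use_groups) {
    score <- apply(r, 1, stats::sd)
    return(new_stability_result("normfinder", score,
                                detail = list(grouped = FALSE)))
  }
  groups <- m$group_of[colnames(z)]
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  ks <- names(tab)
  mk <- sapply(ks, function(k) rowMeans(r[, groups == k, drop = FALSE]))
  vk <- sapply(ks, function(k) apply(r[, groups == k, drop = FALSE], 1,
                                     stats::var))
  d <- mk - rowMeans(mk)
  s2 <- sweep(vk, 2, colMeans(vk) / g)
  s2[s2 < 0] <- 0
  se <- sqrt(sweep(s2, 2, as.numeric(tab[ks]), "/"))
  score <- rowMeans(abs(d) + se)
  new_stability_result("normfinder", score,
                       detail = list(grouped = TRUE, d = d, s = sqrt(s2),
                                     n_per_group = as.integer(tab[ks])))
}

#' Aggregate per-algorithm rankings by geometric mean of positions
#'
#' Each input ranking assigns every gene an integer position (1 = most
#' stable). The consensus score of a gene is the geometric mean of its
#' positions; the overall order sorts this ascending, breaking ties by the
#' arithmetic mean position and then lexicographically.
#'
#' @param rankings list of ordered gene vectors (best first), all
#'   permutations of the same gene set; at least two.
#' @param labels optional algorithm names for the position table.
#' @return List of class `aggregated_ranking` with `positions` (gene x
#'   algorithm integer matrix), `geomean_rank` (named numeric) and
#'   `overall` (ordered character vector).
#' @export
aggregate_rankings <- function(rankings, labels = NULL) {
  stopifnot(length(rankings) >= 2)
  genes <- sort(unique(rankings[[1]]))
  for (i in seq_along(rankings)) {
    gi <- sort(unique(rankings[[i]]))
    if (!identical(gi, genes) || length(rankings[[i]]) != length(genes)) {
      diff <- c(setdiff(genes, gi), setdiff(gi, genes))
      stop("rankings cover different gene sets; symmetric difference: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  labels <- labels %||% paste0("algorithm", seq_along(rankings))
  pos <- vapply(rankings, function(r) match(genes, r),
                integer(length(genes)))
  dimnames(pos) <- list(genes, labels)
  geomean <- apply(pos, 1, geo_mean)
  amean <- rowMeans(pos)
  overall <- genes[order(geomean, amean, genes, method = "radix")]
  structure(list(positions = pos, geomean_rank = geomean,
                 overall = overall),
            class = "aggregated_ranking")
}

#' @export
print.aggregated_ranking <- function(x, ...) {
  cat("Overall ranking (best first):\n ",
      paste(x$overall, collapse = ", "), "\n")
  cat("Geometric-mean rank:\n")
  print(round(x$geomean_rank[x$overall], 4))
  invisible(x)
}

#' Run all four stability algorithms and aggregate
#'
#' Convenience wrapper: GeNorm (on efficiency-corrected relative
#' quantities), DeltaCt, BestKeeper and NormFinder on a collapsed Ct
#' matrix, followed by geometric-mean rank aggregation.
#'
#' @param m a `ct_matrix`.
#' @param primers optional [primer_info()].
#' @param use_groups grouped NormFinder estimator (see
#'   [normfinder_stability()]).
#' @param efficiency_default default amplification efficiency.
#' @param algorithms subset of
#'   `c("genorm", "deltact", "bestkeeper", "normfinder")`.
#' @return List of class `stability_report` with one entry per algorithm
#'   plus `aggregated`.
#' @export
stability_report <- function(m, primers = NULL, use_groups = FALSE,
                             efficiency_default = 2,
                             algorithms = c("genorm", "deltact",
                                            "bestkeeper", "normfinder")) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  out <- list()
  if ("genorm" %in% algorithms) {
    q <- to_relative_quantities(m, primers, efficiency_default)
    out$genorm <- genorm_ranking(q)
  }
  if ("deltact" %in% algorithms) out$deltact <- deltact_stability(m)
  if ("bestkeeper" %in% algorithms) out$bestkeeper <- bestkeeper(m)
  if ("normfinder" %in% algorithms) {
    out$normfinder <- normfinder_stability(m, primers, use_groups,
                                           efficiency_default)
  }
  if (length(out) >= 2) {
    out$aggregated <- aggregate_rankings(lapply(out, `[[`, "ranking"),
                                         labels = names(out))
  }
  class(out) <- "stability_report"
  out
}
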