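# Efficiency-corrected comparative delta-Ct quantification of target genes
# normalized to a multi-gene reference factor, plus dilution-series
# efficiency estimation and the F-test-then-t-test stage comparison.

#' Amplification efficiency from a dilution series
#'
#' Fits Ct against log10 of relative input (log10(1/dilution_factor)) by
#' least squares; the efficiency is \eqn{E = 10^{-1/\mathrm{slope}}}. A
#' perfect doubling assay loses one cycle per 2-fold input increase,
#' i.e. slope -3.3219 and E = 2. A non-negative slope marks a failed assay:
#' the curve is flagged invalid and E is `NA`.
#'
#' @param points data frame with columns `dilution_factor` (fold dilution,
#'   >= 1) and `ct`, or the `dilution_factor` vector when `ct` is given.
#' @param ct optional Ct vector matching `points`.
#' @param gene optional gene name carried in the result.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `valid`, `points`, `gene`.
#' @export
efficiency_from_dilution_series <- function(points, ct = NULL, gene = NA) {
  if (!is.null(ct)) {
    points <- data.frame(dilution_factor = points, ct = ct)
  }
  stopifnot(all(c("dilution_factor", "ct") %in% names(points)))
  if (length(unique(points$dilution_factor)) < 3) {
    stop("at least 3 distinct dilution levels required")
  }
  if (any(points$dilution_factor < 1)) {
    stop("dilution factors must be >= 1")
  }
  x <- log10(1 / points$dilution_factor)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = points$ct, x = x))
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
  valid <- slope < 0
  eff <- if (valid) 10 ^ (-1 / slope) else NA_real_
  if (!valid) warning("non-negative standard-curve slope: invalid assay")
  structure(list(gene = gene, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, efficiency = eff, valid = valid,
                 points = points),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: slope %.4f, R^2 %.4f, E = %.4f%s\n",
              if (is.na(x$gene)) "" else paste0(" (", x$gene, ")"),
              x$slope, x$r_squared, x$efficiency,
              if (x$valid) "" else " [INVALID]"))
  invisible(x)
}

#' Multi-gene normalization factor
#'
#' The per-sample geometric mean of the reference genes' relative
#' quantities. Dividing a target's quantity by this factor removes
#' sample-loading differences; three stable references are the recommended
#' minimum.
#'
#' @param q an `rq_matrix` from [to_relative_quantities()].
#' @param reference_genes character vector of genes present in `q`.
#' @return List of class `normalization_factor` with `reference_genes` and
#'   `nf` (named positive numeric, one value per sample).
#' @export
normalization_factor <- function(q, reference_genes) {
  stopifnot(inherits(q, "rq_matrix"))
  miss <- setdiff(reference_genes, q$genes)
  if (length(miss)) {
    stop("reference gene(s) absent: ", paste(miss, collapse = ", "))
  }
  nf <- apply(q$q[reference_genes, , drop = FALSE], 2, geo_mean)
  structure(list(reference_genes = reference_genes, nf = nf),
            class = "normalization_factor")
}

#' Normalized relative expression with group summaries
#'
#' Divides a target gene's per-sample relative quantity by the
#' normalization factor and rescales so the calibrator group (by default
#' its mean; optionally the single lowest sample) sits at 1. Group means,
#' SEM (SD/sqrt(n)) and n are computed on the rescaled values.
#'
#' @param target_q named numeric vector of the target's relative
#'   quantities, one per sample.
#' @param nf a [normalization_factor()] (or named numeric vector) over the
#'   same samples.
#' @param calibrator_group group label whose mean is set to 1.
#' @param groups named character vector, sample -> group.
#' @param rescale `"group_mean"` (default) or `"min_sample"`.
#' @param gene optional gene name carried in the result.
#' @return List of class `relquant_result`: `gene`, `expression` (named,
#'   rescaled), `summary` (data frame `group,n,mean,sem`), `groups`,
#'   `calibrator_group`.
#' @export
normalized_expression <- function(target_q, nf, calibrator_group, groups,
                                  rescale = c("group_mean", "min_sample"),
                                  gene = NA) {
  rescale <- match.arg(rescale)
  if (inherits(nf, "normalization_factor")) nf <- nf$nf
  if (!setequal(names(target_q), names(nf))) {
    stop("sample sets of target and normalization factor differ: ",
         paste(c(setdiff(names(target_q), names(nf)),
                 setdiff(names(nf), names(target_q))), collapse = ", "))
  }
  miss <- setdiff(names(target_q), names(groups))
  if (length(miss)) stop("no group for sample(s): ",
                         paste(miss, collapse = ", "))
  x <- target_q / nf[names(target_q)]
  grp <- groups[names(x)]
  if (!calibrator_group %in% grp) {
    stop("calibrator group not present: ", calibrator_group)
  }
  denom <- if (rescale == "group_mean") {
    mean(x[grp == calibrator_group])
  } else {
    min(x)
  }
  x <- x / denom
  lev <- unique(grp)
  summary <- data.frame(
    group = lev,
    n     = as.integer(tapply(x, factor(grp, lev), length)),
    mean  = as.numeric(tapply(x, factor(grp, lev), mean)),
    sem   = as.numeric(tapply(x, factor(grp, lev),
                              function(v) stats::sd(v) / sqrt(length(v)))),
    stringsAsFactors = FALSE
  )
  structure(list(gene = gene, expression = x, summary = summary,
                 groups = grp, calibrator_group = calibrator_group),
            class = "relquant_result")
}

#' @export
print.relquant_result <- function(x, ...) {
  cat(sprintf("Relative expression%s (calibrator %s = 1):\n",
              if (is.na(x$gene)) "" else paste0(" of ", x$gene),
              x$calibrator_group))
  print(transform(x$summary, mean = round(mean, 4), sem = round(sem, 4)))
  invisible(x)
}

#' Quantify target genes against a reference set
#'
#' End-to-end convenience wrapper: converts a collapsed Ct matrix to
#' efficiency-corrected relative quantities, builds the reference
#' normalization factor, and normalizes each target gene with the
#' calibrator group rescaled to 1.
#'
#' @param m a `ct_matrix`.
#' @param targets character vector of target genes.
#' @param reference_genes character vector of reference genes.
#' @param calibrator_group calibrator group label.
#' @param primers optional [primer_info()].
#' @param efficiency_default default amplification efficiency.
#' @param rescale see [normalized_expression()].
#' @return Named list of `relquant_result`, one per target.
#' @export
quantify_targets <- function(m, targets, reference_genes, calibrator_group,
                             primers = NULL, efficiency_default = 2,
                             rescale = "group_mean") {
  stopifnot(inherits(m, "ct_matrix"))
  q <- to_relative_quantities(m, primers, efficiency_default)
  miss <- setdiff(targets, q$genes)
  if (length(miss)) stop("target gene(s) absent: ",
                         paste(miss, collapse = ", "))
  nf <- normalization_factor(q, reference_genes)
  out <- lapply(targets, function(g) {
    normalized_expression(q$q[g, ], nf, calibrator_group, m$group_of,
                          rescale = rescale, gene = g)
  })
  stats::setNames(out, targets)
}

#' Two-group comparison: F-test for variances, then t-test
#'
#' Tests whether two stages differ in normalized expression. A two-sided
#' F-test on the variance ratio decides the t-test variant: pooled
#' (Student) when the F-test p-value is at least `alpha_variance`, Welch
#' otherwise. The t-test is two-sided.
#'
#' @param result a `relquant_result` from [normalized_expression()].
#' @param group_a,group_b group labels, each with at least 2 samples.
#' @param alpha_variance significance level of the variance F-test used to
#'   pick the t variant (default 0.05).
#' @return List of class `group_comparison`: `group_a`, `group_b`,
#'   `f_statistic`, `f_p`, `variant` (`"student"` or `"welch"`),
#'   `t_statistic`, `df`, `t_p`.
#' @export
compare_stages <- function(result, group_a, group_b,
                           alpha_variance = 0.05) {
  stopifnot(inherits(result, "relquant_result"))
  a <- result$expression[result$groups == group_a]
  b <- result$expression[result$groups == group_b]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 samples (",
         group_a, ": ", length(a), ", ", group_b, ": ", length(b), ")")
  }
  f <- stats::var.test(a, b)
  pooled <- f$p.value >= alpha_variance
  t <- stats::t.test(a, b, var.equal = pooled)
  structure(list(group_a = group_a, group_b = group_b,
                 f_statistic = unname(f$statistic), f_p = f$p.value,
                 variant = if (pooled) "student" else "welch",
                 t_statistic = unname(t$statistic),
                 df = unname(t$parameter), t_p = t$p.value),
            class = "group_comparison")
}

#' Pairwise comparisons of consecutive stages
#'
#' Applies [compare_stages()] to every consecutive pair of groups in their
#' order of appearance. P-values are unadjusted by default; Holm adjustment
#' is available.
#'
#' @param result a `relquant_result`.
#' @param alpha_variance see [compare_stages()].
#' @param adjust `"none"` (default) or `"holm"`, applied to the t-test
#'   p-values.
#' @return Data frame with one row per consecutive pair:
#'   `group_a,group_b,f_p,variant,t,df,p` (and `p_adj` when adjusted).
#' @export
compare_consecutive_stages <- function(result, alpha_variance = 0.05,
                                       adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  lev <- unique(result$groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  cmp <- lapply(seq_len(length(lev) - 1), function(i) {
    compare_stages(result, lev[i], lev[i + 1], alpha_variance)
  })
  df <- data.frame(
    group_a = vapply(cmp, `[[`, "", "group_a"),
    group_b = vapply(cmp, `[[`, "", "group_b"),
    f_p     = vapply(cmp, `[[`, 0, "f_p"),
    variant = vapply(cmp, `[[`, "", "variant"),
    t       = vapply(cmp, `[[`, 0, "t_statistic"),
    df      = vapply(cmp, `[[`, 0, "df"),
    p       = vapply(cmp, `[[`, 0, "t_p"),
    stringsAsFactors = FALSE
  )
  if (adjust == "holm") df$p_adj <- stats::p.adjust(df$p, "holm")
  df
}
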