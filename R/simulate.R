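# Seeded simulators for Ct tables and expression matrices with planted
# ground truth. The Ct model is additive on the cycle (log2) scale,
# consistent with exponential amplification:
#
#   Ct[g,s,r] = B_g + L_s + T_[g, stage(s)] + delta[g,s] + eps[g,s,r]
#
# with per-sample loading offsets L ~ N(0, loading_sd^2) (the "true"
# normalization factor every stability algorithm tries to recover),
# per-(gene, sample) biological instability delta ~ N(0, instability_sd_g^2),
# fixed stage effects T, and technical-replicate noise eps.

#' Configuration for a simulated Ct experiment
#'
#' @param genes data frame with columns `name`, `base_ct` (cycles) and
#'   `instability_sd` (cycles); gene-specific noise around the sample
#'   baseline. A perfect reference gene has `instability_sd = 0`.
#' @param stages named integer vector: stage label -> number of biological
#'   samples. Defaults to the five postnatal stages P14..P56 with n = 3.
#' @param stage_effects optional genes x stages numeric matrix of fixed Ct
#'   shifts (a regulated target gene gets a nonzero row); default all 0.
#' @param loading_sd SD in cycles of the per-sample loading offset
#'   (pipetting / input differences common to all genes); default 0.5.
#' @param tech_sd SD in cycles of technical-replicate noise; default 0.25.
#' @param replicates technical replicates per reaction; default 3.
#' @param efficiency named numeric vector of per-gene amplification
#'   factors; genes not listed use 2.
#' @param seed integer RNG seed.
#' @return Validated list of class `ct_sim_config`.
#' @export
ct_sim_config <- function(genes,
                          stages = c(P14 = 3, P28 = 3, P35 = 3,
                                     P42 = 3, P56 = 3),
                          stage_effects = NULL,
                          loading_sd = 0.5, tech_sd = 0.25,
                          replicates = 3, efficiency = NULL, seed = 1) {
  stopifnot(is.data.frame(genes),
            all(c("name", "base_ct", "instability_sd") %in% names(genes)))
  genes$name <- normalize_gene(as.character(genes$name))
  if (any(genes$instability_sd < 0)) stop("instability_sd must be >= 0")
  if (loading_sd < 0 || tech_sd < 0) stop("SDs must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(stages) < 1 || any(stages < 1)) stop("invalid stages")
  if (is.null(stage_effects)) {
    stage_effects <- matrix(0, nrow(genes), length(stages),
                            dimnames = list(genes$name, names(stages)))
  } else {
    stage_effects <- as.matrix(stage_effects)
    stopifnot(identical(rownames(stage_effects), genes$name),
              identical(colnames(stage_effects), names(stages)))
  }
  structure(list(genes = genes, stages = stages,
                 stage_effects = stage_effects,
                 loading_sd = loading_sd, tech_sd = tech_sd,
                 replicates = as.integer(replicates),
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "ct_sim_config")
}

#' Simulate a Ct table with planted ground truth
#'
#' Draws the additive Ct model described in the package vignette from a
#' seeded Mersenne-Twister stream: loading offsets per sample, biological
#' deviations per (gene, sample), technical noise per replicate. The same
#' config and seed reproduce bit-identical output on any platform.
#'
#' @param config a [ct_sim_config()].
#' @return List with `table` (a [ct_table()]) and `truth` (class
#'   `synthetic_truth`): `loading` (named per-sample offsets), `bio_dev`
#'   (genes x samples deviation matrix), `samples`, `group_of`, and the
#'   echoed `config`.
#' @export
generate_ct_dataset <- function(config) {
  stopifnot(inherits(config, "ct_sim_config"))
  stages <- config$stages
  samples <- unlist(lapply(names(stages), function(st) {
    paste0(st, "_", seq_len(stages[[st]]))
  }))
  stage_of <- stats::setNames(rep(names(stages), times = stages), samples)
  gn <- config$genes$name
  with_seed(config$seed, {
    loading <- stats::setNames(
      stats::rnorm(length(samples), 0, config$loading_sd), samples)
    bio <- matrix(stats::rnorm(length(gn) * length(samples)),
                  length(gn), length(samples),
                  dimnames = list(gn, samples)) * config$genes$instability_sd
    reps <- config$replicates
    rows <- expand.grid(replicate = seq_len(reps), sample = samples,
                        gene = gn, stringsAsFactors = FALSE)
    mu <- config$genes$base_ct[match(rows$gene, gn)] +
      loading[rows$sample] +
      config$stage_effects[cbind(rows$gene, stage_of[rows$sample])] +
      bio[cbind(rows$gene, rows$sample)]
    ct <- mu + stats::rnorm(nrow(rows), 0, config$tech_sd)
    tab <- ct_table(rows$sample, stage_of[rows$sample], rows$gene,
                    rows$replicate, ct)
    truth <- structure(list(loading = loading, bio_dev = bio,
                            samples = samples, group_of = stage_of,
                            config = config),
                       class = "synthetic_truth")
    list(table = tab, truth = truth)
  })
}

#' Configuration for a simulated grouped expression matrix
#'
#' Emulates the structure of a two-condition-per-comparison microarray
#' study: a planted core of genes with zero true condition effects, a set
#' of planted regulated genes with known true logFC in one comparison
#' each, and background genes whose condition effects drift randomly.
#'
#' @param n_core planted stable-core size (true effects all 0).
#' @param n_regulated planted regulated genes; gene i is shifted in
#'   comparison `(i mod n_comparisons) + 1` with alternating sign.
#' @param n_background genes with condition effects drawn
#'   N(0, `background_sd`^2).
#' @param conditions named integer vector: condition label -> array count.
#' @param comparisons list of length-2 character vectors (condition pairs)
#'   defining the comparisons of interest; defaults to consecutive,
#'   non-overlapping pairs of `conditions`.
#' @param regulated_logfc absolute true logFC planted in regulated genes
#'   (default 0.5).
#' @param background_sd SD of background condition effects (default 0.3).
#' @param noise_sd per-array measurement noise SD (log2 units).
#' @param base_range range of per-gene baseline log2 expression, drawn
#'   uniformly (default 4..14, a typical microarray intensity span).
#' @param seed integer RNG seed.
#' @return Validated list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_core, n_regulated = 0, n_background = 0,
                            conditions, comparisons = NULL,
                            regulated_logfc = 0.5, background_sd = 0.3,
                            noise_sd = 0.05, base_range = c(4, 14),
                            seed = 1) {
  stopifnot(n_core >= 1, n_regulated >= 0, n_background >= 0,
            length(conditions) >= 2, all(conditions >= 1),
            noise_sd >= 0, background_sd >= 0, regulated_logfc >= 0)
  if (is.null(comparisons)) {
    idx <- seq(1, length(conditions) - 1, by = 2)
    comparisons <- lapply(idx, function(i) names(conditions)[c(i, i + 1)])
  }
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2, all(cmp %in% names(conditions)))
  }
  structure(list(n_core = n_core, n_regulated = n_regulated,
                 n_background = n_background, conditions = conditions,
                 comparisons = comparisons,
                 regulated_logfc = regulated_logfc,
                 background_sd = background_sd, noise_sd = noise_sd,
                 base_range = base_range, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a grouped expression matrix with planted truth
#'
#' Model: \eqn{y_{ga} = \mu_g + \mathrm{effect}_g(\mathrm{cond}(a)) +
#' N(0, \mathrm{noise\_sd}^2)}. Core genes (`core...`) have all effects 0;
#' each regulated gene (`reg...`) carries `regulated_logfc` (alternating
#' sign) on the first condition of one comparison; background genes
#' (`bg...`) get independent random condition effects.
#'
#' @param config an [expr_sim_config()].
#' @return List with `matrix` (an [expression_matrix()]) and `truth`:
#'   `effects` (gene x condition), `true_logfc` (gene x comparison),
#'   `core`, `regulated`, echoed `config`.
#' @export
generate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  conds <- config$conditions
  genes <- c(
    if (config$n_core) sprintf("core%03d", seq_len(config$n_core)),
    if (config$n_regulated) sprintf("reg%03d", seq_len(config$n_regulated)),
    if (config$n_background) sprintf("bg%03d", seq_len(config$n_background))
  )
  arrays <- unlist(lapply(names(conds), function(cd) {
    paste0(cd, "_a", seq_len(conds[[cd]]))
  }))
  group_of <- stats::setNames(rep(names(conds), times = conds), arrays)
  eff <- matrix(0, length(genes), length(conds),
                dimnames = list(genes, names(conds)))
  ncmp <- length(config$comparisons)
  if (config$n_regulated) {
    for (i in seq_len(config$n_regulated)) {
      cmp <- config$comparisons[[((i - 1) %% ncmp) + 1]]
      sgn <- if (i %% 2 == 1) 1 else -1
      eff[sprintf("reg%03d", i), cmp[1]] <- sgn * config$regulated_logfc
    }
  }
  with_seed(config$seed, {
    if (config$n_background) {
      bg <- sprintf("bg%03d", seq_len(config$n_background))
      eff[bg, ] <- stats::rnorm(length(bg) * length(conds),
                                0, config$background_sd)
    }
    mu <- stats::runif(length(genes), config$base_range[1],
                       config$base_range[2])
    y <- mu + eff[, group_of[arrays]] +
      matrix(stats::rnorm(length(genes) * length(arrays),
                          0, config$noise_sd),
             length(genes), length(arrays))
    dimnames(y) <- list(genes, arrays)
    true_logfc <- vapply(config$comparisons, function(cmp) {
      eff[, cmp[1]] - eff[, cmp[2]]
    }, numeric(length(genes)))
    colnames(true_logfc) <- vapply(config$comparisons,
                                   paste, "", collapse = "_vs_")
    list(matrix = expression_matrix(y, group_of),
         truth = list(effects = eff, true_logfc = true_logfc,
                      core = grep("^core", genes, value = TRUE),
                      regulated = grep("^reg0", genes, value = TRUE),
                      config = config))
  })
}

#' Read a Ct simulation config from JSON
#'
#' JSON keys mirror the [ct_sim_config()] arguments; `genes` is an array
#' of objects with `name`, `base_ct`, `instability_sd` and optionally
#' `stage_effects` (an object keyed by stage label), `stages` an object of
#' stage -> sample count. A ready-made example mimicking a 16-candidate
#' five-stage study plus a low-abundance trending target is bundled as
#' `system.file("extdata", "paperlike.json", package = "refstab")`.
#'
#' @param path JSON file path.
#' @return A [ct_sim_config()].
#' @export
read_ct_sim_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- data.frame(
    name = vapply(js$genes, `[[`, "", "name"),
    base_ct = vapply(js$genes, `[[`, 0, "base_ct"),
    instability_sd = vapply(js$genes, `[[`, 0, "instability_sd"),
    stringsAsFactors = FALSE
  )
  stages <- unlist(js$stages)
  se <- matrix(0, nrow(genes), length(stages),
               dimnames = list(normalize_gene(genes$name), names(stages)))
  for (g in js$genes) {
    if (!is.null(g$stage_effects)) {
      for (st in names(g$stage_effects)) {
        se[normalize_gene(g$name), st] <- g$stage_effects[[st]]
      }
    }
  }
  ct_sim_config(genes, stages = stages, stage_effects = se,
                loading_sd = js$loading_sd %||% 0.5,
                tech_sd = js$tech_sd %||% 0.25,
                replicates = js$replicates %||% 3,
                efficiency = if (!is.null(js$efficiency))
                  unlist(js$efficiency),
                seed = js$seed %||% 1)
}
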