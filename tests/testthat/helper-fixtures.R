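# Fixture builders shared across tests. All randomness is seeded at the
# call site through with_seed-style wrappers so fixtures are reproducible.

# A ct_matrix built directly from a genes x samples matrix.
fixture_ct_matrix <- function(ct, groups = NULL) {
  if (is.null(groups)) groups <- rep("g1", ncol(ct))
  structure(list(ct = ct, genes = rownames(ct), samples = colnames(ct),
                 group_of = stats::setNames(groups, colnames(ct))),
            class = "ct_matrix")
}

# The worked 3-gene example with hand-computed pairwise SDs.
fixture_xyz <- function() {
  ct <- rbind(X = c(20, 20, 20, 20),
              Y = c(21, 21.5, 21, 21.5),
              Z = c(25, 24, 25, 26))
  colnames(ct) <- paste0("s", 1:4)
  fixture_ct_matrix(ct)
}

# Random Ct matrix: per-gene baseline + per-sample loading + noise.
random_ct_matrix <- function(n_genes, n_samples, seed,
                             loading_sd = 0.5, noise_sd = 0.3,
                             groups = NULL) {
  set.seed(seed)
  base <- runif(n_genes, 16, 28)
  loading <- rnorm(n_samples, 0, loading_sd)
  ct <- outer(base, loading, `+`) +
    matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
  dimnames(ct) <- list(sprintf("g%02d", seq_len(n_genes)),
                       sprintf("s%02d", seq_len(n_samples)))
  fixture_ct_matrix(ct, groups)
}

# Simulated 15-sample, 5-stage dataset with a planted instability ladder.
ladder_sim <- function(seed, sds = c(0.05, 0.1, 0.2, 0.4, 0.8),
                       loading_sd = 0.5) {
  genes <- data.frame(
    name = sprintf("lad%d", seq_along(sds)),
    base_ct = 20 + seq_along(sds),
    instability_sd = sds
  )
  cfg <- ct_sim_config(genes, loading_sd = loading_sd, tech_sd = 0,
                       replicates = 1, seed = seed)
  generate_ct_dataset(cfg)
}

# The four per-algorithm rankings printed for the 16-gene candidate panel,
# used as aggregation inputs.
table1_rankings <- function() {
  list(
    deltact = c("Prdx1", "Ctbp1", "Phf7", "Tbp", "Hprt", "Rpl13a",
                "Sugp2", "Gapdh", "Clock", "18S", "Usp7", "Taf11",
                "Sdha", "Actb", "Hmbs", "Arpc3"),
    bestkeeper = c("Prdx1", "Ctbp1", "Rpl13a", "Phf7", "Tbp", "Hprt",
                   "Sugp2", "Gapdh", "Taf11", "Usp7", "Clock", "18S",
                   "Sdha", "Actb", "Hmbs", "Arpc3"),
    normfinder = c("Phf7", "Tbp", "Prdx1", "Ctbp1", "Hprt", "Rpl13a",
                   "Clock", "Sugp2", "Gapdh", "18S", "Usp7", "Taf11",
                   "Sdha", "Actb", "Hmbs", "Arpc3"),
    genorm = c("Phf7", "Prdx1", "Ctbp1", "Hprt", "Rpl13a", "Gapdh",
               "Sugp2", "Usp7", "Taf11", "Clock", "Tbp", "18S",
               "Sdha", "Actb", "Hmbs", "Arpc3")
  )
}

published_overall <- c("Prdx1", "Phf7", "Ctbp1", "Tbp", "Rpl13a", "Hprt",
                       "Sugp2", "Gapdh", "Clock", "Usp7", "Taf11", "18S",
                       "Sdha", "Actb", "Hmbs", "Arpc3")

# Five-stage study with a monotone trending target (-0.5 cycles per stage
# vs P14) and three reference genes of tunable instability.
wnt_sim <- function(seed, ref_sd = 0.1, loading_sd = 0.5, tech_sd = 0.25) {
  genes <- data.frame(
    name = c("Wnt4", "ref1", "ref2", "ref3"),
    base_ct = c(29, 20, 22, 24),
    instability_sd = c(0, rep(ref_sd, 3))
  )
  stages <- c(P14 = 3, P28 = 3, P35 = 3, P42 = 3, P56 = 3)
  se <- matrix(0, 4, 5, dimnames = list(genes$name, names(stages)))
  se["Wnt4", ] <- c(0, -0.5, -1, -1.5, -2)
  cfg <- ct_sim_config(genes, stages = stages, stage_effects = se,
                       loading_sd = loading_sd, tech_sd = tech_sd,
                       replicates = 3, seed = seed)
  generate_ct_dataset(cfg)
}

# Positions (1 = best) induced by an ordered ranking.
gene_positions_of <- function(ranking) {
  stats::setNames(seq_along(ranking), ranking)
}

# Long-dialect CSV text for a tiny Ct table.
long_csv <- function(rows) {
  paste(c("sample_id,group,gene,replicate,ct,is_noRT", rows),
        collapse = "\n")
}
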