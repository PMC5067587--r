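# Frozen values for the 3-gene worked example come from direct evaluation
# of pairwise Ct-difference standard deviations (see helper fixture_xyz).

test_that("GeNorm M-values match hand-computed pairwise SDs", {
  q <- to_relative_quantities(fixture_xyz())
  m <- genorm_m_values(q)
  expect_equal(m, c(X = 0.5525859, Y = 0.5773503, Z = 0.8412610),
               tolerance = 1e-6)

  # two genes: both M equal the single pairwise SD of the Ct difference
  ct2 <- rbind(A = c(20, 21, 22), B = c(20, 21.5, 23))
  colnames(ct2) <- paste0("s", 1:3)
  m2 <- genorm_m_values(to_relative_quantities(fixture_ct_matrix(ct2)))
  expect_equal(unname(m2), c(0.5, 0.5))

  const <- matrix(5, 1, 3, dimnames = list("A", paste0("s", 1:3)))
  expect_error(genorm_m_values(const), "single gene")
  expect_error(genorm_m_values(rbind(const, B = c(1, 1, -1))), "positive")
})

test_that("stepwise exclusion removes the least stable gene first", {
  gr <- genorm_ranking(to_relative_quantities(fixture_xyz()))
  expect_equal(gr$exclusion_order[1], "Z")
  expect_equal(gr$ranking, c("X", "Y", "Z"))
  # worst-to-best order is the exclusion sequence followed by the final
  # pair reversed
  expect_equal(c(gr$exclusion_order, rev(gr$ranking[1:2])),
               rev(gr$ranking))
  expect_equal(unname(gr$m_values["Z"]), 0.8412610, tolerance = 1e-6)

  # all-constant matrix: every M zero, lexicographic ranking
  ct <- matrix(20, 4, 5, dimnames = list(c("d", "b", "c", "a"),
                                         paste0("s", 1:5)))
  gc <- genorm_ranking(to_relative_quantities(fixture_ct_matrix(ct)))
  expect_equal(gc$ranking, c("a", "b", "c", "d"))
  expect_equal(unname(gc$m_values), rep(0, 4))
})

test_that("stepwise exclusion recovers a planted instability ladder", {
  # Exclusion removes genes until two remain, so the recoverable order is
  # the three most unstable genes, worst first; the closely spaced bottom
  # pair (sigma 0.05 vs 0.1 over 15 samples) is not reliably separable.
  hits <- 0
  for (i in 1:100) {
    sim <- ladder_sim(seed = 200 + i)
    m <- collapse_replicates(sim$table)
    gr <- genorm_ranking(to_relative_quantities(m))
    hits <- hits + identical(gr$exclusion_order,
                             c("lad5", "lad4", "lad3"))
  }
  expect_gte(hits, 85)
})

test_that("pairwise variation follows the normalization-factor definition", {
  m <- fixture_xyz()
  q <- to_relative_quantities(m)
  gr <- genorm_ranking(q)
  v <- genorm_pairwise_variation(q, gr$ranking)
  expect_named(v, "V2_3")

  # direct evaluation oracle
  qm <- q$q
  nf2 <- apply(qm[c("X", "Y"), ], 2, function(x) exp(mean(log(x))))
  nf3 <- apply(qm, 2, function(x) exp(mean(log(x))))
  expect_equal(unname(v), sd(log2(nf2 / nf3)), tolerance = 1e-12)
  expect_true(all(v >= 0))

  ident <- matrix(rep(c(1, 0.5, 0.25), 3), 3, 3, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"), paste0("s", 1:3)))
  expect_equal(unname(genorm_pairwise_variation(ident, c("A", "B", "C"))),
               0)
  expect_length(genorm_pairwise_variation(qm[1:2, ], c("X", "Y")), 0)
})

test_that("DeltaCt equals GeNorm at efficiency 2 and is symmetric for two genes", {
  m <- fixture_xyz()
  d <- deltact_stability(m)
  expect_equal(d$score, c(X = 0.5525859, Y = 0.5773503, Z = 0.8412610),
               tolerance = 1e-6)

  # equivalence oracle on 50 random matrices
  worst <- 0
  for (seed in 1:50) {
    mm <- random_ct_matrix(6, 10, seed)
    diff <- max(abs(genorm_m_values(to_relative_quantities(mm)) -
                    deltact_stability(mm)$score))
    worst <- max(worst, diff)
  }
  expect_lt(worst, 1e-9)

  ct2 <- rbind(A = c(20, 21, 22), B = c(20, 21.5, 23))
  colnames(ct2) <- paste0("s", 1:3)
  d2 <- deltact_stability(fixture_ct_matrix(ct2))
  expect_equal(unname(d2$score), rep(sd(c(0, 0.5, 1)), 2))

  const <- matrix(20, 3, 4, dimnames = list(c("A", "B", "C"),
                                            paste0("s", 1:4)))
  expect_equal(unname(deltact_stability(fixture_ct_matrix(const))$score),
               rep(0, 3))
})

test_that("BestKeeper reports SD, CV, geometric-mean index and correlations", {
  ct <- rbind(A = c(20, 21, 22), B = c(24, 25, 26), flat = c(18, 18, 18))
  colnames(ct) <- paste0("s", 1:3)
  bk <- bestkeeper(fixture_ct_matrix(ct))
  s <- bk$detail$summary
  expect_equal(s$sd_ct[s$gene == "A"], 1)
  expect_equal(s$cv_pct[s$gene == "A"], 100 / 21)
  expect_equal(bk$ranking[1], "flat")          # constant gene ranked first
  expect_true(is.na(s$r[s$gene == "flat"]))    # degenerate correlation

  # identical rows: index equals the shared row, correlations perfect
  two <- rbind(A = c(20, 21, 23), B = c(20, 21, 23))
  colnames(two) <- paste0("s", 1:3)
  bk2 <- bestkeeper(fixture_ct_matrix(two))
  expect_equal(unname(bk2$detail$index), c(20, 21, 23))
  expect_equal(unname(bk2$detail$summary$r), c(1, 1))

  # MAD variant scores by mean absolute deviation
  bkm <- bestkeeper(fixture_ct_matrix(ct), use_mad = TRUE)
  expect_equal(unname(bkm$score["A"]), mean(abs(c(20, 21, 22) - 21)))
})

test_that("NormFinder scores zero on noiseless data and flags the noisy gene", {
  # constant per group, no group effects -> all zero
  ct <- matrix(rep(c(20, 24, 26), 6), 3, 6,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:6)))
  m <- fixture_ct_matrix(ct, groups = rep(c("P14", "P56"), each = 3))
  expect_equal(unname(normfinder_stability(m)$score), rep(0, 3))
  expect_equal(unname(normfinder_stability(m, use_groups = TRUE)$score),
               rep(0, 3))

  # group-free: the one noisy gene gets the top score
  hits <- 0
  for (i in 1:100) {
    set.seed(400 + i)
    ctn <- rbind(noisy = 22 + rnorm(10, 0, 0.5),
                 r1 = rep(20, 10), r2 = rep(24, 10), r3 = rep(26, 10))
    colnames(ctn) <- paste0("s", 1:10)
    sc <- normfinder_stability(fixture_ct_matrix(ctn))$score
    hits <- hits + (names(which.max(sc)) == "noisy")
  }
  expect_gte(hits, 99)
})

test_that("grouped NormFinder recovers a planted group shift", {
  groups <- rep(c("P14", "P56"), each = 4)
  ct <- rbind(shifted = c(rep(22, 4), rep(23, 4)),   # +1 cycle in P56
              r1 = rep(20, 8), r2 = rep(24, 8), r3 = rep(26, 8))
  colnames(ct) <- paste0("s", 1:8)
  m <- fixture_ct_matrix(ct, groups = groups)
  nf <- normfinder_stability(m, use_groups = TRUE)
  expect_equal(nf$ranking[4], "shifted")
  # planted 1-cycle shift appears in d up to the gene-centering factor
  d <- nf$detail$d["shifted", ]
  expect_equal(unname(d["P56"] - d["P14"]), -1 * (1 - 1/4), tolerance = 1e-9)
  # one-sample group rejected by name
  bad <- fixture_ct_matrix(ct, groups = c(rep("P14", 7), "solo"))
  expect_error(normfinder_stability(bad, use_groups = TRUE), "solo")
})

test_that("ratio-based scores ignore per-sample loading; BestKeeper does not", {
  m <- random_ct_matrix(5, 9, seed = 77,
                        groups = rep(c("P14", "P35", "P56"), each = 3))
  shift <- seq(-1.2, 1.2, length.out = 9)
  m2 <- m
  m2$ct <- sweep(m$ct, 2, shift, `+`)
  expect_lt(max(abs(genorm_m_values(to_relative_quantities(m2)) -
                    genorm_m_values(to_relative_quantities(m)))), 1e-9)
  expect_lt(max(abs(deltact_stability(m2)$score -
                    deltact_stability(m)$score)), 1e-9)
  expect_lt(max(abs(normfinder_stability(m2)$score -
                    normfinder_stability(m)$score)), 1e-9)
  expect_lt(max(abs(normfinder_stability(m2, use_groups = TRUE)$score -
                    normfinder_stability(m, use_groups = TRUE)$score)),
            1e-9)
  expect_gt(max(abs(bestkeeper(m2)$score - bestkeeper(m)$score)), 1e-3)
})

test_that("all scores are permutation invariant", {
  m <- random_ct_matrix(6, 10, seed = 5)
  pg <- sample(6); ps <- sample(10)
  m2 <- fixture_ct_matrix(m$ct[pg, ps], groups = m$group_of[ps])
  expect_equal(sort(genorm_m_values(to_relative_quantities(m))),
               sort(genorm_m_values(to_relative_quantities(m2))))
  expect_equal(deltact_stability(m)$score[m2$genes],
               deltact_stability(m2)$score)
  expect_equal(bestkeeper(m)$score[m2$genes], bestkeeper(m2)$score)
  expect_equal(normfinder_stability(m)$score[m2$genes],
               normfinder_stability(m2)$score)
})

test_that("rankings track a planted instability ladder within each algorithm's design limits", {
  # GeNorm and DeltaCt work on pairwise ratios, so per-sample loading
  # offsets cancel and the planted sigma order is recovered through them.
  sds <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  lad <- sprintf("lad%d", 1:5)
  rho_gn <- rho_dc <- rho_bk0 <- numeric(50)
  nf_worst <- 0
  for (i in 1:50) {
    m <- collapse_replicates(ladder_sim(seed = 3000 + i)$table)
    rho_gn[i] <- cor(sds, gene_positions_of(
      genorm_ranking(to_relative_quantities(m))$ranking)[lad],
      method = "spearman")
    rho_dc[i] <- cor(sds, gene_positions_of(
      deltact_stability(m)$ranking)[lad], method = "spearman")
    # NormFinder sample-centering over only 5 genes blurs the closely
    # spaced stable end; the clearly unstable gene is still flagged.
    nf_worst <- nf_worst +
      (normfinder_stability(m)$ranking[5] == "lad5")
    # BestKeeper scores raw-Ct SD, so loading must be controlled for the
    # ladder to be identifiable through it.
    m0 <- collapse_replicates(ladder_sim(seed = 3000 + i,
                                         loading_sd = 0)$table)
    rho_bk0[i] <- cor(sds, gene_positions_of(bestkeeper(m0)$ranking)[lad],
                      method = "spearman")
  }
  expect_gte(mean(rho_gn), 0.9)
  expect_gte(mean(rho_dc), 0.9)
  expect_gte(mean(rho_bk0), 0.9)
  expect_gte(nf_worst, 45)
})

test_that("rank aggregation reproduces the published 16-gene consensus", {
  t1 <- table1_rankings()
  agg <- aggregate_rankings(t1, names(t1))
  expect_equal(agg$overall, published_overall)
  expect_equal(unname(agg$geomean_rank["Prdx1"]), 6^(1/4),
               tolerance = 1e-6)
  # novel candidates occupy the top three positions
  expect_setequal(agg$overall[1:3], c("Prdx1", "Phf7", "Ctbp1"))
})

test_that("rank aggregation is idempotent, bounded and rejects mismatched sets", {
  same <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(aggregate_rankings(same)$overall, c("a", "b", "c"))

  t1 <- table1_rankings()
  agg <- aggregate_rankings(t1, names(t1))
  for (g in rownames(agg$positions)) {
    expect_gte(agg$geomean_rank[[g]], min(agg$positions[g, ]) - 1e-9)
    expect_lte(agg$geomean_rank[[g]], max(agg$positions[g, ]) + 1e-9)
  }
  expect_error(
    aggregate_rankings(list(c("a", "b"), c("a", "x"))),
    "symmetric difference.*[bx]")
})
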