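test_that("standard-curve efficiency inverts the dilution model", {
  # perfect doubling: 10-fold dilutions spaced 3.3219 cycles apart
  sc <- efficiency_from_dilution_series(c(1, 10, 100),
                                        c(20, 23.3219, 26.6439))
  expect_equal(sc$efficiency, 2, tolerance = 1e-4)
  expect_equal(sc$slope, -3.3219, tolerance = 1e-3)
  expect_equal(sc$r_squared, 1, tolerance = 1e-8)

  # closed-form inversion of a generated series
  d <- c(2, 5, 10, 100, 1000)
  sc2 <- efficiency_from_dilution_series(d, 20 + 3.5 * log10(d))
  expect_equal(sc2$slope, -3.5, tolerance = 1e-10)
  expect_equal(sc2$efficiency, 10^(1 / 3.5), tolerance = 1e-10)

  expect_error(efficiency_from_dilution_series(c(1, 10), c(20, 23)),
               "3 distinct")
  expect_warning(
    bad <- efficiency_from_dilution_series(c(1, 10, 100), c(20, 19, 18)),
    "invalid")
  expect_false(bad$valid)
  expect_true(is.na(bad$efficiency))
})

test_that("round-trip: the generator's own forward model is inverted exactly", {
  for (E in c(1.8, 1.9307, 2.0, 2.1)) {
    d <- c(2, 5, 10, 100, 1000)
    ct <- 30 - log(1 / d) / log(E)   # Ct drops by 1/log2(E)... forward model
    sc <- efficiency_from_dilution_series(d, ct)
    expect_equal(sc$efficiency, E, tolerance = 1e-10)
  }
})

test_that("normalization factor is the geometric mean of reference quantities", {
  q <- structure(list(
    q = rbind(r1 = c(1, 0.25), r2 = c(1, 1), r3 = c(1, 0.5)),
    genes = c("r1", "r2", "r3"), samples = c("s1", "s2"),
    group_of = c(s1 = "P14", s2 = "P56")), class = "rq_matrix")
  colnames(q$q) <- q$samples
  expect_equal(unname(normalization_factor(q, c("r1", "r2"))$nf),
               c(1, 0.5))
  expect_equal(unname(normalization_factor(q, c("r1", "r2", "r3"))$nf[2]),
               (0.25 * 1 * 0.5)^(1/3))
  expect_error(normalization_factor(q, c("r1", "nope")), "nope")
})

test_that("normalized expression self-normalizes and recovers a 2-cycle 4-fold change", {
  # target identical to the single reference: flat 1 everywhere
  samples <- paste0("s", 1:6)
  groups <- stats::setNames(rep(c("P14", "P56"), each = 3), samples)
  tq <- stats::setNames(c(1, 0.8, 0.9, 0.5, 0.6, 0.7), samples)
  r <- normalized_expression(tq, stats::setNames(tq, samples), "P14", groups)
  expect_equal(unname(r$expression), rep(1, 6))

  # E = 2, constant references, 2 cycles lower at P56 -> 4-fold
  ct <- rbind(Wnt4 = c(28, 28, 28, 26, 26, 26),
              ref1 = rep(20, 6), ref2 = rep(22, 6), ref3 = rep(24, 6))
  colnames(ct) <- samples
  m <- fixture_ct_matrix(ct, groups = unname(groups))
  rq <- quantify_targets(m, "Wnt4", c("ref1", "ref2", "ref3"), "P14")
  s <- rq$Wnt4$summary
  expect_equal(s$mean[s$group == "P14"], 1)
  expect_equal(s$mean[s$group == "P56"], 4)
  expect_equal(s$sem, c(0, 0))
  expect_equal(s$n, c(3L, 3L))

  # min-sample calibration mode pins the smallest sample to 1
  rq_min <- quantify_targets(m, "Wnt4", c("ref1", "ref2", "ref3"), "P14",
                             rescale = "min_sample")
  expect_equal(min(rq_min$Wnt4$expression), 1)

  expect_error(normalized_expression(tq[1:5],
                                     stats::setNames(tq, samples),
                                     "P14", groups), "differ")
})

test_that("per-sample rescaling of all quantities cancels out (scale invariance)", {
  for (seed in 1:5) {
    set.seed(seed)
    samples <- paste0("s", 1:9)
    groups <- rep(c("P14", "P35", "P56"), each = 3)
    ct <- rbind(tgt = runif(9, 26, 30),
                r1 = runif(9, 19, 21), r2 = runif(9, 21, 23),
                r3 = runif(9, 23, 25))
    colnames(ct) <- samples
    m <- fixture_ct_matrix(ct, groups = groups)
    base <- quantify_targets(m, "tgt", c("r1", "r2", "r3"), "P14")

    # a per-sample Ct offset rescales every gene's quantity in that sample
    off <- rnorm(9, 0, 0.8)
    m2 <- fixture_ct_matrix(sweep(ct, 2, off, `+`), groups = groups)
    shifted <- quantify_targets(m2, "tgt", c("r1", "r2", "r3"), "P14")
    expect_equal(shifted$tgt$expression, base$tgt$expression,
                 tolerance = 1e-9)
  }
})

test_that("a planted monotone trend is recovered through noisy references", {
  planted <- 2^c(0, 0.5, 1, 1.5, 2)  # 1, 1.41, 2, 2.83, 4
  stages <- c("P14", "P28", "P35", "P42", "P56")
  rel_err <- matrix(NA_real_, 50, 5)
  for (i in 1:50) {
    sim <- wnt_sim(seed = 5000 + i, ref_sd = 0.1)
    m <- collapse_replicates(sim$table)
    rq <- quantify_targets(m, "Wnt4", c("ref1", "ref2", "ref3"), "P14")
    s <- rq$Wnt4$summary
    rel_err[i, ] <- abs(s$mean[match(stages, s$group)] - planted) / planted
  }
  expect_lt(mean(rel_err), 0.15)
})

test_that("noisier reference sets degrade fold-change recovery monotonically", {
  planted <- 2^c(0, 0.5, 1, 1.5, 2)
  stages <- c("P14", "P28", "P35", "P42", "P56")
  mae <- vapply(c(0.1, 0.4, 0.8), function(ref_sd) {
    errs <- vapply(1:30, function(i) {
      sim <- wnt_sim(seed = 7000 + i, ref_sd = ref_sd)
      m <- collapse_replicates(sim$table)
      s <- quantify_targets(m, "Wnt4", c("ref1", "ref2", "ref3"),
                            "P14")$Wnt4$summary
      mean(abs(s$mean[match(stages, s$group)] - planted))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) >= 0))
})

test_that("stage comparison applies the F-test-then-t-test decision rule", {
  mk_result <- function(a, b) {
    x <- c(a, b)
    names(x) <- paste0("s", seq_along(x))
    structure(list(gene = "g", expression = x,
                   groups = stats::setNames(rep(c("A", "B"),
                                                c(length(a), length(b))),
                                            names(x)),
                   calibrator_group = "A"),
              class = "relquant_result")
  }
  same <- compare_stages(mk_result(c(1, 2, 3), c(1, 2, 3)), "A", "B")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$t_p, 1)

  # textbook pooled t: equal variances, t = 12.247 on 4 df
  cmp <- compare_stages(mk_result(c(1.0, 1.1, 0.9), c(2.0, 2.1, 1.9)),
                        "A", "B")
  expect_equal(cmp$variant, "student")
  expect_equal(abs(cmp$t_statistic), 12.24745, tolerance = 1e-5)
  expect_equal(cmp$df, 4)

  # independently coded pooled-t + t CDF oracle
  a <- c(1.0, 1.1, 0.9); b <- c(2.0, 2.1, 1.9)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1/3 + 1/3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-6)
  expect_equal(cmp$t_p, p_hand, tolerance = 1e-6)

  # 100x variance ratio at n = 10 switches to Welch
  set.seed(31)
  aa <- rnorm(10, 5, 1); bb <- rnorm(10, 5, 0.1)
  w <- compare_stages(mk_result(aa, bb), "A", "B")
  expect_equal(w$variant, "welch")

  expect_error(compare_stages(mk_result(1, c(1, 2)), "A", "B"),
               "at least 2")
})

test_that("consecutive-stage comparisons cover adjacent pairs with optional Holm", {
  set.seed(8)
  sim <- wnt_sim(seed = 8, ref_sd = 0.1)
  m <- collapse_replicates(sim$table)
  rq <- quantify_targets(m, "Wnt4", c("ref1", "ref2", "ref3"), "P14")
  cmp <- compare_consecutive_stages(rq$Wnt4)
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$group_a, c("P14", "P28", "P35", "P42"))
  expect_true(all(cmp$variant %in% c("student", "welch")))
  cmp_h <- compare_consecutive_stages(rq$Wnt4, adjust = "holm")
  expect_true(all(cmp_h$p_adj >= cmp_h$p))
})
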