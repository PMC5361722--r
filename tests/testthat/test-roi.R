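test_that("directed ranks order samples toward activation, with average-rank ties", {
  e <- tiny_expr(rbind(c(5, 1, 3), c(5, 1, 3), c(2, 2, 7)),
                 genes = c("up1", "dn1", "up2"))
  sig <- gene_signature("s", up = c("up1", "up2"), down = "dn1")
  r <- directed_ranks(e, sig, min_genes = 1)
  expect_equal(unname(r["up1", ]), c(3, 1, 2))
  expect_equal(unname(r["dn1", ]), c(1, 3, 2))   # negation reverses the order
  expect_equal(unname(r["up2", ]), c(1.5, 1.5, 3))
})

test_that("signatures with too few genes present are skipped with a classed error", {
  e <- random_expr(10, 6)
  sig <- gene_signature("sparse", up = c(rownames(e)[1:2], "absent1", "absent2"))
  err <- tryCatch(directed_ranks(e, sig, min_genes = 5), sigact_skip = identity)
  expect_s3_class(err, "sigact_skip")
  expect_equal(err$n_present, 2)
})

test_that("rank sums and the linear order match direct summation", {
  ranks <- rbind(c(1, 2, 3), c(1, 2, 3))
  colnames(ranks) <- paste0("s", 1:3)
  rs <- sigact:::rank_sum_order(ranks)
  expect_equal(unname(rs$rank_sums), c(2, 4, 6))
  expect_equal(rs$sample_order, paste0("s", 1:3))

  tied <- rbind(c(1, 2, 3), c(3, 2, 1))
  colnames(tied) <- c("sc", "sa", "sb")
  expect_equal(sigact:::rank_sum_order(tied)$sample_order, c("sa", "sb", "sc"))

  # 4-sample, 3-gene case against an independent per-entry summation
  e <- tiny_expr(rbind(c(2, 9, 4, 7), c(1, 3, 8, 5), c(6, 2, 9, 1)),
                 genes = c("gA", "gB", "gC"), samples = paste0("s", 1:4))
  sig <- gene_signature("h", up = c("gA", "gB"), down = "gC")
  r <- directed_ranks(e, sig, min_genes = 1)
  manual <- rank(e["gA", ]) + rank(e["gB", ]) + rank(-e["gC", ])
  expect_equal(sigact:::rank_sum_order(r)$rank_sums, manual)
})

test_that("null rank-sums follow the uniform {0..n+1} model per gene", {
  # k = 1, n = 6: uniform on {0..7}, mean 3.5
  x <- null_rank_sums(6, 1, n_trials = 10000, seed = 1)
  expect_true(all(x %in% 0:7))
  se <- sqrt((8^2 - 1) / 12) / sqrt(10000)
  expect_lt(abs(mean(x) - 3.5), 3 * se + 1e-9)
  # determinism under seed
  expect_identical(x, null_rank_sums(6, 1, n_trials = 10000, seed = 1))
  expect_false(identical(x, null_rank_sums(6, 1, n_trials = 10000, seed = 2)))
})

test_that("the exact null pmf matches exhaustive enumeration and the sampled null", {
  # enumeration oracle: all 8^2 outcomes for k = 2, n = 6
  grid <- expand.grid(a = 0:7, b = 0:7)
  oracle <- as.numeric(table(factor(grid$a + grid$b, levels = 0:14)) / 64)
  pmf <- roi_null_pmf(6, 2)
  expect_equal(unname(pmf), oracle, tolerance = 1e-10)
  # sampled histogram converges to the exact pmf
  x <- null_rank_sums(6, 2, n_trials = 50000, seed = 7)
  emp <- as.numeric(table(factor(x, levels = 0:14)) / 50000)
  expect_lt(max(abs(emp - oracle)), 0.01)
})

test_that("region bounds are attainable nearest-rank quantiles with guaranteed coverage", {
  expect_equal(unname(roi_region(rep(5, 100), 0.95)), c(5, 5))
  reg <- roi_region(1:100, 0.95)
  expect_gte(sum(1:100 >= reg[1] & 1:100 <= reg[2]), 95)
  # quantile nesting: the q = 0.5 region lies strictly inside q = 0.95
  reg50 <- roi_region(1:100, 0.5)
  expect_gt(reg50[["lower_sum"]], reg[["lower_sum"]])
  expect_lt(reg50[["upper_sum"]], reg[["upper_sum"]])
})

test_that("exact and sampled region bounds agree for enumerable cases", {
  for (n in c(3, 5)) for (k in c(1, 3)) {
    ex <- roi_region_exact(n, k, 0.95)
    sa <- roi_region(null_rank_sums(n, k, n_trials = 1e5, seed = n * 10 + k), 0.95)
    expect_lte(max(abs(ex - sa)), 1)   # within one attainable rank-sum step
  }
})

test_that("roi assigns each sample exactly one label consistent with the region", {
  sim <- simulate_cohort(n_samples = 80, n_genes = 40,
                         sig_specs = data.frame(k = 10, frac_low = 0.25,
                                                frac_high = 0.25, delta = 2,
                                                frac_down = 0.2), seed = 4)
  fit <- roi(sim$expr, sim$signatures[[1]], n_trials = 2000, seed = 4)
  expect_equal(length(fit$labels), 80)
  expect_false(anyNA(fit$labels))
  lo <- fit$region[["lower_sum"]]; hi <- fit$region[["upper_sum"]]
  expect_true(all((fit$labels == "low") == (fit$rank_sums < lo)))
  expect_true(all((fit$labels == "high") == (fit$rank_sums > hi)))
  # boundary-equal rank-sums (when present) are independent, not low/high
  on_bound <- fit$rank_sums == lo | fit$rank_sums == hi
  if (any(on_bound)) expect_true(all(fit$labels[on_bound] == "independent"))
  expect_lte(lo, hi)
})

test_that("roi recovers planted blocks at strong effect size", {
  sim <- simulate_cohort(n_samples = 100, n_genes = 60,
                         sig_specs = data.frame(k = 20, frac_low = 0.3,
                                                frac_high = 0.3, delta = 3,
                                                frac_down = 0.2), seed = 1)
  fit <- roi(sim$expr, sim$signatures[[1]], n_trials = 5000, seed = 1)
  truth <- sim$truth$sim_sig_01
  lowhigh <- truth %in% c("low", "high")
  expect_gte(mean(as.character(fit$labels)[lowhigh] == truth[lowhigh]), 0.9)
})

test_that("roi is invariant under strictly increasing per-gene transforms", {
  sim <- simulate_cohort(n_samples = 50, n_genes = 30,
                         sig_specs = data.frame(k = 8, frac_low = 0.3,
                                                frac_high = 0.3, delta = 2,
                                                frac_down = 0.25), seed = 9)
  sig <- sim$signatures[[1]]
  f1 <- roi(sim$expr, sig, n_trials = 2000, seed = 11)
  warped <- sim$expr
  set.seed(2)
  for (g in seq_len(nrow(warped))) {
    warped[g, ] <- switch(1 + g %% 3,
                          warped[g, ]^1.7,
                          3 * warped[g, ] + 1,
                          log1p(warped[g, ]))
  }
  f2 <- roi(warped, sig, n_trials = 2000, seed = 11)
  expect_identical(f1$rank_sums, f2$rank_sums)
  expect_identical(f1$labels, f2$labels)
})

test_that("swapping up and down gene sets swaps the low and high classes", {
  sim <- simulate_cohort(n_samples = 60, n_genes = 30,
                         sig_specs = data.frame(k = 10, frac_low = 0.3,
                                                frac_high = 0.3, delta = 2.5,
                                                frac_down = 0.3), seed = 14)
  sig <- sim$signatures[[1]]
  flipped <- gene_signature(sig$signature_id, up = sig$down, down = sig$up)
  f1 <- roi(sim$expr, sig, n_trials = 2000, seed = 15)
  f2 <- roi(sim$expr, flipped, n_trials = 2000, seed = 15)
  expect_identical(which(f1$labels == "low"), which(f2$labels == "high"))
  expect_identical(which(f1$labels == "high"), which(f2$labels == "low"))
  expect_identical(which(f1$labels == "independent"),
                   which(f2$labels == "independent"))
})

test_that("roi labels are cohort-level: adding samples can relabel others", {
  sim <- simulate_cohort(n_samples = 30, n_genes = 30,
                         sig_specs = data.frame(k = 10, frac_low = 0.2,
                                                frac_high = 0.2, delta = 1.5,
                                                frac_down = 0), seed = 21)
  sig <- sim$signatures[[1]]
  f1 <- roi(sim$expr, sig, n_trials = 5000, seed = 5)
  extra <- simulate_cohort(n_samples = 40, n_genes = 30,
                           sig_specs = data.frame(k = 10, frac_low = 0,
                                                  frac_high = 1, delta = 3,
                                                  frac_down = 0), seed = 22)
  colnames(extra$expr) <- paste0("x", seq_len(ncol(extra$expr)))
  f2 <- roi(cbind(sim$expr, extra$expr), sig, n_trials = 5000, seed = 5)
  expect_gt(sum(labels(f1) != labels(f2)[names(labels(f1))]), 0)
})

test_that("roi summary reports null coverage near q", {
  sim <- simulate_cohort(n_samples = 80, n_genes = 30,
                         sig_specs = data.frame(k = 15, frac_low = 0.3,
                                                frac_high = 0.3, delta = 2,
                                                frac_down = 0), seed = 31)
  s <- summary(roi(sim$expr, sim$signatures[[1]], n_trials = 10000, seed = 31))
  expect_gte(s$null_coverage, 0.95)
  expect_lt(s$null_coverage, 0.97)
  expect_equal(sum(s$class_fractions), 1)
})
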