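test_that("dataset-balanced weights equalize dataset influence", {
  w <- dataset_weights(rep(c("a", "b"), c(2, 8)))
  expect_equal(w, c(rep(1 / 4, 2), rep(1 / 16, 8)))   # 1/(D*n_d)
  expect_equal(sum(w[1:2]), 0.5)
  expect_equal(sum(w[3:10]), 0.5)
  expect_equal(sum(w), 1)
  # one dataset: plain 1/n; equal sizes: all equal
  expect_equal(dataset_weights(rep("x", 5)), rep(0.2, 5))
  expect_equal(unique(dataset_weights(rep(c("a", "b"), each = 4))), 0.125)
})

test_that("pair-rule scores match definitional extremes", {
  # gene A above gene B exactly in the 'high' samples
  y <- factor(rep(c("high", "low", "independent"), each = 4), levels = lv3)
  e <- tiny_expr(rbind(c(rep(5, 4), rep(1, 8)), rep(3, 12)),
                 genes = c("gA", "gB"), samples = sprintf("s%02d", 1:12))
  sc <- score_pair_rules(e, y)
  r <- sc[sc$gene_x == "gA" & sc$gene_y == "gB", ]
  expect_equal(r$score_high, 1)     # true for all high, false elsewhere
  expect_equal(r$score_low, -0.5)
  # uninformative rule scores zero: true with equal frequency in/out of class
  e2 <- tiny_expr(rbind(rep(c(5, 1), 6), rep(3, 12)), genes = c("gA", "gB"),
                  samples = sprintf("s%02d", 1:12))
  y2 <- factor(rep(c("high", "low", "independent"), 4), levels = lv3)
  sc2 <- score_pair_rules(e2, y2)
  r2 <- sc2[sc2$gene_x == "gA" & sc2$gene_y == "gB", ]
  expect_equal(r2$score_high, 0, tolerance = 1e-12)
})

test_that("pair-rule scores match a brute-force oracle with weights", {
  set.seed(20)
  e <- random_expr(6, 30, seed = 20)
  y <- factor(sample(lv3, 30, TRUE), levels = lv3)
  w <- dataset_weights(rep(c("d1", "d2"), c(12, 18)))
  sc <- score_pair_rules(e, y, w)
  # independent double loop over ordered pairs and classes
  for (i in sample(nrow(sc), 10)) {
    gx <- sc$gene_x[i]; gy <- sc$gene_y[i]
    truth <- e[gx, ] > e[gy, ]
    for (cl in lv3) {
      inc <- y == cl
      expected <- sum(w[inc & truth]) / sum(w[inc]) -
        sum(w[!inc & truth]) / sum(w[!inc])
      expect_equal(sc[[paste0("score_", cl)]][i], expected, tolerance = 1e-12)
    }
  }
})

test_that("rule scores see only within-sample orderings", {
  e <- random_expr(5, 20, seed = 21)
  y <- factor(sample(lv3, 20, TRUE), levels = lv3)
  sc1 <- score_pair_rules(e, y)
  # per-sample monotone distortion: scale and power each profile
  e2 <- sweep(e^1.3, 2, runif(20, 0.5, 2), `*`)
  sc2 <- score_pair_rules(e2, y)
  expect_equal(sc1, sc2, tolerance = 1e-12)
})

test_that("dataset balance makes scores invariant to replicating a dataset's samples", {
  # doubling every sample of one dataset doubles its size but halves its
  # per-sample weight, so pooled weighted rule frequencies are unchanged
  e <- random_expr(5, 16, seed = 22)
  y <- factor(rep(c("low", "independent", "high", "independent"), 4), levels = lv3)
  ds <- rep(c("d1", "d2"), each = 8)
  sc1 <- score_pair_rules(e, y, dataset_weights(ds))
  e2 <- cbind(e, `colnames<-`(e[, 9:16], paste0("dup", 1:8)))
  y2 <- factor(c(as.character(y), as.character(y[9:16])), levels = lv3)
  ds2 <- c(ds, rep("d2", 8))
  sc2 <- score_pair_rules(e2, y2, dataset_weights(ds2))
  expect_equal(sc1, sc2, tolerance = 1e-12)
})

test_that("naive Bayes tables use Laplace-smoothed effective counts", {
  # one rule: true for all 10 high, false for 10 low and 10 independent
  truth <- matrix(rep(c(1, 0, 0), each = 10), nrow = 1)
  y <- factor(rep(c("high", "low", "independent"), each = 10), levels = lv3)
  nb <- fit_rule_nb(truth, y)
  expect_equal(unname(nb$cond_prob[1, "high"]), 11 / 12)
  expect_equal(unname(nb$cond_prob[1, "low"]), 1 / 12)
  expect_equal(unname(nb$cond_prob[1, "independent"]), 1 / 12)
  expect_equal(unname(nb$priors), rep(1 / 3, 3))
  # a class with zero weight is an error
  y2 <- factor(rep(c("high", "low"), 15), levels = lv3)
  expect_error(fit_rule_nb(truth, y2), "zero weight")
})

test_that("an uninformative model returns the priors for any profile", {
  cond <- matrix(0.5, 2, 3, dimnames = list(NULL, lv3))
  m <- toy_model(cond = cond, priors = c(low = 0.2, independent = 0.5, high = 0.3))
  pred <- predict(m, c(gA = 5, gB = 1, gC = 2, gD = 9))
  expect_equal(pred$p_low, 0.2)
  expect_equal(pred$p_independent, 0.5)
  expect_equal(pred$p_high, 0.3)
})

test_that("cross-validation picks the smallest K when extra rules add nothing", {
  # all predictive signal lives in the (g1, g2) comparison; g3/g4 are a huge
  # constant so every rule touching them has constant truth value; classes are
  # balanced so constant rules cannot tilt the posteriors
  n <- 30
  y <- factor(rep(lv3, each = 10), levels = lv3)
  g1 <- ifelse(y == "high", 5, 1)
  e <- tiny_expr(rbind(g1, rep(3, n), rep(1e6, n), rep(1e6, n)),
                 genes = paste0("g", 1:4), samples = sprintf("s%02d", 1:n))
  fold <- rep(1:5, 6)
  W <- sigact:::class_weight_matrix(y, rep(1 / n, n))
  for (f in 1:5) { Wf <- W[, 1:3]; Wf[fold == f, ] <- 0; W <- cbind(W, Wf) }
  ptm <- sigact:::pair_true_mass(e, W)
  attr(ptm, "tw") <- colSums(W)
  ksel <- sigact:::select_rule_count(ptm, e, y, rep(1 / n, n), fold,
                                     k_grid = c(1, 5, 25), smooth = 1)
  expect_equal(ksel$K, 1)
})

test_that("cross-validated kappa is near zero for pure-noise labels", {
  set.seed(30)
  e <- random_expr(8, 60, seed = 30)
  y <- factor(sample(lv3, 60, TRUE, prob = c(0.3, 0.4, 0.3)), levels = lv3)
  fold <- sigact:::assign_folds(y, rep("d1", 60), 5, seed = 31)
  w <- rep(1 / 60, 60)
  W <- sigact:::class_weight_matrix(y, w)
  for (f in seq_len(max(fold))) {
    Wf <- W[, 1:3]; Wf[fold == f, ] <- 0; W <- cbind(W, Wf)
  }
  ptm <- sigact:::pair_true_mass(e, W)
  attr(ptm, "tw") <- colSums(W)
  ksel <- sigact:::select_rule_count(ptm, e, y, w, fold,
                                     k_grid = c(1, 5, 15), smooth = 1)
  expect_lt(max(ksel$cv$cv_kappa), 0.2)
})

test_that("the gold standard reduces to roi per dataset and tolerates absent signatures", {
  sim <- simulate_cohort(n_samples = 60, n_genes = 40,
                         sig_specs = data.frame(k = 10, frac_low = 0.3,
                                                frac_high = 0.3, delta = 3,
                                                frac_down = 0.2), seed = 41)
  sig <- sim$signatures[[1]]
  gs <- build_gold_standard(list(only = sim$expr), list(sig),
                            n_trials = 2000, seed = 42)
  direct <- roi(sim$expr, sig, n_trials = 2000,
                seed = sigact:::sig_seed(42, "only::sim_sig_01"))
  ent <- gs$entries
  expect_equal(ent$label[match(names(direct$labels), ent$sample_id)],
               as.character(direct$labels))
  # a dataset lacking the signature genes is skipped, the run continues
  blank <- random_expr(10, 30, seed = 43)
  rownames(blank) <- paste0("other", 1:10)
  gs2 <- build_gold_standard(list(a = sim$expr, b = blank), list(sig),
                             n_trials = 1000, seed = 44)
  expect_equal(unique(gs2$entries$dataset_id), "a")
  expect_equal(gs2$skipped$dataset_id, "b")
  expect_equal(gs2$skipped$reason, "too_few_genes")
})

test_that("gold-standard labels match planted truth across datasets at strong effect", {
  sims <- simulate_multidataset(n_datasets = 2, n_samples = c(80, 80),
                                n_genes = 60,
                                sig_specs = data.frame(k = 15, frac_low = 0.3,
                                                       frac_high = 0.3,
                                                       delta = 3,
                                                       frac_down = 0.2),
                                seed = 45)
  gs <- build_gold_standard(lapply(sims$datasets, `[[`, "expr"),
                            sims$signatures, n_trials = 2000, seed = 46)
  for (d in names(sims$datasets)) {
    truth <- sims$datasets[[d]]$truth
    ent <- gs$entries[gs$entries$dataset_id == d, ]
    planted <- truth$sim_sig_01[match(ent$sample_id, truth$sample_id)]
    lowhigh <- planted %in% c("low", "high")
    expect_gte(mean(ent$label[lowhigh] == planted[lowhigh]), 0.9)
  }
})

test_that("trained models serialize and reload with identical predictions", {
  fx <- trained_fixture(seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_models(fx$fit, path)
  back <- read_models(path)[[fx$model$signature_id]]
  profiles <- random_expr(50, 100, seed = 47)
  rownames(profiles) <- rownames(fx$exprs[[1]])
  p1 <- predict(fx$model, profiles)
  p2 <- predict(back, profiles)
  expect_identical(as.character(p1$label), as.character(p2$label))
  expect_equal(p1$p_high, p2$p_high, tolerance = 1e-12)
  expect_equal(p1$p_low, p2$p_low, tolerance = 1e-12)
})

test_that("the trainer retains planted models and excludes uninformative signatures", {
  sims <- simulate_multidataset(n_datasets = 2, n_samples = c(100, 100),
                                n_genes = 60,
                                sig_specs = data.frame(k = c(12, 12),
                                                       frac_low = 0.3,
                                                       frac_high = 0.3,
                                                       delta = c(3, 0),
                                                       frac_down = 0.2),
                                seed = 7)
  exprs <- lapply(sims$datasets, `[[`, "expr")
  fit <- suppressWarnings(sigact(exprs, sims$signatures, n_trials = 2000,
                                 k_grid = c(1, 3, 5, 10), folds = 5, seed = 7))
  smry <- summary(fit)
  expect_true(smry$retained[smry$signature_id == "sim_sig_01"])
  expect_gt(smry$min_kappa[smry$signature_id == "sim_sig_01"], 0.5)
  # the flat (delta = 0) signature never reaches training
  expect_true("sim_sig_02" %in% fit$excluded$signature_id)
  # Bonferroni family size is the candidate-model count
  expect_equal(fit$n_tests, length(fit$models))
})
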