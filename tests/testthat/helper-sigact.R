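# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except through the package's own readers on temp files.

lv3 <- c("low", "independent", "high")

# small deterministic expression matrix
tiny_expr <- function(values, genes = NULL, samples = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(genes))
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# random raw-intensity-like matrix
random_expr <- function(n_genes, n_samples, seed = 1, log_mean = 6, sd = 1) {
  set.seed(seed)
  m <- exp(matrix(rnorm(n_genes * n_samples, log_mean, sd), n_genes, n_samples))
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%04d", seq_len(n_samples)))
  m
}

# a minimal hand-built absolute model over genes gA..gD
toy_model <- function(cond = NULL, priors = c(low = 0.25, independent = 0.5,
                                              high = 0.25)) {
  rules <- data.frame(gene_x = c("gA", "gC"), gene_y = c("gB", "gD"),
                      target_class = c("high", "low"),
                      stringsAsFactors = FALSE)
  if (is.null(cond))
    cond <- matrix(c(0.1, 0.8, 0.3, 0.7, 0.2, 0.1), nrow = 2,
                   dimnames = list(NULL, lv3))
  sigact_model("toy", rules, cond, priors)
}

# quickly trained real model on a small planted cohort (shared by several
# test files; cheap enough to rebuild per call)
trained_fixture <- function(seed = 3) {
  sims <- simulate_multidataset(n_datasets = 2, n_samples = c(80, 80),
                                n_genes = 50,
                                sig_specs = data.frame(k = 10, frac_low = 0.3,
                                                       frac_high = 0.3,
                                                       delta = 3,
                                                       frac_down = 0.2),
                                seed = seed)
  exprs <- lapply(sims$datasets, `[[`, "expr")
  fit <- suppressWarnings(sigact(exprs, sims$signatures, n_trials = 1000,
                                 k_grid = c(1, 3, 5), folds = 5, seed = seed,
                                 apply_winnow = FALSE))
  list(fit = fit, model = fit$models[[1]], exprs = exprs, sims = sims)
}
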