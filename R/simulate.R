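#' Simulate an expression cohort with planted activation structure
#'
#' Generates the structure the region-of-independence procedure assumes: for
#' each planted signature the cohort splits into a high block (signature
#' genes coherently elevated), a low block (coherently depressed) and an
#' independent block (signature genes lose their pairwise correlation).
#' Background expression is log-normal-like: Gaussian on the log scale
#' (mean \code{log_mean}, sd \code{noise_sd}), exponentiated, so values
#' resemble raw non-negative intensities. Effects are applied on the log
#' scale in units of \code{noise_sd}: high-block samples gain
#' \code{+delta * noise_sd} on up genes and \code{-delta * noise_sd} on down
#' genes, low-block samples the mirror image. Independent-block samples
#' receive a per-(gene, sample) shift of magnitude \code{delta * noise_sd}
#' with independent random sign, so each signature gene still varies but the
#' genes are mutually uncorrelated.
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes; signature genes are assigned disjoint
#'   blocks, remaining genes are pure background.
#' @param sig_specs data.frame with one row per planted signature and columns
#'   \code{k} (signature size), \code{frac_low}, \code{frac_high} (block
#'   fractions; the rest is independent), \code{delta} (effect size in sd
#'   units, >= 0) and \code{frac_down} (fraction of down-directed genes).
#' @param noise_sd Log-scale background sd.
#' @param log_mean Log-scale background mean.
#' @param independent_jitter Apply the uncorrelated jitter to the independent
#'   block (default TRUE).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @return A list of class \code{sim_cohort}: \code{expr} (genes x samples,
#'   non-negative), \code{truth} (data.frame sample_id x one label column per
#'   signature), \code{signatures} (list of \code{\link{gene_signature}}),
#'   and \code{config}.
#' @export
simulate_cohort <- function(n_samples = 500L, n_genes = 1000L,
                            sig_specs = data.frame(k = 50, frac_low = 0.3,
                                                   frac_high = 0.3, delta = 3,
                                                   frac_down = 0.2),
                            noise_sd = 1, log_mean = 6,
                            independent_jitter = TRUE, seed = NULL) {
  check_sig_specs(sig_specs)
  if (sum(sig_specs$k) > n_genes)
    stop("simulate_cohort: signature genes (", sum(sig_specs$k),
         ") exceed n_genes (", n_genes, ")")
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    samples <- sprintf("s%04d", seq_len(n_samples))
    L <- matrix(stats::rnorm(n_genes * n_samples, log_mean, noise_sd),
                n_genes, n_samples, dimnames = list(genes, samples))
    assign <- assign_signature_genes(genes, sig_specs)
    planted <- plant_signatures(L, assign, sig_specs, n_samples, noise_sd,
                                independent_jitter)
    truth <- data.frame(sample_id = samples, planted$labels,
                        stringsAsFactors = FALSE, check.names = FALSE)
    structure(list(expr = exp(planted$L), truth = truth,
                   signatures = assign$signatures,
                   config = list(n_samples = n_samples, n_genes = n_genes,
                                 sig_specs = sig_specs, noise_sd = noise_sd,
                                 log_mean = log_mean,
                                 independent_jitter = independent_jitter,
                                 seed = seed)),
              class = "sim_cohort")
  })
}

check_sig_specs <- function(sig_specs) {
  need <- c("k", "frac_low", "frac_high", "delta", "frac_down")
  if (!all(need %in% names(sig_specs)))
    stop("sig_specs needs columns: ", paste(need, collapse = ", "))
  with(sig_specs, {
    if (any(k < 1)) stop("sig_specs: k must be >= 1")
    if (any(delta < 0)) stop("sig_specs: delta must be >= 0")
    if (any(frac_low < 0 | frac_high < 0 | frac_down < 0 |
            frac_low > 1 | frac_high > 1 | frac_down > 1))
      stop("sig_specs: fractions must lie in [0, 1]")
    if (any(frac_low + frac_high > 1))
      stop("sig_specs: frac_low + frac_high must be <= 1")
  })
  invisible(sig_specs)
}

# Disjoint gene blocks + directions for the planted signatures. Consumes RNG
# only for direction choice, so callers can share an assignment across
# datasets by calling it under a common seed.
assign_signature_genes <- function(genes, sig_specs) {
  sigs <- list(); blocks <- list(); downs <- list()
  off <- 0L
  for (i in seq_len(nrow(sig_specs))) {
    k <- sig_specs$k[i]
    id <- sprintf("sim_sig_%02d", i)
    block <- genes[off + seq_len(k)]
    off <- off + k
    n_down <- round(sig_specs$frac_down[i] * k)
    down <- if (n_down > 0L) sample(block, n_down) else character()
    up <- setdiff(block, down)
    sigs[[id]] <- gene_signature(id, up = up, down = down, source = "simulated")
    blocks[[id]] <- block; downs[[id]] <- down
  }
  list(signatures = sigs, blocks = blocks, downs = downs)
}

# Apply the planted block effects to the log-scale matrix.
plant_signatures <- function(L, assign, sig_specs, n_samples, noise_sd,
                             independent_jitter) {
  labels <- list()
  for (i in seq_len(nrow(sig_specs))) {
    id <- names(assign$signatures)[i]
    sig <- assign$signatures[[id]]
    delta <- sig_specs$delta[i]
    n_low <- round(sig_specs$frac_low[i] * n_samples)
    n_high <- round(sig_specs$frac_high[i] * n_samples)
    lab <- rep("independent", n_samples)
    pick <- sample.int(n_samples, n_low + n_high)
    lab[pick[seq_len(n_low)]] <- "low"
    if (n_high > 0L) lab[pick[n_low + seq_len(n_high)]] <- "high"
    if (delta > 0) {
      shift <- delta * noise_sd
      dirs <- ifelse(rownames(L)[match(signature_genes(sig), rownames(L))]
                     %in% sig$down, -1, 1)
      gsel <- match(signature_genes(sig), rownames(L))
      hi <- lab == "high"; lo <- lab == "low"; ind <- lab == "independent"
      if (any(hi)) L[gsel, hi] <- L[gsel, hi] + shift * dirs
      if (any(lo)) L[gsel, lo] <- L[gsel, lo] - shift * dirs
      if (independent_jitter && any(ind)) {
        eps <- matrix(sample(c(-1, 1), length(gsel) * sum(ind), replace = TRUE),
                      length(gsel), sum(ind))
        L[gsel, ind] <- L[gsel, ind] + shift * eps
      }
    }
    labels[[id]] <- lab
  }
  list(L = L, labels = as.data.frame(labels, stringsAsFactors = FALSE))
}

#' Simulate multiple datasets sharing gene universe and signature truth
#'
#' Emulates a multi-cohort training design: all datasets share the gene
#' universe and the planted signatures (same gene blocks and directions), but
#' each dataset draws its own samples, may skew its class fractions
#' (composition imbalance across cohorts) and receives its own monotone
#' platform distortion -- a global power transform expr^a * exp(b) on the raw
#' scale, which preserves both per-gene sample ranks and within-sample gene
#' orderings.
#'
#' @param n_datasets Number of datasets (>= 1).
#' @param n_samples Integer vector of per-dataset sizes (recycled).
#' @param n_genes,sig_specs,noise_sd,log_mean,independent_jitter As in
#'   \code{\link{simulate_cohort}}.
#' @param class_skew Optional list (length \code{n_datasets}) of data.frames
#'   overriding \code{frac_low}/\code{frac_high} per signature per dataset.
#' @param distort Apply per-dataset monotone distortions (default TRUE).
#' @param seed Integer seed.
#' @return List with \code{datasets} (named list of \code{sim_cohort}) and
#'   \code{signatures} (the shared planted signatures).
#' @export
simulate_multidataset <- function(n_datasets = 3L, n_samples = 200L,
                                  n_genes = 1000L,
                                  sig_specs = data.frame(k = 50, frac_low = 0.3,
                                                         frac_high = 0.3,
                                                         delta = 3,
                                                         frac_down = 0.2),
                                  noise_sd = 1, log_mean = 6,
                                  independent_jitter = TRUE,
                                  class_skew = NULL, distort = TRUE,
                                  seed = NULL) {
  stopifnot(n_datasets >= 1L)
  n_samples <- rep_len(n_samples, n_datasets)
  check_sig_specs(sig_specs)
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    assign <- assign_signature_genes(genes, sig_specs)
    datasets <- list()
    for (d in seq_len(n_datasets)) {
      spec_d <- sig_specs
      if (!is.null(class_skew) && !is.null(class_skew[[d]])) {
        ov <- class_skew[[d]]
        for (cn in intersect(c("frac_low", "frac_high"), names(ov)))
          spec_d[[cn]] <- rep_len(ov[[cn]], nrow(spec_d))
        check_sig_specs(spec_d)
      }
      nd <- n_samples[d]
      samples <- sprintf("d%d_s%04d", d, seq_len(nd))
      L <- matrix(stats::rnorm(n_genes * nd, log_mean, noise_sd),
                  n_genes, nd, dimnames = list(genes, samples))
      planted <- plant_signatures(L, assign, spec_d, nd, noise_sd,
                                  independent_jitter)
      Lp <- planted$L
      if (distort) {
        a <- stats::runif(1, 0.8, 1.25)   # raw-scale power exponent
        b <- stats::runif(1, -1, 1)       # log of the raw-scale factor
        Lp <- b + a * Lp                  # exp() => exp(b) * expr^a
      }
      truth <- data.frame(sample_id = samples, planted$labels,
                          stringsAsFactors = FALSE, check.names = FALSE)
      datasets[[paste0("dataset", d)]] <-
        structure(list(expr = exp(Lp), truth = truth,
                       signatures = assign$signatures,
                       config = list(n_samples = nd, n_genes = n_genes,
                                     sig_specs = spec_d, noise_sd = noise_sd,
                                     log_mean = log_mean, distorted = distort,
                                     seed = seed)),
                  class = "sim_cohort")
    }
    list(datasets = datasets, signatures = assign$signatures)
  })
}

#' Render one cohort on two synthetic "platforms"
#'
#' Produces two renderings of the same underlying samples, mimicking the same
#' RNA measured on two technologies: each platform applies its own global
#' monotone power transform a * expr^b (profile-wide, so at zero noise
#' within-sample gene orderings -- and hence absolute predictions -- are
#' preserved exactly), plus independent per-cell log-normal measurement noise
#' whose sd controls how far the platforms disagree.
#'
#' @param expr Base expression matrix (raw non-negative values).
#' @param power_range,scale_range Ranges for the per-platform transform
#'   parameters b and a.
#' @param noise_sd Log-scale sd of the per-cell noise (0 = none).
#' @param seed Integer seed.
#' @return List with matrices \code{platform_a} and \code{platform_b}.
#' @export
simulate_platform_pair <- function(expr, power_range = c(0.7, 1.4),
                                   scale_range = c(0.5, 2), noise_sd = 0,
                                   seed = NULL) {
  with_seed(seed, {
    render <- function() {
      b <- stats::runif(1, power_range[1], power_range[2])
      a <- stats::runif(1, scale_range[1], scale_range[2])
      out <- a * expr^b
      if (noise_sd > 0)
        out <- out * exp(matrix(stats::rnorm(length(expr), 0, noise_sd),
                                nrow(expr), ncol(expr)))
      out
    }
    list(platform_a = render(), platform_b = render())
  })
}
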