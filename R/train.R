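#' Dataset-balanced sample weights
#'
#' Training pools samples from several datasets of very different sizes. To
#' give every dataset equal influence, the weight of a sample from dataset d
#' is 1 / (D * n_d), with D the number of datasets and n_d the size of d:
#' each dataset's weights sum to 1/D and the total weight is 1.
#'
#' @param dataset_ids Character vector giving each sample's dataset.
#' @return Numeric weight per sample (same order as the input).
#' @export
dataset_weights <- function(dataset_ids) {
  dataset_ids <- as.character(dataset_ids)
  tab <- table(dataset_ids)
  if (any(tab == 0L)) stop("dataset_weights: empty dataset")
  D <- length(tab)
  as.numeric(1 / (D * tab[dataset_ids]))
}

#' Build the ROI gold standard over multiple datasets
#'
#' Applies the region-of-independence partition (\code{\link{roi}}) to every
#' signature on every individual dataset -- never on a merged matrix, since
#' cross-platform scales make a pooled ranking meaningless -- and attaches
#' dataset-balanced weights. The resulting labels are the training targets
#' ("gold standard") for the absolute single-sample models.
#'
#' @param datasets Named list of gene-level expression matrices.
#' @param signatures List of \code{\link{gene_signature}} objects.
#' @param q,n_trials,min_genes,draw Passed to \code{\link{roi}}.
#' @param seed Integer seed; an independent stream is derived per
#'   (dataset, signature) pair.
#' @return An object of class \code{gold_standard}: \code{entries} (data.frame
#'   with dataset_id, sample_id, signature_id, label), \code{weights}
#'   (data.frame with dataset_id, sample_id, weight), and \code{skipped}
#'   (dataset/signature pairs omitted because too few signature genes were
#'   present in that dataset).
#' @export
build_gold_standard <- function(datasets, signatures, q = 0.95,
                                n_trials = 10000L, min_genes = 5L,
                                seed = NULL, draw = "integer") {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("d", seq_along(datasets))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)

  entries <- list(); skipped <- list()
  for (d in names(datasets)) {
    for (sig in signatures) {
      s <- if (is.null(seed)) NULL else sig_seed(seed, paste0(d, "::", sig$signature_id))
      fit <- tryCatch(roi(datasets[[d]], sig, q = q, n_trials = n_trials,
                          seed = s, min_genes = min_genes, draw = draw),
                      sigact_skip = function(e) e)
      if (inherits(fit, "sigact_skip")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(dataset_id = d, signature_id = sig$signature_id,
                     reason = "too_few_genes", stringsAsFactors = FALSE)
        next
      }
      entries[[length(entries) + 1L]] <-
        data.frame(dataset_id = d, sample_id = names(fit$labels),
                   signature_id = sig$signature_id,
                   label = as.character(fit$labels), stringsAsFactors = FALSE)
    }
  }
  if (length(entries) == 0L) stop("build_gold_standard: no (dataset, signature) pair could be labelled")
  ds_of_sample <- unlist(lapply(names(datasets), function(d)
    stats::setNames(rep(d, ncol(datasets[[d]])), colnames(datasets[[d]]))))
  weights <- data.frame(dataset_id = as.character(ds_of_sample),
                        sample_id = names(ds_of_sample),
                        weight = dataset_weights(as.character(ds_of_sample)),
                        stringsAsFactors = FALSE)
  structure(list(entries = do.call(rbind, entries), weights = weights,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else data.frame(dataset_id = character(),
                                           signature_id = character(),
                                           reason = character())),
            class = "gold_standard")
}

# ---- pair-rule machinery ----------------------------------------------------

# Weighted "rule true" mass for every ordered gene pair (x, y), x != y, under
# one or more weight columns. Row r of mass corresponds to pair (xi[r], yi[r])
# and holds sum_i W[i, j] * [expr(x, i) > expr(y, i)] for each column j.
pair_true_mass <- function(E, W) {
  G <- nrow(E); S <- ncol(E)
  if (G < 2L) stop("pair rules need a gene universe of at least 2 genes")
  stopifnot(nrow(W) == S)
  xi <- rep(seq_len(G), each = G - 1L)
  yi <- unlist(lapply(seq_len(G), function(x) seq_len(G)[-x]), use.names = FALSE)
  mass <- matrix(0, G * (G - 1L), ncol(W))
  off <- 0L
  for (x in seq_len(G)) {
    Tx <- (matrix(E[x, ], G, S, byrow = TRUE) > E)[-x, , drop = FALSE]
    mass[off + seq_len(G - 1L), ] <- Tx %*% W
    off <- off + G - 1L
  }
  list(xi = xi, yi = yi, mass = mass)
}

# In-class minus out-of-class weighted frequency of "rule true", per class.
# mass3: npairs x 3 true-mass, tw: total weight per class.
mass_to_scores <- function(mass3, tw) {
  tot_true <- rowSums(mass3)
  tot_w <- sum(tw)
  out <- matrix(NA_real_, nrow(mass3), length(tw),
                dimnames = list(NULL, names(tw)))
  for (j in seq_along(tw)) {
    p_in <- mass3[, j] / tw[j]
    p_out <- (tot_true - mass3[, j]) / (tot_w - tw[j])
    out[, j] <- p_in - p_out
  }
  out
}

#' Score all ordered gene-pair rules against class labels
#'
#' For every ordered pair of genes (x, y) and every activation class c, the
#' rule "expr(x) > expr(y) within a sample" is scored by its weighted
#' in-class vs out-of-class frequency difference:
#' score(r, c) = W(r true | c) - W(r true | not c), with W the
#' (dataset-balanced) weighted frequency over the gold standard. Both rule
#' orientations are covered because (x, y) and (y, x) are distinct ordered
#' pairs. Scores depend only on within-sample gene orderings, so they are
#' invariant under any per-sample monotone transform of expression.
#'
#' @param expr Expression matrix over the shared gene universe (genes x
#'   samples).
#' @param labels Activation labels per sample (low/independent/high).
#' @param weights Optional per-sample weights (default: equal).
#' @return A data.frame with one row per ordered pair: \code{gene_x},
#'   \code{gene_y}, and \code{score_low}, \code{score_independent},
#'   \code{score_high}.
#' @export
score_pair_rules <- function(expr, labels, weights = NULL) {
  y <- as_activation_factor(labels)
  stopifnot(ncol(expr) == length(y), !anyNA(y))
  if (is.null(weights)) weights <- rep(1 / ncol(expr), ncol(expr))
  W <- class_weight_matrix(y, weights)
  ptm <- pair_true_mass(expr, W)
  sc <- mass_to_scores(ptm$mass, colSums(W))
  out <- data.frame(gene_x = rownames(expr)[ptm$xi],
                    gene_y = rownames(expr)[ptm$yi], stringsAsFactors = FALSE)
  for (lv in activation_levels()) out[[paste0("score_", lv)]] <- sc[, lv]
  out
}

# n x 3 matrix spreading per-sample weights over the activation classes.
class_weight_matrix <- function(y, w) {
  lv <- activation_levels()
  W <- matrix(0, length(y), length(lv), dimnames = list(NULL, lv))
  for (j in seq_along(lv)) W[y == lv[j], j] <- w[y == lv[j]]
  W
}

# Interleave per-class rule rankings (high, low, independent, repeating) into
# one deduplicated top-k list, so every class contributes rules. Returns
# indices into the pair list plus the class each rule was selected for.
interleave_rules <- function(scores3, k_max,
                             class_order = c("high", "low", "independent")) {
  npairs <- nrow(scores3)
  ords <- lapply(class_order, function(cl)
    order(-scores3[, cl], seq_len(npairs), method = "radix"))
  sel <- integer(0); sel_class <- character(0)
  seen <- logical(npairs)
  pos <- 1L
  while (length(sel) < k_max && pos <= npairs) {
    for (j in seq_along(class_order)) {
      i <- ords[[j]][pos]
      if (!seen[i]) {
        seen[i] <- TRUE
        sel <- c(sel, i); sel_class <- c(sel_class, class_order[j])
        if (length(sel) >= k_max) break
      }
    }
    pos <- pos + 1L
  }
  list(idx = sel, target_class = sel_class)
}

# Truth matrix (rules x samples) for selected pairs.
rule_truth <- function(E, xi, yi) {
  T <- E[xi, , drop = FALSE] > E[yi, , drop = FALSE]
  storage.mode(T) <- "double"
  T
}

#' Fit the naive Bayes combination of binary gene-pair rules
#'
#' Each rule is a binary feature of a single profile. Conditionally on the
#' activation class the rules are treated as independent, and each
#' conditional probability is a smoothed weighted frequency:
#' P(rule true | c) = (m_rc + a) / (n_c + 2a), where m_rc and n_c are the
#' weighted counts rescaled to an effective sample size of n (so that with
#' equal weights they are plain counts) and a is the Laplace smoothing
#' constant (default 1). Priors are the weighted class frequencies.
#'
#' @param truth Rules x samples matrix (logical or 0/1) of rule outcomes.
#' @param labels Activation labels per sample.
#' @param weights Optional per-sample weights (default equal).
#' @param smooth Laplace smoothing constant a.
#' @return List with \code{cond_prob} (rules x 3 matrix of P(true | class))
#'   and \code{priors} (length-3 named vector). Errors if any class carries
#'   zero weight: the gold standard must contain all three classes.
#' @export
fit_rule_nb <- function(truth, labels, weights = NULL, smooth = 1) {
  truth <- as.matrix(truth)
  y <- as_activation_factor(labels)
  n <- length(y)
  stopifnot(ncol(truth) == n)
  if (is.null(weights)) weights <- rep(1, n)
  effn <- weights * n / sum(weights)
  lv <- activation_levels()
  eff_c <- vapply(lv, function(cl) sum(effn[y == cl]), 0)
  if (any(eff_c <= 0))
    stop("fit_rule_nb: class(es) with zero weight: ",
         paste(lv[eff_c <= 0], collapse = ", "),
         " (training labels must contain all three classes)")
  cond <- vapply(lv, function(cl) {
    m <- as.numeric(truth[, y == cl, drop = FALSE] %*% effn[y == cl])
    (m + smooth) / (eff_c[cl] + 2 * smooth)
  }, numeric(nrow(truth)))
  cond <- matrix(cond, nrow = nrow(truth), dimnames = list(NULL, lv))
  priors <- eff_c / sum(eff_c)
  list(cond_prob = cond, priors = priors)
}

# Posterior matrix (samples x 3) from a truth matrix, in log space.
nb_posterior <- function(truth, cond_prob, priors) {
  lv <- colnames(cond_prob)
  lp <- vapply(lv, function(cl) {
    lpr <- log(cond_prob[, cl]); lpf <- log1p(-cond_prob[, cl])
    log(priors[[cl]]) + as.numeric(crossprod(truth, lpr - lpf)) + sum(lpf)
  }, numeric(ncol(truth)))
  lp <- matrix(lp, ncol = length(lv), dimnames = list(colnames(truth), lv))
  post <- exp(lp - apply(lp, 1L, logsumexp))
  post / rowSums(post)
}

# argmax with ties resolved to "independent"
posterior_label <- function(post) {
  lv <- colnames(post)
  lab <- apply(post, 1L, function(p) {
    top <- which(p >= max(p) - 0)
    if (length(top) > 1L) "independent" else lv[top]
  })
  as_activation_factor(lab)
}

# Stratified fold assignment by (dataset, class); folds reduced with a
# warning if the rarest class has fewer members than requested folds.
assign_folds <- function(y, ds, folds, seed = NULL) {
  min_class <- min(table(y))
  folds_eff <- min(folds, min_class)
  if (folds_eff < folds)
    warning("cross-validation folds reduced to ", folds_eff,
            " (rarest class has ", min_class, " samples)")
  if (folds_eff < 2L) return(NULL)
  fold <- integer(length(y))
  with_seed(seed, {
    for (s in split(seq_along(y), list(ds, y), drop = TRUE)) {
      s <- s[sample.int(length(s))]
      fold[s] <- rep_len(seq_len(folds_eff), length(s))
    }
  })
  fold
}

# Cross-validated choice of the rule count K, re-ranking rules within each
# training fold. Returns K (smallest argmax of mean held-out weighted kappa)
# and the CV table.
select_rule_count <- function(ptm, E, y, w, fold, k_grid, smooth) {
  folds_eff <- max(fold)
  k_grid <- sort(unique(pmin(k_grid, nrow(ptm$mass))))
  k_max <- max(k_grid)
  cv <- matrix(NA_real_, length(k_grid), folds_eff,
               dimnames = list(as.character(k_grid), NULL))
  for (f in seq_len(folds_eff)) {
    cols <- 3L * f + (1:3)  # fold-f training-weight columns in the mass matrix
    tw <- attr(ptm, "tw")[cols]
    names(tw) <- activation_levels()
    sc <- mass_to_scores(ptm$mass[, cols, drop = FALSE], tw)
    colnames(sc) <- activation_levels()
    rk <- interleave_rules(sc, k_max)
    Tsel <- rule_truth(E, ptm$xi[rk$idx], ptm$yi[rk$idx])
    tr <- fold != f; te <- !tr
    for (gi in seq_along(k_grid)) {
      K <- k_grid[gi]
      nb <- fit_rule_nb(Tsel[seq_len(K), tr, drop = FALSE], y[tr], w[tr], smooth)
      post <- nb_posterior(Tsel[seq_len(K), te, drop = FALSE], nb$cond_prob, nb$priors)
      cv[gi, f] <- weighted_kappa(posterior_label(post), y[te], w[te])
    }
  }
  means <- rowMeans(cv, na.rm = TRUE)
  best <- max(means, na.rm = TRUE)
  K <- k_grid[which(means >= best - 1e-12)[1L]]
  list(K = K, cv = data.frame(k = k_grid, cv_kappa = as.numeric(means)))
}
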