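#' Construct an absolute single-sample activation model
#'
#' An activation model for one signature consists of K binary gene-pair rules
#' ("expr(gene_x) > expr(gene_y) within the profile"), a naive Bayes table of
#' smoothed conditional probabilities P(rule true | class), and class priors.
#' Because every rule compares two genes inside one profile, predictions are a
#' pure function of (model, profile): they are invariant under any strictly
#' increasing transform of the whole profile and cannot be influenced by which
#' other samples are analysed alongside. Models are usually produced by
#' \code{\link{sigact}}; the constructor is exported so models can be built or
#' rehydrated directly.
#'
#' @param signature_id Signature the model mimics.
#' @param rules data.frame with columns \code{gene_x}, \code{gene_y},
#'   \code{target_class} (and optionally \code{score}).
#' @param cond_prob K x 3 matrix of P(rule true | class), columns
#'   low/independent/high, all entries strictly inside (0, 1).
#' @param priors Named length-3 vector of class priors (summing to 1).
#' @param K Number of rules (defaults to \code{nrow(rules)}).
#' @param cv Optional CV table from model selection (data.frame k, cv_kappa).
#' @param kappa_by_dataset Optional per-training-dataset agreement table.
#' @param retained Whether the model passed the per-dataset kappa filter.
#' @param meta Optional list of training provenance.
#' @return An object of class \code{sigact_model}.
#' @export
sigact_model <- function(signature_id, rules, cond_prob, priors,
                         K = nrow(rules), cv = NULL, kappa_by_dataset = NULL,
                         retained = NA, meta = list()) {
  lv <- activation_levels()
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_x", "gene_y", "target_class") %in% names(rules)),
            nrow(rules) == K, is.matrix(cond_prob), nrow(cond_prob) == K)
  if (any(rules$gene_x == rules$gene_y))
    stop("sigact_model: a rule compares a gene with itself")
  cond_prob <- cond_prob[, lv, drop = FALSE]
  if (any(cond_prob <= 0 | cond_prob >= 1))
    stop("sigact_model: conditional probabilities must lie strictly in (0, 1)")
  priors <- priors[lv]
  if (abs(sum(priors) - 1) > 1e-9) stop("sigact_model: priors must sum to 1")
  structure(list(signature_id = as.character(signature_id), rules = rules,
                 cond_prob = cond_prob, priors = priors, K = K, cv = cv,
                 kappa_by_dataset = kappa_by_dataset, retained = retained,
                 meta = meta),
            class = "sigact_model")
}

#' @export
print.sigact_model <- function(x, ...) {
  cat("Absolute activation model for signature '", x$signature_id, "'\n", sep = "")
  cat("  rules: ", x$K, " gene-pair rule(s); priors: ",
      paste(sprintf("%s %.3f", names(x$priors), x$priors), collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$retained))
    cat("  retained after per-dataset kappa filtering: ", x$retained, "\n", sep = "")
  invisible(x)
}

#' Rules and conditional probabilities of a fitted model
#'
#' @param object A \code{sigact_model}.
#' @param ... Unused.
#' @return The rule table with the P(rule true | class) columns appended.
#' @export
coef.sigact_model <- function(object, ...) {
  out <- object$rules
  for (lv in colnames(object$cond_prob))
    out[[paste0("p_true_", lv)]] <- object$cond_prob[, lv]
  out
}

# Predict one named profile. Pure function of (model, profile); rules whose
# genes are absent are dropped and counted, and the likelihood is
# renormalized over the evaluated rules.
predict_profile <- function(model, values, max_missing = 0.5) {
  vx <- values[model$rules$gene_x]
  vy <- values[model$rules$gene_y]
  ok <- !is.na(vx) & !is.na(vy)
  n_missing <- sum(!ok)
  if (n_missing > max_missing * model$K)
    stop("predict: ", n_missing, " of ", model$K,
         " rules have missing genes (coverage threshold ", max_missing, ")")
  lv <- activation_levels()
  lp <- vapply(lv, function(cl) {
    p <- model$cond_prob[ok, cl]
    obs <- vx[ok] > vy[ok]       # strict: ties evaluate false
    log(model$priors[[cl]]) + sum(ifelse(obs, log(p), log1p(-p)))
  }, 0)
  post <- exp(lp - logsumexp(lp))
  post <- post / sum(post)
  top <- which(post == max(post))
  label <- if (length(top) > 1L) "independent" else lv[top]
  list(label = label, posteriors = post, rules_evaluated = sum(ok),
       rules_missing = n_missing)
}

#' Predict activation from expression profiles with an absolute model
#'
#' Applies the gene-pair rules to each profile independently and combines
#' them through the naive Bayes tables. The call for a sample is bit-identical
#' whether the sample is predicted alone, inside any batch, or in any column
#' order: no cohort statistics enter the computation.
#'
#' @param object A \code{sigact_model}.
#' @param newdata A named numeric vector (one profile, names = gene ids) or a
#'   genes x samples matrix of raw non-negative expression.
#' @param max_missing Maximum tolerated fraction of rules with a missing
#'   gene; above it prediction refuses with an error. Missing-gene rules are
#'   dropped and the likelihood renormalized over the evaluated rules.
#' @param ... Unused.
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{signature_id}, \code{label}, \code{p_low}, \code{p_independent},
#'   \code{p_high}, \code{rules_evaluated}, \code{rules_missing}. Posteriors
#'   sum to 1 and \code{label} is the argmax (posterior ties fall back to
#'   independent).
#' @export
predict.sigact_model <- function(object, newdata, max_missing = 0.5, ...) {
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata)))
      stop("predict: a single profile must be a named numeric vector (names = gene ids)")
    prof <- list(sample = newdata)
  } else {
    prof <- lapply(seq_len(ncol(newdata)),
                   function(j) stats::setNames(newdata[, j], rownames(newdata)))
    names(prof) <- colnames(newdata)
  }
  rows <- lapply(names(prof), function(id) {
    pr <- predict_profile(object, prof[[id]], max_missing = max_missing)
    data.frame(sample_id = id, signature_id = object$signature_id,
               label = pr$label, p_low = pr$posteriors[["low"]],
               p_independent = pr$posteriors[["independent"]],
               p_high = pr$posteriors[["high"]],
               rules_evaluated = pr$rules_evaluated,
               rules_missing = pr$rules_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- as_activation_factor(out$label)
  out
}

#' Train absolute single-sample activation models
#'
#' The end-to-end trainer. For each signature it (1) computes the
#' region-of-independence gold standard on every training dataset separately
#' (\code{\link{build_gold_standard}}); (2) optionally winnows the signature
#' collection on the largest dataset, discarding signatures whose partition is
#' indistinguishable from random (independent fraction above
#' \code{winnow_cutoff}); (3) scores every ordered gene-pair rule over the
#' shared gene universe with dataset-balanced weights, interleaving the
#' per-class rankings (high, low, independent) into a candidate rule list;
#' (4) picks the rule count K by stratified 10-fold cross-validation,
#' re-ranking rules within each training fold and maximizing held-out
#' weighted kappa (ties to the smallest K); (5) fits the naive Bayes
#' combination of the top-K rules; and (6) retains only models whose
#' agreement with the gold standard is significant in every individual
#' training dataset (Bonferroni-corrected kappa p-value below \code{alpha},
#' family = number of candidate models).
#'
#' @param datasets Named list of gene-level expression matrices (raw
#'   non-negative values; sample ids must be unique across datasets).
#' @param signatures List of \code{\link{gene_signature}} objects.
#' @param q,n_trials Region-of-independence parameters for the gold standard.
#' @param k_grid Candidate rule counts (default 1..50).
#' @param folds Cross-validation folds (default 10), stratified jointly by
#'   class and dataset; reduced with a warning when a class is rarer.
#' @param alpha Significance level for the per-dataset kappa filter.
#' @param winnow_cutoff Independent-fraction cutoff for winnowing.
#' @param apply_winnow Apply the winnowing filter (default TRUE). Signatures
#'   failing it are excluded before model fitting.
#' @param min_genes Minimum signature genes present per dataset.
#' @param seed Integer seed controlling every random element (null trials,
#'   permutation control, fold assignment); independent streams are derived
#'   per signature and dataset so results do not depend on processing order.
#' @param draw Null rank draw scheme, see \code{\link{null_rank_sums}}.
#' @param smooth Laplace smoothing for the naive Bayes tables.
#' @param verbose Print per-signature progress.
#' @return An object of class \code{sigact}: \code{models} (named list of
#'   \code{\link{sigact_model}}, retained or not), \code{excluded}
#'   (data.frame of signatures dropped before training, with reasons),
#'   \code{winnow} (the winnowing report or NULL), \code{gold} (the
#'   \code{gold_standard}), \code{universe}, \code{n_tests} (Bonferroni
#'   family size), and the configuration used.
#' @examples
#' \donttest{
#' sims <- simulate_multidataset(n_datasets = 2, n_samples = c(80, 80),
#'                               n_genes = 60,
#'                               sig_specs = data.frame(k = 12, frac_low = 0.3,
#'                                                      frac_high = 0.3,
#'                                                      delta = 3,
#'                                                      frac_down = 0.2),
#'                               seed = 7)
#' fit <- sigact(lapply(sims$datasets, `[[`, "expr"), sims$signatures,
#'               n_trials = 1000, k_grid = c(1, 5, 10), folds = 5, seed = 7)
#' summary(fit)
#' }
#' @export
sigact <- function(datasets, signatures, q = 0.95, n_trials = 10000L,
                   k_grid = 1:50, folds = 10L, alpha = 0.05,
                   winnow_cutoff = 0.8, apply_winnow = TRUE,
                   min_genes = 5L, seed = NULL, draw = "integer",
                   smooth = 1, verbose = FALSE) {
  stopifnot(is.list(datasets), length(datasets) >= 1L, length(k_grid) >= 1L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("d", seq_along(datasets))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  all_samples <- unlist(lapply(datasets, colnames))
  if (anyDuplicated(all_samples))
    stop("sigact: sample ids must be unique across datasets")

  shared <- intersect_genes(datasets)
  universe <- rownames(shared[[1L]])
  if (length(universe) < 2L) stop("sigact: shared gene universe has fewer than 2 genes")
  E <- do.call(cbind, shared)
  colnames(E) <- all_samples
  ds <- rep(names(datasets), vapply(datasets, ncol, 0L))
  w <- dataset_weights(ds)

  excluded <- data.frame(signature_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  wreport <- NULL
  if (apply_winnow) {
    largest <- which.max(vapply(datasets, ncol, 0L))
    wreport <- suppressWarnings(
      winnow(datasets[[largest]], signatures, cutoff = winnow_cutoff, q = q,
             n_trials = n_trials, min_genes = min_genes,
             seed = if (is.null(seed)) NULL else sig_seed(seed, "winnow"),
             draw = draw))
    bad <- !wreport$informative
    if (any(bad)) {
      reason <- ifelse(nzchar(wreport$reason[bad]), wreport$reason[bad],
                       "uninformative")
      excluded <- rbind(excluded,
                        data.frame(signature_id = wreport$signature_id[bad],
                                   reason = reason, stringsAsFactors = FALSE))
      signatures <- signatures[wreport$informative]
    }
  }
  if (length(signatures) == 0L)
    return(structure(list(models = list(), excluded = excluded,
                          winnow = wreport, gold = NULL, universe = universe,
                          n_tests = 0L, datasets = names(datasets),
                          q = q, alpha = alpha, seed = seed),
                     class = "sigact"))

  gold <- build_gold_standard(datasets, signatures, q = q, n_trials = n_trials,
                              min_genes = min_genes, seed = seed, draw = draw)

  models <- list()
  for (sig in signatures) {
    id <- sig$signature_id
    ent <- gold$entries[gold$entries$signature_id == id, , drop = FALSE]
    if (nrow(ent) == 0L) {
      excluded <- rbind(excluded, data.frame(signature_id = id,
                                             reason = "too_few_genes",
                                             stringsAsFactors = FALSE))
      next
    }
    idx <- match(ent$sample_id, colnames(E))
    y <- as_activation_factor(ent$label)
    if (any(table(y) == 0L)) {
      excluded <- rbind(excluded, data.frame(signature_id = id,
                                             reason = "missing_class",
                                             stringsAsFactors = FALSE))
      next
    }
    if (verbose) message("training model for '", id, "' (n = ", length(idx), ")")
    m <- train_signature(E[, idx, drop = FALSE], y, w[idx], ds[idx], id,
                         k_grid = k_grid, folds = folds,
                         seed = if (is.null(seed)) NULL else sig_seed(seed, id),
                         smooth = smooth)
    m$meta <- list(datasets = names(datasets), n_train = length(idx),
                   seed = seed, q = q)
    models[[id]] <- m
  }

  # per-dataset kappa filter; Bonferroni family = candidate models per dataset
  n_tests <- length(models)
  for (id in names(models)) {
    m <- models[[id]]
    ent <- gold$entries[gold$entries$signature_id == id, , drop = FALSE]
    kbd <- lapply(split(ent, ent$dataset_id), function(e) {
      pred <- predict(m, E[, match(e$sample_id, colnames(E)), drop = FALSE])
      kr <- suppressWarnings(cohen_kappa(pred$label, as_activation_factor(e$label)))
      data.frame(dataset_id = e$dataset_id[1L], kappa = kr$kappa, p = kr$p,
                 p_bonferroni = min(1, kr$p * n_tests), stringsAsFactors = FALSE)
    })
    kbd <- do.call(rbind, kbd)
    rownames(kbd) <- NULL
    m$kappa_by_dataset <- kbd
    m$retained <- nrow(kbd) == length(unique(ent$dataset_id)) &&
      all(is.finite(kbd$p)) && all(kbd$p_bonferroni < alpha)
    models[[id]] <- m
  }

  structure(list(models = models, excluded = excluded, winnow = wreport,
                 gold = gold, universe = universe, n_tests = n_tests,
                 datasets = names(datasets), q = q, alpha = alpha,
                 seed = seed),
            class = "sigact")
}

# Core per-signature trainer: rule scoring, CV choice of K, final NB fit.
train_signature <- function(E, y, w, ds, signature_id, k_grid, folds, seed,
                            smooth) {
  lv <- activation_levels()
  fold <- assign_folds(y, ds, folds, seed = seed)
  folds_eff <- if (is.null(fold)) 0L else max(fold)
  W <- class_weight_matrix(y, w)            # full-data columns 1..3
  if (folds_eff >= 2L) {
    for (f in seq_len(folds_eff)) {
      Wf <- W[, 1:3, drop = FALSE] * 1
      Wf[fold == f, ] <- 0                  # mask the held-out fold
      W <- cbind(W, Wf)
    }
  }
  ptm <- pair_true_mass(E, W)
  attr(ptm, "tw") <- colSums(W)

  if (folds_eff >= 2L) {
    ksel <- select_rule_count(ptm, E, y, w, fold, k_grid, smooth)
  } else {
    warning("signature '", signature_id,
            "': too few samples per class for cross-validation; using smallest K")
    ksel <- list(K = min(k_grid), cv = NULL)
  }
  tw <- attr(ptm, "tw")[1:3]
  names(tw) <- lv
  sc <- mass_to_scores(ptm$mass[, 1:3, drop = FALSE], tw)
  colnames(sc) <- lv
  rk <- interleave_rules(sc, ksel$K)
  Tsel <- rule_truth(E, ptm$xi[rk$idx], ptm$yi[rk$idx])
  nb <- fit_rule_nb(Tsel, y, w, smooth)
  rules <- data.frame(gene_x = rownames(E)[ptm$xi[rk$idx]],
                      gene_y = rownames(E)[ptm$yi[rk$idx]],
                      target_class = rk$target_class,
                      score = sc[cbind(rk$idx, match(rk$target_class, lv))],
                      stringsAsFactors = FALSE)
  sigact_model(signature_id, rules, nb$cond_prob, nb$priors, K = ksel$K,
               cv = ksel$cv)
}

#' @export
print.sigact <- function(x, ...) {
  nret <- sum(vapply(x$models, `[[`, NA, "retained"), na.rm = TRUE)
  cat("Absolute signature-activation model set\n")
  cat("  datasets: ", paste(x$datasets, collapse = ", "), "\n", sep = "")
  cat("  candidate models: ", length(x$models), "; retained: ", nret,
      "; excluded before training: ", nrow(x$excluded), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sigact <- function(object, ...) {
  rows <- lapply(object$models, function(m) {
    data.frame(signature_id = m$signature_id, K = m$K,
               min_kappa = min(m$kappa_by_dataset$kappa),
               max_p_bonferroni = max(m$kappa_by_dataset$p_bonferroni),
               retained = m$retained, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(signature_id = character(), K = integer(),
                         min_kappa = numeric(), max_p_bonferroni = numeric(),
                         retained = logical())
  rownames(out) <- NULL
  out
}

#' Predict activation for all (retained) models in a fitted set
#'
#' @param object A \code{sigact} fit.
#' @param newdata Named numeric profile or genes x samples matrix.
#' @param retained_only Predict only with retained models (default).
#' @param max_missing Passed to \code{\link{predict.sigact_model}}.
#' @param ... Unused.
#' @return Stacked prediction data.frame over models.
#' @export
predict.sigact <- function(object, newdata, retained_only = TRUE,
                           max_missing = 0.5, ...) {
  models <- object$models
  if (retained_only)
    models <- Filter(function(m) isTRUE(m$retained), models)
  if (length(models) == 0L) stop("predict.sigact: no models to predict with")
  out <- do.call(rbind, lapply(models, predict, newdata = newdata,
                               max_missing = max_missing))
  rownames(out) <- NULL
  out
}
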