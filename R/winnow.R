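#' Winnow a signature collection to the informative signatures
#'
#' A signature is informative in a cohort when its region-of-independence
#' partition is distinguishable from random: the fraction of samples labelled
#' independent must not exceed \code{cutoff} (default 0.8, "exceed" strict, so
#' informative iff frac_independent <= cutoff). As a negative control the same
#' statistic is computed on a gene-label-permuted copy of the cohort, where
#' every signature should behave like a random gene set.
#'
#' @param expr Expression matrix; a warning is issued below 200 samples, where
#'   the region of independence is less stable.
#' @param signatures A list of \code{\link{gene_signature}} objects (or one).
#' @param cutoff Maximum independent fraction for an informative signature.
#' @param q,n_trials,min_genes,draw Passed to \code{\link{roi}}.
#' @param seed Integer seed; one RNG stream is derived per signature so
#'   results do not depend on processing order. The permutation control uses
#'   one global gene-label permutation of the dataset, shared by all
#'   signatures.
#' @param permuted_control If \code{FALSE} the permuted-control column is
#'   skipped (NA), halving the work.
#' @return A data.frame (one row per signature): \code{signature_id},
#'   \code{k_used}, \code{frac_low}, \code{frac_independent},
#'   \code{frac_high}, \code{frac_independent_permuted}, \code{informative},
#'   \code{reason}. Signatures with too few genes present are reported as
#'   non-informative with reason \code{"too_few_genes"}.
#' @export
winnow <- function(expr, signatures, cutoff = 0.8, q = 0.95,
                   n_trials = 10000L, min_genes = 5L, seed = NULL,
                   draw = "integer", permuted_control = TRUE) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (ncol(expr) < 200L)
    warning("winnow: fewer than 200 samples; region-of-independence fractions may be unstable")
  perm <- if (permuted_control)
    permute_gene_labels(expr, seed = if (is.null(seed)) NULL else sig_seed(seed, "|perm"))
  else NULL

  rows <- lapply(signatures, function(sig) {
    s <- if (is.null(seed)) NULL else sig_seed(seed, sig$signature_id)
    fit <- tryCatch(roi(expr, sig, q = q, n_trials = n_trials, seed = s,
                        min_genes = min_genes, draw = draw),
                    sigact_skip = function(e) e)
    if (inherits(fit, "sigact_skip"))
      return(data.frame(signature_id = sig$signature_id, k_used = fit$n_present,
                        frac_low = NA_real_, frac_independent = NA_real_,
                        frac_high = NA_real_, frac_independent_permuted = NA_real_,
                        informative = FALSE, reason = "too_few_genes",
                        stringsAsFactors = FALSE))
    frac <- as.numeric(table(fit$labels)) / fit$n
    fip <- NA_real_
    if (!is.null(perm)) {
      pfit <- tryCatch(roi(perm, sig, q = q, n_trials = n_trials,
                           seed = if (is.null(seed)) NULL
                                  else sig_seed(seed, paste0(sig$signature_id, "|perm")),
                           min_genes = min_genes, draw = draw),
                       sigact_skip = function(e) NULL)
      if (!is.null(pfit)) fip <- mean(pfit$labels == "independent")
    }
    data.frame(signature_id = sig$signature_id, k_used = fit$k_used,
               frac_low = frac[1L], frac_independent = frac[2L],
               frac_high = frac[3L], frac_independent_permuted = fip,
               informative = frac[2L] <= cutoff, reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
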