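#' Relative z-score activation score for a signature
#'
#' The classic relative combiner: each signature gene is standardized across
#' the cohort (mean 0, sd 1), down-regulated genes are negated after
#' standardization, and a sample's score is the sum of its gene z-scores
#' divided by sqrt(k). Because the standardization uses cohort statistics the
#' score of a sample depends on which other samples are present -- the
#' cohort-composition instability the absolute classifier removes.
#'
#' @param expr Expression matrix (genes x samples).
#' @param signature A \code{\link{gene_signature}}.
#' @param sd_type \code{"population"} (n denominator, default, deterministic
#'   under resampling conventions) or \code{"sample"} (n - 1).
#' @return Named numeric vector of per-sample scores. Zero-variance genes are
#'   dropped with a warning; if no gene survives, all scores are 0 with a
#'   warning.
#' @export
zscore_signature <- function(expr, signature, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  up <- intersect(signature$up, rownames(expr))
  down <- intersect(signature$down, rownames(expr))
  if (length(up) + length(down) == 0L)
    stop("zscore_signature: no signature gene present")
  sub <- expr[c(up, down), , drop = FALSE]
  n <- ncol(sub)
  mu <- rowMeans(sub)
  va <- rowSums((sub - mu)^2) / if (sd_type == "population") n else (n - 1L)
  keep <- va > 0
  if (!all(keep))
    warning("zscore_signature: dropping ", sum(!keep), " zero-variance gene(s)")
  if (!any(keep)) {
    warning("zscore_signature: all genes zero-variance; scores undefined, returning 0")
    return(stats::setNames(rep(0, n), colnames(expr)))
  }
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sqrt(va[keep])
  sgn <- ifelse(rownames(z) %in% down, -1, 1)
  stats::setNames(colSums(z * sgn) / sqrt(sum(keep)), colnames(expr))
}

#' Scorer wrapper for absolute models
#'
#' Adapts a fitted model set to the scorer interface of
#' \code{\link{stability_experiment}}. The score of a sample is the posterior
#' contrast p(high) - p(low) from the signature's model, a pure function of
#' the single profile.
#'
#' @param models A \code{sigact} fit or a named list of
#'   \code{\link{sigact_model}} objects.
#' @return A function \code{(expr, signature) -> named numeric scores}.
#' @export
sigact_scorer <- function(models) {
  if (inherits(models, "sigact")) models <- models$models
  if (inherits(models, "sigact_model")) models <- list(models)
  names(models) <- vapply(models, `[[`, "", "signature_id")
  function(expr, signature) {
    m <- models[[signature$signature_id]]
    if (is.null(m))
      stop("sigact_scorer: no model for signature '", signature$signature_id, "'")
    pred <- predict(m, expr)
    stats::setNames(pred$p_high - pred$p_low, pred$sample_id)
  }
}

#' Cohort-composition stability experiment
#'
#' Scores every sample twice: once in the full cohort and once in the cohort
#' restricted to the sample's own stratum (e.g. receptor status), and records
#' the absolute shift. Relative scorers such as the z-score combiner shift
#' when the cohort composition changes; absolute single-sample models shift
#' by exactly zero because no cohort statistic enters their computation.
#'
#' @param expr Expression matrix.
#' @param signatures List of \code{\link{gene_signature}} objects (or one).
#' @param strata Factor/character vector over samples partitioning the cohort.
#' @param scorer \code{"zscore"} or a function \code{(expr, signature)}
#'   returning named per-sample scores (see \code{\link{sigact_scorer}}).
#' @param ... Passed to the scorer when \code{scorer = "zscore"}.
#' @return data.frame with one row per (sample, signature):
#'   \code{sample_id}, \code{signature_id}, \code{stratum},
#'   \code{score_all}, \code{score_stratum}, \code{abs_diff}.
#' @export
stability_experiment <- function(expr, signatures, strata, scorer = "zscore", ...) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  stopifnot(length(strata) == ncol(expr))
  strata <- as.character(strata)
  fn <- if (is.function(scorer)) scorer
        else switch(scorer,
                    zscore = function(e, s) zscore_signature(e, s, ...),
                    stop("unknown scorer '", scorer, "'"))
  if (!is.function(scorer) && identical(scorer, "zscore")) {
    small <- names(which(table(strata) < 10L))
    if (length(small) > 0L)
      warning("stability_experiment: strata below 10 samples (unstable standardization): ",
              paste(small, collapse = ", "))
  }
  rows <- lapply(signatures, function(sig) {
    s_all <- fn(expr, sig)
    s_str <- rep(NA_real_, ncol(expr))
    names(s_str) <- colnames(expr)
    for (st in unique(strata)) {
      sel <- strata == st
      s_str[colnames(expr)[sel]] <- fn(expr[, sel, drop = FALSE], sig)[colnames(expr)[sel]]
    }
    data.frame(sample_id = colnames(expr), signature_id = sig$signature_id,
               stratum = strata, score_all = as.numeric(s_all[colnames(expr)]),
               score_stratum = as.numeric(s_str[colnames(expr)]),
               abs_diff = abs(as.numeric(s_all[colnames(expr)]) -
                              as.numeric(s_str[colnames(expr)])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
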