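#' Cohen's kappa with large-sample significance
#'
#' Chance-corrected agreement between two paired categorical labelings:
#' kappa = (p_o - p_e) / (1 - p_e), where p_o is the observed agreement and
#' p_e the agreement expected from the marginals. Significance against the
#' null of chance agreement uses the classical large-sample null variance
#' (Fleiss, Cohen & Everitt 1969):
#' var0 = [p_e + p_e^2 - sum_i r_i c_i (r_i + c_i)] / (n (1 - p_e)^2),
#' with r_i, c_i the row/column marginal proportions; z = kappa / sqrt(var0)
#' and a two-sided normal p-value. The formula is validated in the test suite
#' against a label-permutation null, which is the authoritative check.
#'
#' @param a,b Paired categorical vectors (factors or characters) of equal
#'   length >= 2. Levels are taken as the union of both.
#' @return An object of class \code{kappa_result}: \code{kappa}, \code{p_o},
#'   \code{p_e}, \code{se0}, \code{z}, \code{p}, \code{n}. When both raters
#'   are constant and identical (p_e = 1), kappa is undefined and returned as
#'   \code{NA} with a warning.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  lev <- union(levels(factor(a)), levels(factor(b)))
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  r <- rowSums(tab); cc <- colSums(tab)
  p_e <- sum(r * cc)
  if (p_e >= 1 - 1e-12) {
    warning("cohen_kappa: both labelings constant and equal; kappa undefined")
    out <- list(kappa = NA_real_, p_o = p_o, p_e = p_e, se0 = NA_real_,
                z = NA_real_, p = NA_real_, n = n)
    class(out) <- "kappa_result"
    return(out)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  var0 <- (p_e + p_e^2 - sum(r * cc * (r + cc))) / (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  out <- list(kappa = kappa, p_o = p_o, p_e = p_e, se0 = se0, z = z, p = p, n = n)
  class(out) <- "kappa_result"
  out
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (p_o = %.4f, p_e = %.4f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  if (!is.na(x$z))
    cat(sprintf("  z = %.3f, two-sided p = %.3g\n", x$z, x$p))
  invisible(x)
}

# Weighted kappa point estimate (no significance); used internally for
# cross-validated model selection where samples carry dataset-balancing
# weights.
weighted_kappa <- function(a, b, w) {
  lev <- union(levels(factor(a)), levels(factor(b)))
  a <- factor(a, levels = lev); b <- factor(b, levels = lev)
  W <- sum(w)
  if (W <= 0) return(NA_real_)
  p_o <- sum(w[a == b]) / W
  r <- vapply(lev, function(l) sum(w[a == l]), 0) / W
  cc <- vapply(lev, function(l) sum(w[b == l]), 0) / W
  p_e <- sum(r * cc)
  if (p_e >= 1 - 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Exact association between class labels and a grouping
#'
#' Fisher's exact test on the contingency table of labels x groups. For
#' tables beyond 2x2 the network algorithm is attempted first and a seeded
#' Monte-Carlo exact test is used as fallback for large tables.
#'
#' @param labels,groups Paired categorical vectors.
#' @param simulate_b Monte-Carlo replicates for the fallback.
#' @return Two-sided p-value. Degenerate tables (a single observed row or
#'   column) return 1 with a warning.
#' @export
fisher_association <- function(labels, groups, simulate_b = 1e5) {
  tab <- table(as.character(labels), as.character(groups))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("fisher_association: degenerate table; returning p = 1")
    return(1)
  }
  ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                 error = function(e)
                   stats::fisher.test(tab, simulate.p.value = TRUE, B = simulate_b))
  ft$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment
#' (via \code{stats::p.adjust}).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis association between a score and class labels
#'
#' Thin wrapper around \code{stats::kruskal.test} for testing whether a
#' continuous score (e.g. a proliferation score) differs across activation
#' classes.
#'
#' @param score Numeric vector.
#' @param groups Categorical vector of the same length.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
kruskal_association <- function(score, groups) {
  kt <- stats::kruskal.test(score, factor(groups))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
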