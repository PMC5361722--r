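#' Directed per-gene sample ranks for a signature
#'
#' For every signature gene present in the matrix, samples are ranked 1..n by
#' ascending expression; genes in the down-regulated subset are ranked on the
#' negated values, so low expression earns a high rank and every gene orders
#' samples in the direction of activation. Tied expression values receive
#' average ranks.
#'
#' @param expr Gene-level expression matrix (genes x samples).
#' @param signature A \code{\link{gene_signature}}.
#' @param min_genes Minimum number of signature genes that must be present;
#'   below it the signature is skipped with a classed error
#'   (condition class \code{"sigact_skip"}) carrying the count found.
#' @return A genes-present x samples matrix of directed ranks, with attribute
#'   \code{"direction"} (+1 up, -1 down per retained gene).
#' @export
directed_ranks <- function(expr, signature, min_genes = 5L) {
  up <- intersect(signature$up, rownames(expr))
  down <- intersect(signature$down, rownames(expr))
  k <- length(up) + length(down)
  if (k < min_genes)
    stop(errorCondition(
      sprintf("signature '%s': only %d of %d genes present (min_genes = %d)",
              signature$signature_id, k, length(signature_genes(signature)), min_genes),
      n_present = k, class = c("sigact_skip", "error", "condition")))
  sub <- expr[c(up, down), , drop = FALSE]
  if (length(down) > 0L) {
    di <- seq.int(length(up) + 1L, k)
    sub[di, ] <- -sub[di, , drop = FALSE]
  }
  ranks <- t(apply(sub, 1L, rank, ties.method = "average"))
  dimnames(ranks) <- list(c(up, down), colnames(expr))
  attr(ranks, "direction") <- c(rep(1L, length(up)), rep(-1L, length(down)))
  ranks
}

# Rank-sum per sample and the induced linear order (ascending sum,
# ties broken by sample id for determinism).
rank_sum_order <- function(ranks) {
  sums <- colSums(ranks)
  ord <- order(sums, colnames(ranks), method = "radix")
  list(rank_sums = sums, sample_order = colnames(ranks)[ord])
}

#' Randomized rank-sums of an artificial sample
#'
#' The null model behind the region of independence: an artificial sample
#' "n + 1" is ranked independently by each of the k signature genes with a
#' uniformly random rank from \{0, ..., n + 1\}, and the k ranks are summed.
#' Repeating this many times yields the null rank-sum distribution against
#' which the observed cohort rank-sums are judged.
#'
#' @param n Number of samples in the cohort.
#' @param k Number of signature genes used.
#' @param n_trials Number of randomized trials (at least 100).
#' @param draw \code{"integer"} draws ranks uniformly from the integers
#'   \{0, ..., n + 1\}; \code{"continuous"} draws from the continuous
#'   uniform on (0, n + 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of \code{n_trials} null rank-sums.
#' @export
null_rank_sums <- function(n, k, n_trials = 10000L, draw = c("integer", "continuous"),
                           seed = NULL) {
  draw <- match.arg(draw)
  stopifnot(n >= 2L, k >= 1L, n_trials >= 100L)
  with_seed(seed, {
    r <- switch(draw,
      integer = sample.int(n + 2L, k * n_trials, replace = TRUE) - 1L,
      continuous = stats::runif(k * n_trials, 0, n + 1))
    colSums(matrix(r, nrow = k, ncol = n_trials))
  })
}

#' Empirical region of independence from null rank-sums
#'
#' The region at coverage q is the closed interval between the (1-q)/2 and
#' (1+q)/2 empirical quantiles of the null rank-sums. Nearest-rank (type 1)
#' quantiles are used so both bounds are attainable null values and the closed
#' interval is guaranteed to contain at least a fraction q of the trials.
#'
#' @param null_sums Null rank-sums (see \code{\link{null_rank_sums}}).
#' @param q Coverage in (0, 1).
#' @return Numeric \code{c(lower_sum, upper_sum)}.
#' @export
roi_region <- function(null_sums, q = 0.95) {
  stopifnot(length(null_sums) > 0L, q > 0, q < 1)
  s <- sort(null_sums)
  m <- length(s)
  lower <- s[max(1L, ceiling(m * (1 - q) / 2))]
  upper <- s[min(m, ceiling(m * (1 + q) / 2))]
  c(lower_sum = lower, upper_sum = upper)
}

#' Exact null rank-sum distribution
#'
#' Probability mass function of the sum of k independent uniform draws from
#' the integers \{0, ..., n + 1\}, i.e. the exact distribution the sampled
#' null of \code{\link{null_rank_sums}} converges to. Feasible for small k.
#'
#' @param n Number of samples.
#' @param k Number of signature genes.
#' @return Named numeric vector of probabilities over sums 0 .. k(n+1).
#' @export
roi_null_pmf <- function(n, k) {
  stopifnot(n >= 1L, k >= 1L)
  base <- rep(1 / (n + 2), n + 2L)
  pmf <- base
  if (k > 1L) for (i in seq_len(k - 1L)) {
    pmf <- stats::convolve(pmf, rev(base), type = "open")
    pmf[pmf < 0] <- 0   # clip fft round-off
  }
  pmf <- pmf / sum(pmf)
  names(pmf) <- 0:(k * (n + 1L))
  pmf
}

#' Exact region of independence
#'
#' Region bounds computed from the exact null pmf with the same nearest-rank
#' quantile convention as \code{\link{roi_region}}: each bound is the smallest
#' attainable sum whose cumulative probability reaches the target.
#'
#' @inheritParams roi_null_pmf
#' @param q Coverage in (0, 1).
#' @return Numeric \code{c(lower_sum, upper_sum)}.
#' @export
roi_region_exact <- function(n, k, q = 0.95) {
  pmf <- roi_null_pmf(n, k)
  cdf <- cumsum(pmf)
  vals <- as.numeric(names(pmf))
  lower <- vals[which(cdf >= (1 - q) / 2)[1L]]
  upper <- vals[which(cdf >= (1 + q) / 2)[1L]]
  c(lower_sum = lower, upper_sum = upper)
}

#' Region-of-independence partition of a cohort for one signature
#'
#' Ranks every sample by each signature gene in the direction of activation,
#' sums the ranks into a per-sample score, and contrasts the observed scores
#' with a permutation null in which an artificial sample is ranked uniformly
#' at random by every gene. Samples whose rank-sum falls below the null region
#' are called \code{low}, above it \code{high}, and inside it (bounds
#' included) \code{independent}: their signature genes show no coherent
#' pattern beyond what uncorrelated ranks produce. The partition is
#' cohort-level by construction -- adding samples can move other samples'
#' labels -- which is exactly the behaviour the absolute classifier
#' (\code{\link{sigact}}) removes.
#'
#' @param expr Gene-level expression matrix (genes x samples), raw
#'   non-negative values. Any strictly increasing per-gene transform leaves
#'   the result unchanged.
#' @param signature A \code{\link{gene_signature}}.
#' @param q Null coverage of the region, default 0.95.
#' @param n_trials Number of null trials, default 10000.
#' @param seed Optional integer seed for the null draws.
#' @param min_genes Minimum signature genes present (default 5).
#' @param draw Null rank draw scheme, see \code{\link{null_rank_sums}}.
#' @return An object of class \code{roi}: list with \code{signature_id},
#'   \code{rank_sums} (named per sample), \code{sample_order},
#'   \code{null_sums}, \code{region} (lower_sum, upper_sum), \code{labels}
#'   (named factor low/independent/high), \code{k_used}, \code{n}, \code{q},
#'   \code{n_trials}.
#' @examples
#' sim <- simulate_cohort(n_samples = 60, n_genes = 40,
#'                        sig_specs = data.frame(k = 10, frac_low = 0.3,
#'                                               frac_high = 0.3, delta = 3,
#'                                               frac_down = 0.2),
#'                        seed = 1)
#' fit <- roi(sim$expr, sim$signatures[[1]], n_trials = 1000, seed = 1)
#' table(labels(fit))
#' @export
roi <- function(expr, signature, q = 0.95, n_trials = 10000L, seed = NULL,
                min_genes = 5L, draw = c("integer", "continuous")) {
  draw <- match.arg(draw)
  stopifnot(q > 0, q < 1, n_trials >= 100L)
  ranks <- directed_ranks(expr, signature, min_genes = min_genes)
  k <- nrow(ranks)
  n <- ncol(ranks)
  rs <- rank_sum_order(ranks)
  null_sums <- null_rank_sums(n, k, n_trials = n_trials, draw = draw, seed = seed)
  region <- roi_region(null_sums, q)
  lab <- ifelse(rs$rank_sums < region[["lower_sum"]], "low",
         ifelse(rs$rank_sums > region[["upper_sum"]], "high", "independent"))
  labels <- as_activation_factor(lab)
  names(labels) <- names(rs$rank_sums)
  structure(list(signature_id = signature$signature_id,
                 rank_sums = rs$rank_sums, sample_order = rs$sample_order,
                 null_sums = null_sums, region = region, labels = labels,
                 k_used = k, n = n, q = q, n_trials = n_trials),
            class = "roi")
}

#' @export
labels.roi <- function(object, ...) object$labels

#' @export
print.roi <- function(x, ...) {
  cat("Region-of-independence partition for signature '", x$signature_id, "'\n",
      sep = "")
  cat("  samples: ", x$n, ", signature genes used: ", x$k_used, "\n", sep = "")
  cat(sprintf("  region (q = %.2f): [%.1f, %.1f] from %d null trials\n",
              x$q, x$region[["lower_sum"]], x$region[["upper_sum"]], x$n_trials))
  print(table(x$labels))
  invisible(x)
}

#' @export
summary.roi <- function(object, ...) {
  tab <- table(object$labels)
  frac <- as.numeric(tab) / object$n
  names(frac) <- names(tab)
  coverage <- mean(object$null_sums >= object$region[["lower_sum"]] &
                   object$null_sums <= object$region[["upper_sum"]])
  out <- list(signature_id = object$signature_id, n = object$n,
              k_used = object$k_used, q = object$q, region = object$region,
              class_fractions = frac, null_coverage = coverage)
  class(out) <- "summary.roi"
  out
}

#' @export
print.summary.roi <- function(x, ...) {
  cat("ROI summary -- signature '", x$signature_id, "' (n = ", x$n,
      ", k = ", x$k_used, ")\n", sep = "")
  cat(sprintf("  region: [%.1f, %.1f], null coverage %.4f (q = %.2f)\n",
              x$region[["lower_sum"]], x$region[["upper_sum"]],
              x$null_coverage, x$q))
  cat("  class fractions:\n")
  print(round(x$class_fractions, 4))
  invisible(x)
}

#' Plot the observed rank-sum order against the region of independence
#'
#' @param x A \code{roi} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.roi <- function(x, ...) {
  ord <- x$sample_order
  sums <- x$rank_sums[ord]
  cols <- c(low = "#2166AC", independent = "grey60", high = "#B2182B")
  plot(seq_along(sums), sums, pch = 16, col = cols[as.character(x$labels[ord])],
       xlab = "samples (rank-sum order)", ylab = "directed rank-sum",
       main = paste0("ROI_", format(x$q * 100), " -- ", x$signature_id), ...)
  graphics::abline(h = x$region, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}
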