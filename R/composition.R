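#' Exact upper-tail binomial probability
#'
#' Computes \eqn{P(X \ge x)} for \eqn{X \sim \mathrm{Binomial}(n, p)} by
#' direct summation of the probability mass function, with each term
#' evaluated on the log scale (\code{lchoose}) for numerical stability. This
#' is the one-sided enrichment tail used by the cluster-composition test.
#'
#' @param x observed count, \code{0 <= x <= n}.
#' @param n number of trials.
#' @param p success probability in \code{[0, 1]}.
#' @return \eqn{P(X \ge x)}, a probability in \code{[0, 1]}.
#' @examples
#' binomial_tail(10, 10, 246 / 342)  # ~0.0371
#' binomial_tail(4, 5, 96 / 342)     # ~0.0241
#' @export
binomial_tail <- function(x, n, p) {
  if (length(x) != 1 || length(n) != 1 || length(p) != 1)
    stop("binomial_tail is scalar; vectorise with vapply()")
  if (!is.finite(x) || !is.finite(n) || !is.finite(p) ||
      x != round(x) || n != round(n))
    stop("x and n must be finite integers, p finite")
  if (x < 0 || x > n) stop("x must satisfy 0 <= x <= n")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (x == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- x:n
  terms <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  ## sum on log scale from the largest term
  m <- max(terms)
  min(1, exp(m) * sum(exp(terms - m)))
}

#' Cluster-composition test against dataset priors
#'
#' For every cluster and every label, tests whether the label is
#' over-represented in the cluster relative to its overall proportion in the
#' dataset: the one-sided exact binomial tail \eqn{P(X \ge x)} with
#' \eqn{X \sim \mathrm{Binomial}(n, p_\ell)}, where \eqn{x} is the label's
#' count in the cluster, \eqn{n} the cluster size and \eqn{p_\ell} the
#' label's dataset prior. A cluster is tagged enriched for the label with the
#' smallest tail when that tail is at or below \code{alpha} and the minimum
#' is unique; otherwise it is left unclassified. P-values are reported per
#' cluster without correction by default (matching per-cluster reporting at a
#' fixed level); \code{adjust = "BH"} applies a Benjamini-Hochberg correction
#' across all cluster-label tails before tagging.
#'
#' @param solution a \code{cluster_solution} with label counts (see
#'   \code{\link{summarize_clusters}}).
#' @param priors named prior proportions from \code{\link{dataset_priors}}
#'   (or any named numeric vector covering the solution's labels).
#' @param alpha enrichment level; default 0.05.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return A data frame, one row per cluster: cluster id, size \code{n},
#'   centroid and sd columns, per-label counts \code{n_<label>}, per-label
#'   tails \code{p_<label>}, \code{enriched} (label or \code{NA}), and
#'   \code{p_value} (the tail of the tagged label, \code{NA} if unclassified).
#' @export
composition_test <- function(solution, priors, alpha = 0.05,
                             adjust = c("none", "BH")) {
  stopifnot(inherits(solution, "cluster_solution"))
  adjust <- match.arg(adjust)
  if (is.null(solution$label_set))
    stop("solution has no label counts; run summarize_clusters() first")
  labs <- solution$label_set
  missing_p <- setdiff(labs, names(priors))
  if (length(missing_p) > 0)
    stop("priors missing label(s): ", paste(missing_p, collapse = ", "))
  summ <- solution$summaries
  tails <- sapply(labs, function(l)
    vapply(seq_len(nrow(summ)), function(i)
      binomial_tail(summ[[paste0("n_", l)]][i], summ$size[i], priors[[l]]),
      numeric(1)))
  tails <- matrix(tails, nrow = nrow(summ),
                  dimnames = list(NULL, paste0("p_", labs)))
  crit <- if (adjust == "BH") {
    matrix(stats::p.adjust(tails, method = "BH"), nrow = nrow(tails),
           dimnames = dimnames(tails))
  } else tails
  enriched <- rep(NA_character_, nrow(summ))
  p_value <- rep(NA_real_, nrow(summ))
  for (i in seq_len(nrow(summ))) {
    best <- which(crit[i, ] == min(crit[i, ]))
    if (length(best) == 1 && crit[i, best] <= alpha) {
      enriched[i] <- labs[best]
      p_value[i] <- tails[i, best]
    }
  }
  out <- cbind(summ, tails)
  out$enriched <- enriched
  out$p_value <- p_value
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}
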