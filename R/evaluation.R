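# Scoring ranked couplings against contact maps: positive predictive value
# of the top-k couplings, average precision over the full ranking, and paired
# comparison of per-protein accuracies between two contact definitions.

#' Positive predictive value of the top-k ranked couplings
#'
#' PPV is the fraction of the k highest-scoring eligible pairs that are
#' contacts in the given map. The conventional depth is k = floor(L/2).
#'
#' @param rp A `ranked_pairs` object (see [rank_pairs()]).
#' @param cm A `contact_map` over the same chain and separation rule.
#' @param k Ranking depth; default `floor(L/2)`.
#' @return Object of class `eval_result`: list with `ppv`, `k`, `n_true`
#'   (contact count of the map) and `average_precision` (`NA` here; see
#'   [evaluate_ranking()]).
#' @export
ppv_top_k <- function(rp, cm, k = NULL) {
  stopifnot(inherits(rp, "ranked_pairs"), inherits(cm, "contact_map"))
  L <- attr(rp, "L")
  if (L != cm$L || attr(rp, "min_sep") != cm$min_sep) {
    stop("ranking and contact map differ in L or min_sep")
  }
  if (is.null(k)) k <- floor(L / 2)
  stopifnot(k >= 1)
  if (k > nrow(rp)) {
    stop("k = ", k, " exceeds the ", nrow(rp), " eligible ranked pairs")
  }
  keys_cm <- .pair_key(cm$pairs$i, cm$pairs$j, L)
  top <- rp[seq_len(k), ]
  hit <- .pair_key(top$i, top$j, L) %in% keys_cm
  structure(list(ppv = mean(hit), k = as.integer(k),
                 n_true = nrow(cm$pairs), average_precision = NA_real_),
            class = "eval_result")
}

#' Average precision of a ranking against a contact map
#'
#' AP = sum over ranking depths k of (R_k - R_{k-1}) * P_k, where P_k and R_k
#' are precision and recall at depth k; equivalently the mean precision at
#' the ranks of the true contacts. Computed over the full eligible ranking.
#'
#' @inheritParams ppv_top_k
#' @return Average precision in 0..1.
#' @export
average_precision <- function(rp, cm) {
  stopifnot(inherits(rp, "ranked_pairs"), inherits(cm, "contact_map"))
  L <- attr(rp, "L")
  if (L != cm$L || attr(rp, "min_sep") != cm$min_sep) {
    stop("ranking and contact map differ in L or min_sep")
  }
  if (nrow(cm$pairs) == 0L) stop("empty contact map")
  keys_cm <- .pair_key(cm$pairs$i, cm$pairs$j, L)
  lab <- .pair_key(rp$i, rp$j, L) %in% keys_cm
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / nrow(cm$pairs)
}

#' PPV and average precision in one call
#'
#' @inheritParams ppv_top_k
#' @return An `eval_result` with both `ppv` (at depth `k`) and
#'   `average_precision` (over the full ranking) filled in.
#' @export
evaluate_ranking <- function(rp, cm, k = NULL) {
  r <- ppv_top_k(rp, cm, k)
  r$average_precision <- average_precision(rp, cm)
  r
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: PPV@%d = %.3f | true contacts = %d", x$k, x$ppv,
              x$n_true))
  if (!is.na(x$average_precision)) {
    cat(sprintf(" | AP = %.3f", x$average_precision))
  }
  cat("\n")
  invisible(x)
}

#' Paired comparison of per-protein accuracies under two contact definitions
#'
#' Runs a two-sided Wilcoxon signed-rank test on paired accuracy vectors and
#' reports the median of the per-protein ratios b/a as a percent increase.
#' The exact null distribution is used below 25 pairs and the normal
#' approximation (with continuity correction) at or above.
#'
#' @param ppvs_a,ppvs_b Equal-length numeric vectors (length >= 5) of
#'   per-protein accuracies under definitions a and b.
#' @return Object of class `paired_comparison`: list with `median_ratio`,
#'   `percent_increase`, `statistic`, `p_value`, `n`.
#' @export
paired_comparison <- function(ppvs_a, ppvs_b) {
  stopifnot(is.numeric(ppvs_a), is.numeric(ppvs_b))
  n <- length(ppvs_a)
  if (length(ppvs_b) != n) stop("paired vectors differ in length")
  if (n < 5L) stop("need at least 5 pairs")
  d <- ppvs_b - ppvs_a
  if (all(d == 0)) stop("all paired differences are zero; test is degenerate")
  wt <- suppressWarnings(
    wilcox.test(ppvs_b, ppvs_a, paired = TRUE, exact = n < 25,
                correct = TRUE, alternative = "two.sided")
  )
  ratio <- ppvs_b / ppvs_a
  med <- median(ratio)
  structure(list(
    median_ratio = med,
    percent_increase = (med - 1) * 100,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n = n
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "paired_comparison (n = %d): median ratio %.3f (%+.1f%%), V = %g, p = %.3g\n",
    x$n, x$median_ratio, x$percent_increase, x$statistic, x$p_value))
  invisible(x)
}
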