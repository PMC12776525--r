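# Non-parametric group comparisons and single-feature ROC. The U statistic
# convention is fixed here once: U counts, over all between-group pairs,
# the pairs in which the group-a value exceeds the group-b value (ties
# half); so U = 0 when every a is below every b, and AUROC on scores with
# a = positives is exactly U / (n_pos * n_neg).

#' Two-sample non-parametric comparison
#'
#' Kolmogorov-Smirnov two-sample test (D statistic, two-tailed p) or
#' Mann-Whitney / Wilcoxon rank-sum test. For the Mann-Whitney test the
#' reported U counts pairs in which a value from \code{a} exceeds a value
#' from \code{b} (ties counted 1/2), so \code{U = 0} means all of
#' \code{a} below all of \code{b}; exact or normal-approximate p follows
#' the \code{stats::wilcox.test} convention.
#'
#' @param a,b numeric vectors, each of length at least 2
#' @param test \code{"ks"} or \code{"mann_whitney"}
#' @return list: \code{statistic} (named D or U), \code{p},
#'   \code{n_a}, \code{n_b}, \code{direction} (sign of median(a) -
#'   median(b))
#' @examples
#' compareGroups(c(1, 2), c(3, 4), "ks")$statistic   # D = 1
#' @export
compareGroups <- function(a, b, test = c("ks", "mann_whitney")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-missing values")
  if (test == "ks") {
    ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
    statistic <- c(D = unname(ht$statistic))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    statistic <- c(U = unname(ht$statistic))
  }
  list(statistic = statistic, p = ht$p.value,
       n_a = length(a), n_b = length(b),
       direction = sign(stats::median(a) - stats::median(b)))
}

#' ROC analysis of a single score
#'
#' Area under the ROC curve computed as a rank statistic with midrank tie
#' correction — the probability that a random positive outscores a random
#' negative (ties half). The p-value against AUROC = 0.5 comes from the
#' tie-corrected normal approximation to the Mann-Whitney U statistic.
#' The full threshold curve (sensitivity, specificity at every distinct
#' score cut) is returned for plotting. For a single predictor, logistic
#' regression is a monotone transform of the score and leaves the ROC
#' unchanged, so the score is used directly.
#'
#' @param labels binary vector (1/TRUE = positive); both classes required
#' @param scores numeric scores, higher = more positive-like
#' @return list: \code{auroc}, \code{p}, \code{n_pos}, \code{n_neg},
#'   \code{curve} (data.frame \code{threshold}, \code{sensitivity},
#'   \code{specificity})
#' @examples
#' rocFromScores(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auroc   # 1
#' @export
rocFromScores <- function(labels, scores) {
  labels <- as.logical(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  auroc <- u / (n_pos * n_neg)
  # tie-corrected normal approximation to U
  n <- n_pos + n_neg
  ties <- table(scores)
  sigma2 <- n_pos * n_neg / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (sigma2 > 0)
    2 * stats::pnorm(-abs(u - n_pos * n_neg / 2) / sqrt(sigma2))
  else 1
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[!labels] < t),
                         numeric(1))
  )
  list(auroc = auroc, p = p, n_pos = n_pos, n_neg = n_neg, curve = curve)
}
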