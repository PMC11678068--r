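# Binned normal-approximation test: compare the bin-count profile of the
# observed data with that of a matched normal reference sample of the same
# size, mean and standard deviation.

#' Bin observed data against a matched normal reference sample
#'
#' Draws a reference sample of the same length as `x` from
#' `Normal(mean(x), sd(x))` (seeded), partitions the reference range into `k`
#' equal-width (or, optionally, equal-quantile) intervals, replaces the first
#' break by `-Inf` and the last by `+Inf` so every observation falls in some
#' bin, and counts both vectors into the bins (half-open intervals
#' `[break_i, break_{i+1})`).
#'
#' @param x Numeric vector; missing values are removed first.
#' @param k Number of partitions (at least 2).
#' @param seed Integer seed for the reference draw.
#' @param mode `"equal_width"` (default) or `"equal_quantile"` partitions of
#'   the reference sample.
#' @return A list of class `bin_summary` with elements `k`, `breaks`
#'   (length `k + 1`), `obs_counts`, `ref_counts`, `n`, `mode`, `seed`.
#' @export
make_reference_bins <- function(x, k, seed,
                                mode = c("equal_width", "equal_quantile")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(x) < k) stop("need at least k finite observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("sd(x) is zero; binning is degenerate", call. = FALSE)
  ref <- withr::with_seed(seed, stats::rnorm(length(x), mean(x), s))
  breaks <- if (mode == "equal_width") {
    seq(min(ref), max(ref), length.out = k + 1)
  } else {
    stats::quantile(ref, probs = seq(0, 1, length.out = k + 1), names = FALSE)
  }
  breaks[1] <- -Inf
  breaks[k + 1] <- Inf
  structure(list(k = as.integer(k), breaks = breaks,
                 obs_counts = bin_counts(x, breaks),
                 ref_counts = bin_counts(ref, breaks),
                 n = length(x), mode = mode, seed = seed),
            class = "bin_summary")
}

# half-open binning [b_i, b_{i+1}); infinite end breaks catch everything
bin_counts <- function(x, breaks) {
  idx <- findInterval(x, breaks, rightmost.closed = FALSE, left.open = FALSE)
  tabulate(idx, nbins = length(breaks) - 1)
}

#' Chi-square association test between two paired count vectors
#'
#' Cross-tabulates the `k` pairs `(u_i, v_i)` by their distinct values into an
#' r x c contingency table and computes the Pearson independence statistic
#' (no continuity correction), with `df = (r - 1)(c - 1)`. This is the
#' count-vector comparison the binned normal-approximation procedure uses;
#' note it tests association between the paired bin counts, not goodness of
#' fit in the conventional sense. In particular, whenever all `v` values are
#' distinct the statistic is `k (r - 1)` and the df `(r - 1)(k - 1)`
#' regardless of the actual counts.
#'
#' @param u,v Integer vectors of equal length `k`.
#' @return A list of class `chisq_result` with `statistic`, `df`, `p`.
#' @examples
#' paired_count_chisq(c(1, 1, 2), c(5, 6, 7))  # statistic 3, df 2
#' @export
paired_count_chisq <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length",
                                   call. = FALSE)
  fu <- factor(u); fv <- factor(v)
  if (nlevels(fu) < 2 || nlevels(fv) < 2) {
    warning("degenerate table (a vector is constant); statistic 0, df 0")
    return(structure(list(statistic = 0, df = 0L, p = 1),
                     class = "chisq_result"))
  }
  ct <- suppressWarnings(stats::chisq.test(fu, fv, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p = unname(ct$p.value)),
            class = "chisq_result")
}

#' Binned normal-approximation test
#'
#' Tests whether `x` is "reasonably approximated" by a normal distribution by
#' binning `x` against a matched seeded normal reference sample
#' ([make_reference_bins()]) and comparing the two count vectors with
#' [paired_count_chisq()]. The null hypothesis is that the distribution is
#' well approximated by the normal, so a small p-value indicates deviance.
#'
#' @inheritParams make_reference_bins
#' @return A list of class `chisq_result` with `statistic`, `df`, `p`, plus
#'   the `bin_summary` as attribute `"bins"`.
#' @export
norm_approx_test <- function(x, k, seed,
                             mode = c("equal_width", "equal_quantile")) {
  bins <- make_reference_bins(x, k, seed, mode = match.arg(mode))
  out <- paired_count_chisq(bins$obs_counts, bins$ref_counts)
  attr(out, "bins") <- bins
  out
}

#' Classic chi-square goodness-of-fit test against a fitted normal
#'
#' Conventional counterpart to [norm_approx_test()]: expected counts come
#' from the `Normal(mean(x), sd(x))` cumulative distribution over `k`
#' equal-width bins of `[min(x), max(x)]` (first/last break at infinity), and
#' the statistic is the usual `sum((O - E)^2 / E)` with `df = k - 3` (two
#' estimated parameters).
#'
#' @param x Numeric vector.
#' @param k Number of bins.
#' @return A list of class `chisq_result` with `statistic`, `df`, `p` and an
#'   attribute `"expected"` of expected counts.
#' @export
classic_gof_test <- function(x, k) {
  x <- x[is.finite(x)]
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(x) < k) stop("need at least k finite observations", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("sd(x) is zero", call. = FALSE)
  breaks <- seq(min(x), max(x), length.out = k + 1)
  breaks[1] <- -Inf
  breaks[k + 1] <- Inf
  obs <- bin_counts(x, breaks)
  p_bins <- diff(stats::pnorm(breaks, mean(x), s))
  expected <- length(x) * p_bins
  if (any(expected < 1)) {
    warning("expected count below 1 in ", sum(expected < 1),
            " bin(s); the chi-square approximation may be poor")
  }
  statistic <- sum((obs - expected)^2 / expected)
  df <- as.integer(k - 3)
  out <- structure(list(statistic = statistic, df = df,
                        p = stats::pchisq(statistic, df, lower.tail = FALSE)),
                   class = "chisq_result")
  attr(out, "expected") <- expected
  out
}

#' @export
print.chisq_result <- function(x, ...) {
  cat("Chi-square result: X-squared =", format(x$statistic, digits = 6),
      ", df =", x$df, ", p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' @export
print.bin_summary <- function(x, ...) {
  cat("Bin summary: k =", x$k, ", n =", x$n, ", mode =", x$mode, "\n")
  cat(" obs counts:", utils::head(x$obs_counts, 10),
      if (x$k > 10) "..." else "", "\n")
  cat(" ref counts:", utils::head(x$ref_counts, 10),
      if (x$k > 10) "..." else "", "\n")
  invisible(x)
}
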