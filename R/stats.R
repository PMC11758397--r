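# cache of exact Mann-Whitney U null distributions, keyed by "n1,n2"
.u_null_cache <- new.env(parent = emptyenv())

# counts of rank configurations giving each U in 0..n1*n2 (no ties);
# classic count-partitions dynamic programme, equivalent to enumerating
# all choose(n1+n2, n1) labelings
u_null_counts <- function(n1, n2) {
  key <- paste(n1, n2, sep = ",")
  if (!is.null(.u_null_cache[[key]])) return(.u_null_cache[[key]])
  # f[[m]][u+1] = number of m-subsets with U = u, built by adding samples
  f <- matrix(0, nrow = n1 + 1, ncol = n1 * n2 + 1)
  f[1, 1] <- 1
  for (j in seq_len(n1 + n2)) {
    # adding the j-th smallest rank: either to x (raising U by the number
    # of y seen so far) or to y
    for (m in rev(seq_len(min(j, n1)))) {
      ny <- j - m  # y count if this one goes to x
      if (ny > n2) next
      shift <- ny
      prev <- f[m, ]
      # contribution: choose the largest rank as x; U gains (# y below) = ny
      f[m + 1, (shift + 1):(n1 * n2 + 1)] <-
        f[m + 1, (shift + 1):(n1 * n2 + 1)] + prev[1:(n1 * n2 + 1 - shift)]
    }
  }
  counts <- f[n1 + 1, ]
  .u_null_cache[[key]] <- counts
  counts
}

two_sided_from_tails <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Wilcoxon Mann-Whitney U test
#'
#' Two-sided two-sample rank test. When both samples have at most
#' `exact_n_max` observations the p-value is exact: without ties it
#' comes from the full null distribution of U (count-partitions
#' recursion over all rank labelings); with ties, from complete
#' enumeration of the label assignments when feasible. Otherwise the
#' normal approximation with tie and continuity corrections is used.
#' Two-sided p doubles the smaller exact tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_n_max Largest per-group n for the exact route.
#' @param max_enum Largest number of label assignments enumerated for
#'   the tied-data exact route.
#' @return List (`test_result`): `statistic` (U, the smaller of U1/U2),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`,
#'   `tie_correction` (logical).
#' @export
mann_whitney_u <- function(x, y, exact_n_max = 10, max_enum = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0L
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)

  if (n1 <= exact_n_max && n2 <= exact_n_max) {
    if (!ties) {
      counts <- u_null_counts(n1, n2)
      tot <- sum(counts)
      p_le <- sum(counts[seq_len(u1 + 1)]) / tot
      p_ge <- sum(counts[(u1 + 1):length(counts)]) / tot
      return(structure(list(statistic = u,
                            p_value = two_sided_from_tails(p_le, p_ge),
                            method = "exact", n1 = n1, n2 = n2,
                            tie_correction = FALSE),
                       class = "test_result"))
    }
    if (choose(n1 + n2, n1) <= max_enum) {
      combos <- utils::combn(n1 + n2, n1)
      rks <- matrix(rk[combos], nrow = n1)
      u_perm <- colSums(rks) - n1 * (n1 + 1) / 2
      p_le <- mean(u_perm <= u1 + 1e-9)
      p_ge <- mean(u_perm >= u1 - 1e-9)
      return(structure(list(statistic = u,
                            p_value = two_sided_from_tails(p_le, p_ge),
                            method = "exact", n1 = n1, n2 = n2,
                            tie_correction = TRUE),
                       class = "test_result"))
    }
  }
  # normal approximation, tie-corrected sigma, continuity correction
  N <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  structure(list(statistic = u,
                 p_value = min(1, 2 * stats::pnorm(-abs(z))),
                 method = "normal_approx", n1 = n1, n2 = n2,
                 tie_correction = ties),
            class = "test_result")
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided paired rank test on the differences `post - pre`. Zero
#' differences are dropped (Wilcoxon's treatment; `zero_method =
#' "pratt"` keeps them in the ranking but excludes them from the
#' statistic). With at most `exact_n_max` nonzero differences the
#' p-value is exact by enumeration of all 2^n sign patterns; otherwise
#' the tie-corrected normal approximation with continuity correction
#' applies.
#'
#' @param pre,post Equal-length numeric vectors.
#' @param exact_n_max Largest n for the exact route.
#' @param zero_method `"drop"` or `"pratt"`.
#' @return List (`test_result`): `statistic` (W+, sum of positive
#'   ranks), `p_value`, `method`, `n_pairs` (nonzero differences),
#'   `tie_correction`, `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_n_max = 12,
                                 zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(pre) != length(post)) stop("unequal lengths", call. = FALSE)
  d <- post - pre
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    return(structure(list(statistic = 0, p_value = 1, method = "exact",
                          n_pairs = 0L, tie_correction = FALSE,
                          all_zero = TRUE), class = "test_result"))
  }
  if (zero_method == "drop") d <- d[d != 0]
  r <- rank(abs(d))
  if (zero_method == "pratt") {
    keep <- d != 0
    r <- r[keep]; d <- d[keep]
  }
  n <- length(d)
  w_pos <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L

  if (n <= exact_n_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_perm <- as.numeric(signs %*% r)
    p_le <- mean(w_perm <= w_pos + 1e-9)
    p_ge <- mean(w_perm >= w_pos - 1e-9)
    return(structure(list(statistic = w_pos,
                          p_value = two_sided_from_tails(p_le, p_ge),
                          method = "exact", n_pairs = n,
                          tie_correction = ties, all_zero = FALSE),
                     class = "test_result"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
  structure(list(statistic = w_pos,
                 p_value = min(1, 2 * stats::pnorm(-abs(z))),
                 method = "normal_approx", n_pairs = n,
                 tie_correction = ties, all_zero = FALSE),
            class = "test_result")
}

#' Box-and-whisker summary
#'
#' Quartiles by linear interpolation (type 7); whiskers at the farthest
#' data points within 1.5 interquartile ranges of the quartiles; points
#' beyond the fences are outliers.
#'
#' @param values Numeric vector, n >= 1.
#' @return List with `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no data", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Group mean and sample standard deviation
#'
#' @param values Numeric vector, n >= 1.
#' @return List with `mean`, `sd` (n-1 estimator; 0 with `n1_flag` when
#'   n = 1), `n`, `n1_flag`.
#' @export
group_mean_sd <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no data", call. = FALSE)
  list(mean = mean(values),
       sd = if (n == 1L) 0 else stats::sd(values),
       n = n, n1_flag = n == 1L)
}
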