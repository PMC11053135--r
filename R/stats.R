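# Exact small-sample nonparametric tests. The exact null distributions are
# computed by count-generating dynamic programming over doubled midranks,
# which tallies exactly the same 2^m sign assignments (signed-rank) or
# C(n1 + n2, n1) labelings (rank-sum) that brute-force enumeration would
# visit; all counts stay below 2^53, so the arithmetic is exact in doubles
# for every sample size the exact path accepts.

new_stat_result <- function(method, statistic, p_value, alternative, n,
                            exact, ties = FALSE, note = NULL) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         alternative = alternative, n = n, exact = exact, ties = ties,
         note = note),
    class = "ees_stat")
}

#' @export
print.ees_stat <- function(x, ...) {
  cat(sprintf("<%s>%s\n", x$method, if (x$exact) " (exact)" else " (approximate)"))
  cat(sprintf("  %s = %g, p = %.6g, alternative: %s, n = %s\n",
              names(x$statistic)[1L], x$statistic[1L], x$p_value,
              x$alternative, paste(x$n, collapse = "/")))
  if (x$ties) cat("  ties handled with midranks\n")
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

# Exact distribution of a sum of a subset of (doubled, integer) ranks:
# returns counts over achievable sums 0..sum(r2) of including each rank
# independently (signed-rank null).
signed_rank_counts <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1L] <- 1
  for (rr in r2) f <- f + c(rep(0, rr), f[seq_len(total + 1L - rr)])
  f
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank test with the exact null distribution obtained
#' by enumerating all `2^m` sign assignments of the nonzero absolute
#' differences (midranks for tied magnitudes). Zero differences are dropped
#' before ranking. The statistic is W, the sum of positive-difference ranks.
#' Two-sided p-values use the doubling convention
#' `min(1, 2 * min(lower tail, upper tail))`. The exact path is used whenever
#' `m <= 25` (and can be forced); larger samples fall back to the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x Numeric vector: first member of each pair, or the differences
#'   themselves when `y` is `NULL`.
#' @param y Optional numeric vector paired with `x`.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`. Sidedness is never inferred from the data.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` chooses exact for `m <= 25`.
#' @return An object of class `ees_stat` with the W statistic, p-value,
#'   alternative, sample size, and exact/tie flags.
#' @examples
#' wilcoxon_exact(c(3077, 4600, 9500, 14500, 2070),
#'                c(80, 3400, 1100, 5700, 81), alternative = "greater")
#' @export
wilcoxon_exact <- function(x, y = NULL,
                           alternative = c("two.sided", "greater", "less"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y))
      stop_invalid("`x` and `y` must have equal length (paired test)")
    x - y
  }
  if (length(d) < 1L) stop_invalid("at least one pair is required")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    stop_invalid("degenerate test: all paired differences are zero")
  r <- rank(abs(d))
  has_ties <- anyDuplicated(abs(d)) > 0L
  W <- sum(r[d > 0])
  if (is.null(exact)) exact <- m <= 25L

  if (exact) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_counts(r2)
    total <- length(f) - 1L
    w2 <- as.integer(round(2 * W))
    n_assign <- 2^m
    p_greater <- sum(f[(w2 + 1L):(total + 1L)]) / n_assign
    p_less <- sum(f[seq_len(w2 + 1L)]) / n_assign
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    s <- sqrt(sigma2)
    p_greater <- stats::pnorm((W - 0.5 - mu) / s, lower.tail = FALSE)
    p_less <- stats::pnorm((W + 0.5 - mu) / s)
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  new_stat_result("Wilcoxon signed-rank", c(W = W), p, alternative,
                  n = c(pairs = m), exact = exact, ties = has_ties,
                  note = if (n_zero > 0)
                    sprintf("%d zero difference(s) dropped", n_zero))
}

# Exact distribution of the rank sum of the first group: counts[k + 1, s + 1]
# = number of ways to pick k of the pooled (doubled) ranks summing to s.
rank_sum_counts <- function(r2, n1) {
  total <- sum(r2)
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (rr in r2) {
    for (k in n1:1L) {
      src <- f[k, seq_len(total + 1L - rr)]
      f[k + 1L, (rr + 1L):(total + 1L)] <-
        f[k + 1L, (rr + 1L):(total + 1L)] + src
    }
  }
  f[n1 + 1L, ]
}

#' Exact Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Unpaired two-sample rank test with the exact null distribution obtained by
#' enumerating all `choose(n1 + n2, n1)` assignments of the pooled ranks
#' (midranks under ties) to the first group. Reports the Mann-Whitney U
#' statistic for `x`. Two-sided p-values use the doubling convention
#' `min(1, 2 * min(lower tail, upper tail))`, capped at 1. The exact path is
#' used whenever `min(n1, n2) <= 25`; larger designs fall back to the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (each at least one observation).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact Force or forbid exact enumeration; default `NULL` chooses
#'   exact for `min(n1, n2) <= 25`.
#' @return An object of class `ees_stat`.
#' @examples
#' # complete separation, group sizes 4 and 5: p = 2/126
#' mannwhitney_exact(1:4, 5:9)
#' @export
mannwhitney_exact <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact = NULL) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_invalid("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  has_ties <- anyDuplicated(pooled) > 0L
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- min(n1, n2) <= 25L

  if (exact) {
    r2 <- as.integer(round(2 * r))
    counts <- rank_sum_counts(r2, n1)
    n_assign <- choose(n1 + n2, n1)
    R1d <- as.integer(round(2 * R1))
    total <- length(counts) - 1L
    p_greater <- sum(counts[(R1d + 1L):(total + 1L)]) / n_assign
    p_less <- sum(counts[seq_len(R1d + 1L)]) / n_assign
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    s <- sqrt(sigma2)
    p_greater <- stats::pnorm((U - 0.5 - mu) / s, lower.tail = FALSE)
    p_less <- stats::pnorm((U + 0.5 - mu) / s)
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  new_stat_result("Mann-Whitney", c(U = U), p, alternative,
                  n = c(n1 = n1, n2 = n2), exact = exact, ties = has_ties)
}

#' Kruskal-Wallis rank test
#'
#' H statistic on pooled midranks with the standard tie correction. The
#' p-value uses the chi-square approximation with `k - 1` degrees of freedom
#' by default; `exact = TRUE` enumerates all distinct group labelings of the
#' pooled sample (feasible only for small pooled sizes, guarded at N <= 10)
#' and returns the exact permutation p-value `P(H* >= H)`.
#'
#' @param groups List of numeric vectors, at least two, each non-empty.
#' @param exact Use full permutation enumeration for the p-value.
#' @return An object of class `ees_stat` with the H statistic.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6))) # H = 32/7
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  k <- length(groups)
  if (k < 2L) stop_invalid("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop_invalid("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  H <- kw_statistic(rank(pooled), rep(seq_len(k), sizes), sizes)
  if (is.na(H)) { # all pooled values identical
    return(new_stat_result("Kruskal-Wallis", c(H = 0), 1, "two.sided",
                           n = sizes, exact = FALSE, ties = TRUE,
                           note = "all values identical"))
  }
  has_ties <- anyDuplicated(pooled) > 0L
  if (exact) {
    if (N > 10L)
      stop_invalid("exact permutation Kruskal-Wallis is limited to N <= 10")
    r <- rank(pooled)
    perms <- group_assignments(N, sizes)
    Hs <- vapply(perms, function(g) kw_statistic(r, g, sizes), numeric(1))
    p <- mean(Hs >= H - 1e-12)
  } else {
    p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  }
  new_stat_result("Kruskal-Wallis", c(H = H), p, "two.sided", n = sizes,
                  exact = exact, ties = has_ties)
}

# Tie-corrected H for given pooled ranks r and group labels g; NA when the
# tie correction degenerates (all values identical).
kw_statistic <- function(r, g, sizes) {
  N <- length(r)
  Rsum <- vapply(split(r, g), sum, numeric(1))
  H_raw <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  tie_tab <- table(r)
  Cties <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (Cties == 0) return(NA_real_)
  H_raw / Cties
}

# All distinct assignments of N pooled positions to groups of the given
# sizes, as integer label vectors.
group_assignments <- function(N, sizes) {
  assignments <- list(list(avail = seq_len(N), labels = integer(N)))
  for (gi in seq_along(sizes)) {
    nxt <- list()
    last <- gi == length(sizes)
    for (a in assignments) {
      if (last) {
        lab <- a$labels
        lab[a$avail] <- gi
        nxt[[length(nxt) + 1L]] <- lab
      } else {
        picks <- utils::combn(length(a$avail), sizes[gi], simplify = FALSE)
        for (p in picks) {
          lab <- a$labels
          lab[a$avail[p]] <- gi
          nxt[[length(nxt) + 1L]] <- list(avail = a$avail[-p], labels = lab)
        }
      }
    }
    assignments <- nxt
  }
  assignments
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from mean-rank differences after a Kruskal-Wallis
#' test, with tie-corrected pooled variance, two-sided normal p-values and
#' optional multiplicity adjustment. The default is no adjustment;
#' `"bonferroni"` multiplies each p by the number of pairs (capped at 1) and
#' `"holm"` applies the step-down correction.
#'
#' @param groups List of numeric vectors (as in [kruskal_wallis()]).
#' @param adjust `"none"`, `"bonferroni"` or `"holm"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 2L) stop_invalid("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop_invalid("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_len(k), sizes)
  rbar <- vapply(split(r, g), mean, numeric(1))
  tie_tab <- table(pooled)
  var_base <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    se <- sqrt(var_base * (1 / sizes[i1] + 1 / sizes[i2]))
    z <- if (se == 0) 0 else (rbar[i1] - rbar[i2]) / se
    data.frame(group1 = nm[i1], group2 = nm[i2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Mean and standard error
#'
#' @param values Numeric vector, at least one observation.
#' @return A list of class `summary_stat` with `mean`, `se` (sample SD over
#'   `sqrt(n)`; 0 by convention when `n = 1`, flagged via `single`), and `n`.
#' @examples
#' mean_se(c(2, 4)) # mean 3, SE 1
#' @export
mean_se <- function(values) {
  n <- length(values)
  if (n < 1L) stop_invalid("at least one value is required")
  structure(
    list(mean = mean(values),
         se = if (n == 1L) 0 else stats::sd(values) / sqrt(n),
         n = n, single = n == 1L),
    class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf("mean %.6g +/- %.6g SE (n = %d%s)\n", x$mean, x$se, x$n,
              if (x$single) ", SE = 0 by convention for n = 1" else ""))
  invisible(x)
}
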