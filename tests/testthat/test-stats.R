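test_that("five positive differences give one-sided p = 1/32", {
  res <- wilcoxon_exact(c(5, 12, 3, 40, 7), rep(0, 5),
                        alternative = "greater")
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)
  expect_equal(res$statistic[["W"]], 15)
})

test_that("zero differences are dropped and all-zero input is degenerate", {
  res <- wilcoxon_exact(c(1, 2, 3, 4), c(1, 2, 1, 1))
  expect_equal(res$n[["pairs"]], 2)
  expect_match(res$note, "2 zero difference")
  expect_error(wilcoxon_exact(c(1, 2), c(1, 2)), "degenerate")
})

test_that("signed-rank p-values agree with brute-force enumeration", {
  set.seed(101)
  for (i in seq_len(60)) {
    m <- sample(3:8, 1)
    # mix of continuous values and small integers to provoke ties
    d <- if (i %% 2) round(rnorm(m), 0) else rnorm(m)
    d[d == 0] <- 0.5
    alt <- sample(c("two.sided", "greater", "less"), 1)
    expect_equal(wilcoxon_exact(d, alternative = alt)$p_value,
                 brute_wilcoxon(d, alternative = alt),
                 info = paste("case", i))
  }
})

test_that("signed-rank agrees with the reference implementation when tie-free", {
  set.seed(7)
  for (i in seq_len(20)) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(wilcoxon_exact(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("complete separation gives the analytic rank-sum limits", {
  expect_equal(mannwhitney_exact(1:4, 5:9)$p_value, 2 / 126)
  expect_equal(mannwhitney_exact(1:3, 4:8)$p_value, 2 / 56)
  expect_equal(mannwhitney_exact(101:104, 5:9)$p_value, 2 / 126)
  # identical samples are maximally non-significant
  expect_equal(mannwhitney_exact(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("rank-sum p-values agree with brute-force enumeration", {
  set.seed(202)
  for (i in seq_len(60)) {
    n1 <- sample(2:5, 1); n2 <- sample(2:(8 - n1 + 1), 1)
    pool <- if (i %% 2) sample(1:4, n1 + n2, replace = TRUE) else rnorm(n1 + n2)
    x <- pool[seq_len(n1)]; y <- pool[-seq_len(n1)]
    alt <- sample(c("two.sided", "greater", "less"), 1)
    expect_equal(mannwhitney_exact(x, y, alternative = alt)$p_value,
                 brute_mannwhitney(x, y, alternative = alt),
                 info = paste("case", i))
  }
})

test_that("rank tests are invariant to monotone transformations", {
  set.seed(11)
  x <- rexp(6); y <- rexp(7) + 0.3
  p1 <- mannwhitney_exact(x, y)$p_value
  expect_equal(mannwhitney_exact(log(x), log(y))$p_value, p1)
  expect_equal(mannwhitney_exact(x^3, y^3)$p_value, p1)
  d <- rnorm(6)
  f <- function(v) sign(v) * abs(v)^1.7 # odd monotone map keeps signs/ranks
  expect_equal(wilcoxon_exact(f(d))$p_value, wilcoxon_exact(d)$p_value)
})

test_that("the exact signed-rank test holds its nominal size", {
  set.seed(303)
  n_rep <- 10000
  rejections <- 0
  for (i in seq_len(n_rep)) {
    d <- rnorm(8)
    rejections <- rejections + (wilcoxon_exact(d)$p_value <= 0.05)
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rejections / n_rep, 0.05 + 2 * mc_se)
})

test_that("Kruskal-Wallis H matches hand computation and handles ties", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$statistic[["H"]], 32 / 7, tolerance = 1e-9)
  expect_equal(res$p_value,
               pchisq(32 / 7, df = 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(same$statistic[["H"]], 0)
  expect_equal(same$p_value, 1)

  # cross-check against the reference implementation, with ties
  g <- list(c(1, 2, 2, 5), c(2, 3, 9), c(4, 4, 4, 7, 1))
  ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
  mine <- kruskal_wallis(g)
  expect_equal(mine$statistic[["H"]], unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
})

test_that("H depends only on the grouping, not on ordering or group labels", {
  set.seed(17)
  x <- c(3, 1, 4); y <- c(1, 5, 9, 2, 6)
  H <- function(g) kruskal_wallis(g)$statistic[["H"]]
  expect_equal(H(list(x, y)), H(list(y, x)))
  expect_equal(H(list(sample(x), sample(y))), H(list(x, y)))
})

test_that("exact permutation Kruskal-Wallis p matches direct enumeration", {
  x <- c(1, 2); y <- c(3, 4); z <- c(5, 6)
  res <- kruskal_wallis(list(x, y, z), exact = TRUE)
  # direct enumeration over all 6!/(2!2!2!) = 90 assignments of ranks 1..6
  pool <- c(x, y, z)
  splits <- 0; hits <- 0
  for (a in utils::combn(6, 2, simplify = FALSE)) {
    rest <- setdiff(1:6, a)
    for (b in utils::combn(4, 2, simplify = FALSE)) {
      g <- list(pool[a], pool[rest[b]], pool[rest[-b]])
      splits <- splits + 1
      hits <- hits +
        (kruskal_wallis(g)$statistic[["H"]] >= res$statistic[["H"]] - 1e-12)
    }
  }
  expect_equal(res$p_value, hits / splits)
  expect_error(kruskal_wallis(list(1:6, 1:6), exact = TRUE), "N <= 10")
})

test_that("Dunn post-hoc comparisons behave at the boundaries", {
  d <- dunn_posthoc(list(a = c(1, 2), b = c(1, 2), c = c(9, 10)))
  ab <- d[d$group1 == "a" & d$group2 == "b", ]
  expect_equal(ab$p, 1) # identical groups
  extreme <- d[order(-abs(d$z)), ][1, ]
  expect_true((extreme$group1 == "a" & extreme$group2 == "c") ||
                (extreme$group1 == "b" & extreme$group2 == "c"))

  d2 <- dunn_posthoc(list(c(1, 2), c(3, 4), c(5, 6)), adjust = "bonferroni")
  d0 <- dunn_posthoc(list(c(1, 2), c(3, 4), c(5, 6)), adjust = "none")
  expect_equal(d2$p_adj, pmin(1, d0$p * 3))

  # the extreme pair has the largest |z|
  expect_equal(which.max(abs(d0$z)), which(d0$group1 == "group1" &
                                             d0$group2 == "group3"))
})

test_that("mean_se follows the stated conventions", {
  ms <- mean_se(c(2, 4))
  expect_equal(ms$mean, 3)
  expect_equal(ms$se, 1)
  one <- mean_se(5)
  expect_equal(one$se, 0)
  expect_true(one$single)
  expect_equal(mean_se(rep(7, 4))$se, 0)
})
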