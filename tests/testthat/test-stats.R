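test_that("Kruskal-Wallis H matches the brute-force rank formula", {
  expect_equal(unname(kruskal_wallis(list(a = 1:4, b = 1:4))$statistic), 0)

  res <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(unname(res$statistic), 7.2)  # textbook rank-sum value
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # random integer fixtures (ties included) against the brute-force ranker
  # and against the reference implementation in base R
  set.seed(42)
  for (i in 1:20) {
    g <- replicate(sample(2:4, 1),
                   sample.int(8, sample(3:8, 1), replace = TRUE),
                   simplify = FALSE)
    names(g) <- paste0("g", seq_along(g))
    h <- unname(kruskal_wallis(g)$statistic)
    expect_equal(h, bf_kw_h(g))
    ref <- kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(h, unname(ref$statistic))
    expect_equal(kruskal_wallis(g)$p_value, unname(ref$p.value))
  }

  # rank invariance under strictly increasing transforms
  g <- list(a = c(0.1, 0.9, 2.3), b = c(1.1, 3.2, 0.4), c = c(5, 2, 7))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(v) exp(v) + 10))$statistic)

  # all observations identical: H = 0, p = 1, no error
  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2, 2)))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)
})

test_that("Dunn post hoc z and Bonferroni adjustment match hand computation", {
  ident <- dunn_posthoc(list(a = 1:5, b = 1:5, c = 1:5))
  expect_true(all(ident$pairwise$p_adj == 1))

  # 3 x 4 fixture, frozen from the textbook mean-rank formula with tie
  # correction (mid-ranks, sigma^2 = N(N+1)/12 - sum(t^3 - t)/(12(N-1)))
  res <- dunn_posthoc(list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8),
                           c = c(2, 4, 6, 8)))
  expect_equal(res$pairwise$z,
               c(-2.3700256, -1.4812660, 0.8887596), tolerance = 1e-7)
  expect_equal(res$pairwise$p_adj,
               c(0.05336056, 0.41560712, 1.0), tolerance = 1e-7)
  # adjustment multiplies raw p by the number of pairs, capped at 1
  expect_equal(res$pairwise$p_adj, pmin(1, res$pairwise$p_raw * 3))
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))

  # widely separated groups: every pair flagged (adjacent-group z is capped
  # by the ranks at n = 10, so 0.05 is the attainable level for all pairs)
  sep <- dunn_posthoc(list(a = 1:10, b = 101:110, c = 201:210), alpha = 0.05)
  expect_true(all(sep$pairwise$significant))

  expect_error(dunn_posthoc(list(a = 1:5)), "2 groups")
})

test_that("Mann-Whitney U by pair counting with exact enumeration p", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(res$statistic), bf_u_stat(c(1, 2), c(3, 4)))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 2 / choose(4, 2))  # full labelling enumeration

  # identical multisets: U = n^2 / 2 and p = 1
  res <- mann_whitney(1:6, 1:6)
  expect_equal(unname(res$statistic), 18)
  expect_equal(res$p_value, 1)

  # exact p agrees with full-permutation enumeration for all small fixtures,
  # with and without ties
  set.seed(99)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    withties <- i %% 2 == 0
    a <- if (withties) sample.int(4, na, replace = TRUE) else runif(na)
    b <- if (withties) sample.int(4, nb, replace = TRUE) else runif(nb)
    res <- mann_whitney(a, b)
    expect_equal(unname(res$statistic), bf_u_stat(a, b))
    expect_equal(res$p_value, bf_mw_exact_p(a, b))
  }

  # no-ties exact branch agrees with the reference implementation
  set.seed(100)
  a <- runif(8); b <- runif(9)
  expect_equal(mann_whitney(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value)
  expect_equal(unname(mann_whitney(a, b)$statistic),
               unname(wilcox.test(a, b)$statistic))

  # large samples switch to the tie-corrected normal approximation
  set.seed(101)
  a <- rnorm(25); b <- rnorm(25)
  res <- mann_whitney(a, b)
  expect_match(res$method, "normal approximation")
  expect_equal(res$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)

  # rank invariance
  expect_equal(mann_whitney(exp(a), exp(b))$statistic, res$statistic)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("one-way ANOVA F and Bonferroni pairs match hand computation", {
  # 3 x 3 integer fixture: SSB = 42, SSW = 6 -> F = 21 on (2, 6) df
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- one_way_anova_bonferroni(g)
  expect_equal(unname(res$statistic), 21)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, pf(21, 2, 6, lower.tail = FALSE))

  # sum-of-squares decomposition and location invariance
  x <- unlist(g)
  ssb <- sum(3 * (sapply(g, mean) - mean(x))^2)
  ssw <- sum(sapply(g, function(v) sum((v - mean(v))^2)))
  expect_equal(sum((x - mean(x))^2), ssb + ssw)
  shifted <- one_way_anova_bonferroni(lapply(g, `+`, 100))
  expect_equal(shifted$statistic, res$statistic)

  # pairwise Bonferroni p values match pooled-SD t tests scaled by 3
  raw <- stats::pairwise.t.test(x, rep(names(g), lengths(g)), pool.sd = TRUE,
                                p.adjust.method = "none")$p.value
  expect_equal(sort(res$pairwise$p_adj),
               sort(pmin(1, as.vector(raw[!is.na(raw)]) * 3)))

  degen <- one_way_anova_bonferroni(list(a = c(1, 1), b = c(1, 1)))
  expect_true(degen$degenerate)
  expect_error(one_way_anova_bonferroni(list(a = 1, b = 1:3)), "n >= 2")
})

test_that("type-I error simulation is calibrated and respects alpha bounds", {
  expect_equal(type1_error_sim("kw", 10, 3, reps = 100, alpha = 1,
                               seed = 1)$rate, 1)
  expect_equal(type1_error_sim("kw", 10, 3, reps = 100, alpha = 0,
                               seed = 1)$rate, 0)
  sim <- type1_error_sim("mw", 10, reps = 400, alpha = 0.05, seed = 2)
  expect_gte(sim$rate, 0.05 - qnorm(0.995) * sqrt(0.05 * 0.95 / 400))
  expect_lte(sim$rate, 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / 400))
})
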