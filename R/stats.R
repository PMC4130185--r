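as_group_data <- function(data) {
  if (is.data.frame(data) && all(c("group", "value") %in% names(data)))
    data <- split(data$value, data$group)
  if (!is.list(data) || length(data) < 2)
    stop("need a named list of >= 2 groups (or a group/value data.frame)")
  if (is.null(names(data)) || any(!nzchar(names(data))))
    names(data) <- paste0("group", seq_along(data))
  data <- lapply(data, function(g) as.numeric(na.omit(g)))
  if (any(lengths(data) == 0)) stop("every group must be non-empty")
  data
}

tie_sizes <- function(x) {
  t <- table(x)
  as.numeric(t[t > 1])
}

#' Kruskal-Wallis rank test for k groups
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = k - 1). Ranks are mid-ranks for ties. When every observation is
#' identical the statistic is 0 and p = 1 (returned, not an error).
#'
#' @param data Named list of numeric vectors, or a data.frame with `group`
#'   and `value` columns.
#' @return A list of class `hq_test`: `method`, `statistic` (H), `df`,
#'   `p_value`, `n`, mean ranks per group.
#' @export
kruskal_wallis <- function(data) {
  g <- as_group_data(data)
  x <- unlist(g, use.names = FALSE)
  n <- lengths(g)
  N <- length(x)
  if (N < 3) stop("need at least 3 observations in total")
  r <- rank(x)
  grp <- rep(seq_along(g), n)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ts <- tie_sizes(x)
  C <- 1 - sum(ts^3 - ts) / (N^3 - N)
  if (C <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / C
    p <- pchisq(H, df = length(g) - 1, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis rank sum test (tie-corrected)",
                 statistic = c(H = H), df = length(g) - 1, p_value = p,
                 n = n, mean_ranks = as.numeric(rbar),
                 groups = names(g)),
            class = "hq_test")
}

#' Dunn's multiple-comparison post hoc test
#'
#' Pairwise z statistics from the mean ranks of the pooled ranking with the
#' standard tie correction, two-sided normal p values, Bonferroni-adjusted
#' across all `k (k - 1) / 2` pairs and capped at 1.
#'
#' @param data Named list of numeric vectors, or a `group`/`value`
#'   data.frame.
#' @param alpha Significance level used for the `significant` flags.
#' @return A list of class `hq_test` with a `pairwise` data.frame:
#'   `group1`, `group2`, `z`, `p_raw`, `p_adj`, `significant`.
#' @export
dunn_posthoc <- function(data, alpha = 0.05) {
  g <- as_group_data(data)
  k <- length(g)
  x <- unlist(g, use.names = FALSE)
  n <- lengths(g)
  N <- length(x)
  r <- rank(x)
  grp <- rep(seq_along(g), n)
  rbar <- tapply(r, grp, mean)
  ts <- tie_sizes(x)
  sigma2 <- N * (N + 1) / 12 - sum(ts^3 - ts) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / n[i1] + 1 / n[i2]))
    z[j] <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    p_raw[j] <- 2 * pnorm(-abs(z[j]))
  }
  p_adj <- pmin(1, p_raw * m)
  structure(list(method = "Dunn's post hoc test (Bonferroni-adjusted)",
                 alpha = alpha,
                 pairwise = data.frame(
                   group1 = names(g)[pairs[1, ]],
                   group2 = names(g)[pairs[2, ]],
                   z = z, p_raw = p_raw, p_adj = p_adj,
                   significant = p_adj < alpha)),
            class = "hq_test")
}

#' Mann-Whitney U test
#'
#' U counts pairs where the first group exceeds the second (ties count one
#' half). The p value is exact whenever `length(a) * length(b) <= exact_limit`:
#' from the exact null distribution of U when there are no ties, and by full
#' enumeration of group labelings when there are ties and the enumeration is
#' feasible; otherwise the normal approximation with tie correction and
#' continuity correction is used. The method actually applied is recorded in
#' the result.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact_limit Largest `n_a * n_b` for which an exact p is attempted.
#' @param max_enumeration Largest `choose(n, n_a)` enumerated when ties force
#'   a permutation p value.
#' @return A list of class `hq_test`: `statistic` (U for `a` over `b`),
#'   `p_value` (two-sided), `method`, group sizes and medians.
#' @export
mann_whitney <- function(a, b, exact_limit = 400, max_enumeration = 2e5) {
  a <- as.numeric(na.omit(a)); b <- as.numeric(na.omit(b))
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty")
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # pairs a > b, ties 1/2
  mu <- na * nb / 2
  ties <- anyDuplicated(x) > 0
  if (na * nb <= exact_limit && !ties) {
    p <- min(1, 2 * min(pwilcox(U, na, nb), 1 - pwilcox(U - 1, na, nb)))
    method <- "exact (null distribution of U)"
  } else if (na * nb <= exact_limit && choose(na + nb, na) <= max_enumeration) {
    combs <- utils::combn(na + nb, na)
    offset <- na * (na + 1) / 2
    ustat <- colSums(matrix(r[combs], nrow = na)) - offset
    p <- mean(abs(ustat - mu) >= abs(U - mu) - 1e-9)
    method <- "exact (permutation enumeration, ties)"
  } else {
    ts <- tie_sizes(x)
    N <- na + nb
    sigma <- sqrt(na * nb / 12 * ((N + 1) - sum(ts^3 - ts) / (N * (N - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
      p <- min(1, 2 * pnorm(-abs((U - mu - cc) / sigma)))
    }
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  structure(list(method = paste("Mann-Whitney U test,", method),
                 statistic = c(U = U), p_value = p,
                 n = c(a = na, b = nb),
                 median_a = median(a), median_b = median(b)),
            class = "hq_test")
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Classical fixed-effects one-way ANOVA (F = MS_between / MS_within) with
#' pooled-SD pairwise t tests, Bonferroni-adjusted. Zero total variance is
#' returned as a flagged degenerate result rather than an error.
#'
#' @param data Named list of numeric vectors, or a `group`/`value`
#'   data.frame.
#' @return A list of class `hq_test`: `statistic` (F), `df`, `p_value`,
#'   `pairwise` data.frame (`group1`, `group2`, `p_adj`), `degenerate` flag.
#' @export
one_way_anova_bonferroni <- function(data) {
  g <- as_group_data(data)
  if (any(lengths(g) < 2)) stop("every group needs n >= 2")
  df <- data.frame(value = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), lengths(g)),
                                  levels = names(g)))
  if (sd(df$value) == 0) {
    return(structure(list(method = "One-way ANOVA (degenerate: zero variance)",
                          statistic = c(F = NA_real_), df = c(NA, NA),
                          p_value = NA_real_, pairwise = NULL,
                          degenerate = TRUE),
                     class = "hq_test"))
  }
  fit <- aov(value ~ group, data = df)
  tab <- anova(fit)
  pw <- stats::pairwise.t.test(df$value, df$group, pool.sd = TRUE,
                               p.adjust.method = "bonferroni")
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  structure(list(method = "One-way ANOVA with Bonferroni post hoc t tests",
                 statistic = c(F = tab$`F value`[1]),
                 df = c(tab$Df[1], tab$Df[2]),
                 p_value = tab$`Pr(>F)`[1],
                 pairwise = data.frame(
                   group1 = rownames(pm)[pairs[, 1]],
                   group2 = colnames(pm)[pairs[, 2]],
                   p_adj = pm[pairs]),
                 degenerate = FALSE),
            class = "hq_test")
}

#' @export
print.hq_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && length(x$statistic))
    cat(sprintf("  %s = %.4g", names(x$statistic)[1], x$statistic[1]),
        if (!is.null(x$p_value)) sprintf(", p = %.4g", x$p_value), "\n",
        sep = "")
  if (!is.null(x$pairwise)) {
    cat("  pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Monte-Carlo type-I error of the implemented tests
#'
#' Simulates all-null standard-Gaussian groups and returns the fraction of
#' replicates rejected at `alpha`, with a 99% normal-approximation interval
#' around the nominal level for calibration checks.
#'
#' @param test One of `"kw"`, `"mw"`, `"anova"`.
#' @param n_per_group Observations per group.
#' @param k_groups Number of groups (forced to 2 for `"mw"`).
#' @param reps Number of simulated datasets (>= 100).
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return A list: `rate`, `alpha`, `reps`, `ci99_null` (99% interval for the
#'   rejection rate under correct calibration), `test`.
#' @export
type1_error_sim <- function(test = c("kw", "mw", "anova"), n_per_group = 20,
                            k_groups = 3, reps = 2000, alpha = 0.05,
                            seed = 1L) {
  test <- match.arg(test)
  if (reps < 100) stop("`reps` must be >= 100")
  if (test == "mw") k_groups <- 2
  pfun <- switch(test,
    kw = function(g) kruskal_wallis(g)$p_value,
    mw = function(g) mann_whitney(g[[1]], g[[2]])$p_value,
    anova = function(g) one_way_anova_bonferroni(g)$p_value)
  with_seed(seed, {
    rej <- logical(reps)
    for (i in seq_len(reps)) {
      g <- replicate(k_groups, rnorm(n_per_group), simplify = FALSE)
      names(g) <- paste0("g", seq_len(k_groups))
      rej[i] <- pfun(g) < alpha
    }
    half <- qnorm(0.995) * sqrt(alpha * (1 - alpha) / reps)
    list(rate = mean(rej), alpha = alpha, reps = reps,
         ci99_null = c(max(0, alpha - half), min(1, alpha + half)),
         test = test)
  })
}
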