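test_that("spearman correlation handles monotone series and small-n exact p", {
  expect_equal(spearman_test(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(spearman_test(1:6, -(1:6))$rho, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")

  # n = 5 exact p equals brute force over all 120 rank permutations
  set.seed(17)
  for (i in 1:5) {
    x <- sample(100, 5); y <- sample(100, 5)
    got <- spearman_test(x, y)
    perms <- all_perms(5)
    rho_obs <- cor(rank(x), rank(y))
    rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
    expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  }
})

test_that("bisector test recovers exact fits and matches OLS normal equations", {
  x <- c(0.2, 0.5, 0.8, 1.1)
  f0 <- bisector_test(x, x)
  expect_equal(f0$slope, 1)
  expect_equal(f0$intercept, 0)
  expect_equal(f0$p_slope_vs_1, 1)
  expect_equal(f0$p_intercept_vs_0, 1)
  f1 <- bisector_test(x, x + 0.37)
  expect_equal(f1$intercept, 0.37)
  expect_equal(f1$slope, 1)
  expect_equal(f1$p_intercept_vs_0, 0)   # exact shifted fit: zero residual

  # closed-form normal-equation oracle on random data
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- runif(n); y <- 0.8 * x + rnorm(n, 0, 0.1)
    fit <- bisector_test(x, y)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    s2 <- sum((y - a - b * x)^2) / (n - 2)
    expect_equal(fit$slope, b)
    expect_equal(fit$intercept, a)
    expect_equal(fit$se_slope, sqrt(s2 / sxx))
    expect_equal(fit$se_intercept, sqrt(s2 * (1 / n + mean(x)^2 / sxx)))
    expect_equal(fit$p_slope_vs_1,
                 2 * pt(abs((b - 1) / sqrt(s2 / sxx)), n - 2, lower.tail = FALSE))
  }
})

test_that("binomial status test doubles the smaller tail with ties excluded", {
  st <- paired_status(
    molecular = c("Good", "Good", "High", "Poor", "Bad", "Moderate"),
    morphological = c("Good", "Moderate", "High", "Good", "Poor", "Moderate"))
  expect_equal(st$change,
               c("equal", "improved", "equal", "worsened", "worsened", "equal"))
  got <- binomial_status_test(st)
  expect_equal(got$n_equal, 3L)
  # cross-check against the standard exact binomial (identical at p0 = 1/2
  # by symmetry)
  expect_equal(got$p, binom.test(1, 3, 0.5)$p.value)

  expect_equal(binomial_status_test(n_improved = 0, n_worsened = 0)$p, 1)
  # symmetric under swapping improved/worsened
  expect_equal(binomial_status_test(n_improved = 3, n_worsened = 5)$p,
               binomial_status_test(n_improved = 5, n_worsened = 3)$p)
  # closed form for a one-sided sweep
  expect_equal(binomial_status_test(n_improved = 17, n_worsened = 0)$p,
               2 * 0.5^17)
})

test_that("friedman test matches the classic statistic and its permutation law", {
  # identical columns: no information
  same <- paired_status(rep("Good", 4), rep("Good", 4))
  got <- friedman_status_test(same)
  expect_equal(got$chi2, 0)
  expect_equal(got$p, 1)
  # one method uniformly one class better, no ties: chi2 = n for k = 2
  up <- paired_status(rep("Good", 7), rep("Moderate", 7))
  expect_equal(friedman_status_test(up)$chi2, 7)
  expect_error(friedman_status_test(paired_status("Good", "Bad")), "2 blocks")

  # agreement with the standard implementation on untied blocks
  set.seed(29)
  mol <- sample(c("Bad", "Moderate", "High"), 8, replace = TRUE)
  mor <- sample(c("Poor", "Good"), 8, replace = TRUE)
  st <- paired_status(mol, mor)
  y <- cbind(as.integer(st$status_molecular), as.integer(st$status_morphological))
  expect_equal(friedman_status_test(st)$chi2,
               unname(friedman.test(y)$statistic))

  # within-block permutation oracle at n = 6: enumerate all 2^6 sign flips,
  # computing the reference statistic with stats::friedman.test
  mol6 <- c("Good", "Bad", "High", "Moderate", "Good", "Poor")
  mor6 <- c("Moderate", "Poor", "Good", "Good", "High", "Bad")
  st6 <- paired_status(mol6, mor6)
  got6 <- friedman_status_test(st6, p_method = "permutation")
  y6 <- cbind(as.integer(st6$status_molecular),
              as.integer(st6$status_morphological))
  obs <- unname(friedman.test(y6)$statistic)
  stats_all <- sapply(0:(2^6 - 1), function(mask) {
    flip <- bitwAnd(mask, 2^(0:5)) > 0
    yy <- y6
    yy[flip, ] <- y6[flip, 2:1]
    unname(friedman.test(yy)$statistic)
  })
  stats_all[is.nan(stats_all)] <- 0
  expect_equal(got6$chi2, obs)
  expect_equal(got6$p, mean(stats_all >= obs - 1e-12))
})

test_that("mann-whitney reports U and rank-sum with exact small-n p", {
  got <- mann_whitney_test(c(3, 4), c(1, 2))
  expect_equal(got$W, 4)                       # U convention
  expect_equal(got$rank_sum, 4 + 3)            # summed ranks of x
  same <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)

  # enumeration oracle over all C(6,3) labelings
  set.seed(37)
  for (i in 1:5) {
    v <- sample(100, 6)
    x <- v[1:3]; y <- v[4:6]
    got <- mann_whitney_test(x, y)
    Us <- apply(combn(6, 3), 2,
                function(ix) sum(outer(v[ix], v[-ix], ">")))
    expect_equal(got$p, mean(abs(Us - 4.5) >= abs(got$W - 4.5) - 1e-12))
  }
})

test_that("jaccard dissimilarity is a metric on finite sets", {
  expect_equal(jaccard_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_dissimilarity(c("a", "b"), c("c", "d")), 1)
  expect_error(jaccard_dissimilarity(character(0), character(0)), "empty")
  expect_equal(jaccard_dissimilarity(c("a", "a", "b"), c("a", "b")), 0)  # set semantics
  set.seed(41)
  pool <- paste0("t", 1:12)
  for (i in 1:25) {
    a <- sample(pool, sample(1:10, 1))
    b <- sample(pool, sample(1:10, 1))
    c_ <- sample(pool, sample(1:10, 1))
    dab <- jaccard_dissimilarity(a, b)
    expect_equal(dab, jaccard_dissimilarity(b, a))
    expect_lte(dab,
               jaccard_dissimilarity(a, c_) + jaccard_dissimilarity(c_, b) + 1e-12)
  }
})

test_that("permanova reproduces vegan's marginal decomposition", {
  skip_if_not_installed("vegan")
  set.seed(47)
  pa <- matrix(rbinom(12 * 40, 1, 0.35), 12)
  meta <- data.frame(method = rep(c("bulk", "edna"), each = 6),
                     site = rep(paste0("S", 1:6), 2))
  d <- jaccard_dist(pa)
  ours <- permanova(d, meta, n_perm = 99, seed = 1)
  vg <- vegan::adonis2(d ~ method + site, data = meta, by = "margin",
                       permutations = 999)
  expect_equal(ours["method", "SumOfSqs"], vg["method", "SumOfSqs"])
  expect_equal(ours["site", "SumOfSqs"], vg["site", "SumOfSqs"])
  expect_equal(ours["method", "F"], vg["method", "F"])
  expect_equal(ours["method", "R2"], vg["method", "R2"])
  expect_equal(ours["Residual", "SumOfSqs"], vg["Residual", "SumOfSqs"])
  # our distances match vegan's Jaccard
  expect_equal(max(abs(as.matrix(d) -
                         as.matrix(vegan::vegdist(pa, "jaccard")))), 0,
               tolerance = 1e-12)
})

test_that("permanova decomposition, bounds and input validation hold", {
  set.seed(53)
  x <- matrix(rnorm(8 * 3), 8)
  f <- data.frame(g = rep(c("a", "b"), each = 4))
  d <- dist(x)
  res <- permanova(d, f, n_perm = 49, seed = 2)
  # single factor: term SS + residual SS = total SS
  expect_equal(res["g", "SumOfSqs"] + res["Residual", "SumOfSqs"],
               res["Total", "SumOfSqs"])
  expect_true(all(res$R2 >= 0 & res$R2 <= 1))
  expect_gte(res["g", "p"], 1 / 50)
  bad <- matrix(runif(16), 4); diag(bad) <- 0
  expect_error(permanova(bad, data.frame(g = c("a", "a", "b", "b"))),
               "symmetric")
  # aliased factor: rank-deficient marginal design
  f2 <- data.frame(g = rep(c("a", "b"), each = 4),
                   h = rep(c("a", "b"), each = 4))
  expect_error(permanova(d, f2, n_perm = 9), "rank-deficient")
})

test_that("permanova p equals exhaustive enumeration at n = 6", {
  # 1-D Euclidean case so the pseudo-F has an independent classical oracle
  set.seed(59)
  v <- c(0.1, 0.9, 0.3, 1.4, 0.2, 0.8)
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  d <- dist(v)
  perms <- all_perms(6)
  res <- permanova(d, data.frame(g = g), permutations = perms)
  # oracle: classic one-way ANOVA F over all 720 label permutations
  f_of <- function(vals) {
    fit <- anova(lm(vals ~ g))
    fit$`F value`[1]
  }
  F_obs <- f_of(v)
  F_all <- apply(perms, 1, function(p) f_of(v[p]))
  p_exact <- (sum(F_all >= F_obs - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(res["g", "F"], F_obs, tolerance = 1e-10)
  expect_equal(res["g", "p"], p_exact)
})

test_that("permanova achieves nominal type-I error under the null", {
  # 500 null simulations, alpha = 0.05, rejection rate within 2 binomial SE
  set.seed(61)
  n_sim <- 500
  rejections <- 0
  for (i in seq_len(n_sim)) {
    x <- matrix(rnorm(12 * 4), 12)
    f <- data.frame(g = sample(rep(c("a", "b", "c"), each = 4)))
    p <- permanova(dist(x), f, n_perm = 199)["g", "p"]
    rejections <- rejections + (p <= 0.05)
  }
  rate <- rejections / n_sim
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_gte(rate, 0.05 - 2 * se)
  expect_lte(rate, 0.05 + 2 * se)
})
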