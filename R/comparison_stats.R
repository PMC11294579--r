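#' Spearman rank correlation with small-sample exact p
#'
#' Rank correlation with average ranks for ties. The p-value is computed by
#' exact enumeration of the permutation distribution when n <= 8 and there
#' are no ties, and by the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rank correlation undefined")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 8L && !ties)))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Test a regression line against the bisector
#'
#' Ordinary least squares of `y` on `x` with two-sided t-tests of the two
#' hypotheses that define the identity line: slope = 1 and intercept = 0.
#' Used to ask whether one monitoring method systematically reads higher
#' than another across the quality gradient: a pure offset shows up in the
#' intercept, a gradient-dependent distortion in the slope.
#'
#' With an exact fit (zero residual variance) the standard errors collapse
#' to 0; p is then reported as 1 when the estimate equals its null value
#' and 0 otherwise.
#'
#' @param x predictor (e.g. morphological EQR).
#' @param y response (e.g. molecular EQR).
#' @return a `bisector_fit` list: `slope`, `intercept`, `se_slope`,
#'   `se_intercept`, `p_slope_vs_1`, `p_intercept_vs_0`, `n`.
#' @export
bisector_test <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 paired observations")
  if (sd(x) == 0) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # zero-residual fits handled below
  cf <- sm$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  sigma <- sm$sigma
  p_vs <- function(estimate, stderr, null) {
    if (!is.finite(stderr) || stderr < .Machine$double.eps^0.5 * max(1, abs(estimate))) {
      return(if (isTRUE(all.equal(unname(estimate), null, tolerance = 1e-8))) 1 else 0)
    }
    unname(2 * pt(abs((estimate - null) / stderr), df = n - 2L,
                  lower.tail = FALSE))
  }
  if (sigma < 1e-10) se[] <- 0
  structure(list(slope = unname(est["x"]),
                 intercept = unname(est["(Intercept)"]),
                 se_slope = unname(se["x"]),
                 se_intercept = unname(se["(Intercept)"]),
                 p_slope_vs_1 = p_vs(est["x"], se["x"], 1),
                 p_intercept_vs_0 = p_vs(est["(Intercept)"], se["(Intercept)"], 0),
                 n = n),
            class = "bisector_fit")
}

#' Pair up ecological statuses from two methods
#'
#' @param molecular,morphological status vectors (character or factor with
#'   levels Bad, Poor, Moderate, Good, High), same samples in the same
#'   order.
#' @param sample_id optional sample identifiers.
#' @return a `paired_status` data.frame with the per-sample `change` of the
#'   molecular status relative to the morphological one (`improved`,
#'   `equal` or `worsened`).
#' @export
paired_status <- function(molecular, morphological, sample_id = NULL) {
  to_ord <- function(z) {
    f <- factor(as.character(z), levels = STATUS_LEVELS, ordered = TRUE)
    if (anyNA(f)) stop("unknown status class; expected one of ",
                       paste(STATUS_LEVELS, collapse = ", "))
    f
  }
  mol <- to_ord(molecular)
  mor <- to_ord(morphological)
  if (length(mol) != length(mor)) stop("status vectors must have equal length")
  change <- ifelse(as.integer(mol) > as.integer(mor), "improved",
                   ifelse(as.integer(mol) < as.integer(mor), "worsened", "equal"))
  df <- data.frame(sample_id = if (is.null(sample_id)) seq_along(mol) else sample_id,
                   status_molecular = mol, status_morphological = mor,
                   change = change, stringsAsFactors = FALSE)
  class(df) <- c("paired_status", "data.frame")
  df
}

#' Two-sided exact binomial test on paired status changes
#'
#' Ties (equal statuses) are excluded; under the null that a method is as
#' likely to read better as worse, the number of improvements among the
#' changed samples is Binomial(n, 1/2). The two-sided p doubles the smaller
#' tail, capped at 1: p = min(1, 2 min(P(X <= k), P(X >= k))). With no
#' changed samples there is no evidence either way and p = 1.
#'
#' @param statuses a [paired_status()] data.frame; alternatively give
#'   `n_improved` and `n_worsened` directly.
#' @param n_improved,n_worsened direct counts (used when `statuses` is
#'   NULL).
#' @return list with `p`, `n_improved`, `n_worsened`, `n_equal`.
#' @export
binomial_status_test <- function(statuses = NULL, n_improved = NULL,
                                 n_worsened = NULL) {
  if (!is.null(statuses)) {
    stopifnot(inherits(statuses, "paired_status"))
    n_improved <- sum(statuses$change == "improved")
    n_worsened <- sum(statuses$change == "worsened")
    n_equal <- sum(statuses$change == "equal")
  } else {
    if (is.null(n_improved) || is.null(n_worsened)) {
      stop("give either statuses or both counts")
    }
    n_equal <- NA_integer_
  }
  n <- n_improved + n_worsened
  p <- if (n == 0L) 1 else {
    min(1, 2 * min(pbinom(n_improved, n, 0.5),
                   pbinom(n_improved - 1L, n, 0.5, lower.tail = FALSE)))
  }
  list(p = p, n_improved = n_improved, n_worsened = n_worsened,
       n_equal = n_equal)
}

# Tie-corrected Friedman chi-square statistic on an n-blocks x k-treatments
# matrix of ordinal values (average ranks within blocks).
friedman_statistic <- function(y) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1L, rank))
  Rj <- colSums(r)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) return(0)        # all blocks fully tied: no information
  num / den
}

#' Friedman test on paired ordinal statuses
#'
#' Ranks the two methods' status classes (coded Bad = 1 ... High = 5)
#' within each sample (block), with average ranks for ties and the usual
#' tie-corrected chi-square statistic. `p_method = "permutation"`
#' enumerates all within-block orderings exactly (k = 2: all 2^n sign
#' flips) instead of using the chi-square approximation.
#'
#' @param statuses a [paired_status()] with at least 2 samples.
#' @param p_method `"chisq"` (default) or `"permutation"` (exact, k = 2,
#'   n <= 20).
#' @return list with `chi2`, `df`, `p`, `n`.
#' @export
friedman_status_test <- function(statuses, p_method = c("chisq", "permutation")) {
  stopifnot(inherits(statuses, "paired_status"))
  p_method <- match.arg(p_method)
  n <- nrow(statuses)
  if (n < 2L) stop("need at least 2 blocks (samples)")
  y <- cbind(as.integer(statuses$status_molecular),
             as.integer(statuses$status_morphological))
  chi2 <- friedman_statistic(y)
  k <- ncol(y)
  if (p_method == "chisq") {
    p <- if (chi2 == 0) 1 else pchisq(chi2, df = k - 1L, lower.tail = FALSE)
  } else {
    if (n > 20L) stop("exact permutation limited to n <= 20 blocks")
    stats_all <- vapply(seq_len(2^n) - 1L, function(mask) {
      flip <- bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L
      yy <- y
      yy[flip, ] <- y[flip, 2:1]
      friedman_statistic(yy)
    }, numeric(1))
    p <- mean(stats_all >= chi2 - 1e-12)
  }
  list(chi2 = chi2, df = k - 1L, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, exact for small
#' tie-free samples and tie-corrected normal approximation otherwise. Both
#' statistic conventions are returned: `W` is the Mann-Whitney U of the
#' first sample (the convention printed by base R), `rank_sum` the summed
#' ranks of the first sample (W = rank_sum - n1 (n1 + 1) / 2).
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `W`, `rank_sum`, `p`, `n1`, `n2`.
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y))
  W <- unname(wt$statistic)
  list(W = W,
       rank_sum = W + length(x) * (length(x) + 1) / 2,
       p = wt$p.value,
       n1 = length(x), n2 = length(y))
}

#' Jaccard dissimilarity of two taxon sets
#'
#' One minus the shared fraction of the union. 0 for identical sets, 1 for
#' disjoint ones; an error if both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return numeric in \[0, 1\].
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) stop("both sets empty: Jaccard undefined")
  1 - length(intersect(a, b)) / length(u)
}

#' Compare two monitoring methods end to end
#'
#' Bundles the method-comparison statistics for paired per-sample results:
#' Spearman correlation and bisector regression of the EQR values, exact
#' binomial and Friedman tests on the paired status classes, Mann-Whitney
#' on the raw index values, and (optionally) a PERMANOVA on a
#' presence/absence community matrix with method and site as crossed
#' factors.
#'
#' @param molecular,morphological `index_result` data.frames (or any
#'   data.frame with `sample_id`, `ibmwp`, `eqr`, `status`) for the same
#'   samples.
#' @param pa optional presence/absence matrix (rows = observations matching
#'   `pa_meta`) for the community PERMANOVA.
#' @param pa_meta optional data.frame with factors `method` and `site` for
#'   the rows of `pa`.
#' @param n_perm permutations for the PERMANOVA.
#' @param seed RNG seed for the PERMANOVA.
#' @return list with elements `spearman`, `bisector`, `binomial`,
#'   `friedman`, `mann_whitney`, `statuses` and (when `pa` is given)
#'   `permanova`.
#' @export
compare_methods <- function(molecular, morphological, pa = NULL,
                            pa_meta = NULL, n_perm = 999L, seed = NULL) {
  common <- intersect(molecular$sample_id, morphological$sample_id)
  if (length(common) < 3L) stop("need at least 3 shared samples")
  mol <- molecular[match(common, molecular$sample_id), , drop = FALSE]
  mor <- morphological[match(common, morphological$sample_id), , drop = FALSE]
  st <- paired_status(mol$status, mor$status, sample_id = common)
  out <- list(
    spearman = spearman_test(mor$eqr, mol$eqr),
    bisector = bisector_test(mor$eqr, mol$eqr),
    binomial = binomial_status_test(st),
    friedman = friedman_status_test(st),
    mann_whitney = mann_whitney_test(mol$ibmwp, mor$ibmwp),
    statuses = st)
  if (!is.null(pa)) {
    if (is.null(pa_meta)) stop("pa_meta required with pa")
    d <- jaccard_dist(pa)
    out$permanova <- permanova(d, pa_meta, n_perm = n_perm, seed = seed)
  }
  out
}

#' Jaccard distance matrix from a presence/absence matrix
#'
#' Pairwise Jaccard dissimilarities between the rows (observations) of a
#' binary observation-by-taxon matrix.
#'
#' @param pa numeric or logical matrix; any positive entry counts as
#'   presence.
#' @return a `dist` object.
#' @export
jaccard_dist <- function(pa) {
  pa <- (as.matrix(pa) > 0) + 0
  n <- nrow(pa)
  shared <- tcrossprod(pa)
  tot <- diag(shared)
  un <- outer(tot, tot, "+") - shared
  d <- ifelse(un > 0, 1 - shared / un, 0)
  stats::as.dist(d)
}
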