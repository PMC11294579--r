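#' Permutational multivariate ANOVA with marginal term tests
#'
#' Distance-based multivariate analysis of variance (McArdle-Anderson
#' style), written around the Gower-centred inner-product matrix
#' G = -(1/2) C D^2 C (C the centring matrix). Explained sums of squares
#' are traces of hat-matrix projections of G; with several factors each
#' term is tested marginally: its sum of squares is SS(full model) minus
#' SS(model without the term), so the order of the factors does not matter.
#' Pseudo-F per term uses the full-model residual; significance comes from
#' free permutation of the observation labels (rows and columns of the
#' distance matrix permuted jointly), with the observed statistic included
#' in the reference set: p = (#\{F* >= F\} + 1) / (n_perm + 1).
#'
#' @param d a `dist` or symmetric numeric matrix with zero diagonal.
#' @param factors data.frame of one or more categorical predictors (rows in
#'   the same order as the observations of `d`).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; set it for reproducible p-values.
#' @param permutations optional integer matrix of permutation index rows to
#'   use instead of random draws (e.g. the full enumeration for an exact
#'   test); overrides `n_perm`.
#' @return a `permanova` data.frame with one row per term plus Residual and
#'   Total: columns `Df`, `SumOfSqs`, `R2`, `F`, `p`; the number of
#'   permutations is kept in attribute `n_perm`.
#' @export
permanova <- function(d, factors, n_perm = 999L, seed = NULL,
                      permutations = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (ncol(D) != n || any(abs(D - t(D)) > 1e-8)) stop("d must be symmetric")
  if (any(abs(diag(D)) > 1e-8)) stop("d must have a zero diagonal")
  factors <- as.data.frame(factors, stringsAsFactors = TRUE)
  if (nrow(factors) != n) stop("factors must have one row per observation")
  for (j in seq_along(factors)) factors[[j]] <- factor(factors[[j]])
  terms <- names(factors)

  # Gower-centred inner-product matrix
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  hat_of <- function(cols) {
    # hat matrix of the additive model with the given factor columns
    f <- if (length(cols) == 0L) {
      ~1
    } else {
      stats::as.formula(paste("~", paste(cols, collapse = "+")))
    }
    X <- model.matrix(f, data = factors)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    list(H = tcrossprod(Q), rank = q$rank)
  }

  full <- hat_of(terms)
  df_res <- n - full$rank
  if (df_res <= 0L) stop("model saturates the data: no residual degrees of freedom")
  reduced <- lapply(terms, function(t) hat_of(setdiff(terms, t)))
  df_term <- vapply(seq_along(terms),
                    function(i) full$rank - reduced[[i]]$rank, integer(1))
  if (any(df_term == 0L)) {
    stop("rank-deficient design: term(s) ",
         paste(terms[df_term == 0L], collapse = ", "),
         " add no degrees of freedom")
  }

  ss_fun <- function(Gm) {
    ss_full <- sum(full$H * Gm)          # trace(H G) for symmetric G
    ss_t <- vapply(reduced, function(r) ss_full - sum(r$H * Gm), numeric(1))
    c(ss_t, ss_full)
  }
  obs <- ss_fun(G)
  ss_term <- obs[seq_along(terms)]
  ss_res <- ss_total - obs[length(obs)]
  F_obs <- (ss_term / df_term) / (ss_res / df_res)

  if (is.null(permutations)) {
    n_perm <- as.integer(n_perm)
    if (n_perm < 1L) stop("n_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  } else {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != n) stop("permutation rows must have length n")
    n_perm <- nrow(permutations)
  }
  exceed <- numeric(length(terms))
  for (i in seq_len(n_perm)) {
    idx <- permutations[i, ]
    v <- ss_fun(G[idx, idx])
    ss_res_p <- ss_total - v[length(v)]
    F_p <- (v[seq_along(terms)] / df_term) / (ss_res_p / df_res)
    exceed <- exceed + (F_p >= F_obs - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)

  res <- data.frame(
    Df = c(df_term, df_res, n - 1L),
    SumOfSqs = c(ss_term, ss_res, ss_total),
    R2 = c(ss_term / ss_total, ss_res / ss_total, 1),
    F = c(F_obs, NA, NA),
    p = c(p, NA, NA),
    row.names = c(terms, "Residual", "Total"))
  attr(res, "n_perm") <- n_perm
  class(res) <- c("permanova", "data.frame")
  res
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate ANOVA (marginal term tests)\n")
  cat(sprintf("Permutations: %d (free permutation of observations)\n\n",
              attr(x, "n_perm")))
  print.data.frame(round_df(x), ...)
  invisible(x)
}

round_df <- function(x, digits = 4) {
  for (j in seq_along(x)) if (is.numeric(x[[j]])) x[[j]] <- round(x[[j]], digits)
  x
}
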