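#' GLM residuals for the conditional-independence test
#'
#' Regresses the target on the conditioning variables and returns one
#' residual per sample. Continuous targets use ordinary linear-regression
#' residuals `x - x_hat` (intercept-only when the conditioning set is
#' empty). Categorical targets use the summed Pearson residual from a
#' multinomial logit fit,
#' `r_i = sum_k (x_ik - mu_ik) / sqrt(mu_ik (1 - mu_ik))`,
#' over the `L - 1` reference-coded indicators (levels 2..L), which for a
#' binary target reduces to the ordinary logistic Pearson residual. Fitted
#' probabilities are clamped to `[1e-8, 1 - 1e-8]`; collinear conditioning
#' columns are dropped.
#'
#' @param data a [mixed_data] object.
#' @param target target node name.
#' @param conditioning character vector of conditioning node names (may be
#'   empty).
#' @return numeric residual vector of length `n`.
#' @export
ci_residuals <- function(data, target, conditioning = character()) {
  if (target %in% conditioning) stop("target cannot be in the conditioning set")
  X <- build_design(data, conditioning, drop_collinear = TRUE, warn = FALSE)
  y <- data$values[[target]]
  n <- data$n
  if (data$node_types[[target]] == "continuous") {
    if (ncol(X) == 0) return(y - mean(y))
    fit <- stats::lm.fit(cbind(1, X), y)
    return(as.numeric(fit$residuals))
  }
  L <- data$levels[[target]]$n_levels
  mu <- fitted_multinom_probs(X, y, L)          # n x L
  eps <- 1e-8
  if (any(mu < eps | mu > 1 - eps)) {
    mu <- pmin(pmax(mu, eps), 1 - eps)
    warning("fitted probabilities clamped to [1e-8, 1 - 1e-8] for target '",
            target, "'")
  }
  r <- numeric(n)
  for (k in seq(2L, L)) {                       # indicators for levels 2..L
    xk <- as.numeric(y == k)
    muk <- mu[, k]
    r <- r + (xk - muk) / sqrt(muk * (1 - muk))
  }
  r
}

# Fitted class probabilities (n x L matrix, column l = P(y = l)) from a
# multinomial logit of integer-coded y on design X; intercept-only when X
# has no columns.
fitted_multinom_probs <- function(X, y, L) {
  n <- length(y)
  if (ncol(X) == 0) {
    p <- tabulate(y, nbins = L) / n
    return(matrix(p, nrow = n, ncol = L, byrow = TRUE))
  }
  yf <- factor(y, levels = seq_len(L))
  fit <- nnet::multinom(yf ~ X, trace = FALSE, maxit = 200, MaxNWts = 5000)
  lev <- fit$lev
  pr <- stats::fitted(fit)
  if (length(lev) == 2) {
    # two-level fits return P(second level) only (vector or n x 1 matrix)
    pr <- cbind(1 - as.numeric(pr), as.numeric(pr))
  }
  mu <- matrix(0, nrow = n, ncol = L)
  mu[, as.integer(lev)] <- pr
  mu
}

#' Residual partial correlation
#'
#' Pearson correlation of two centered residual vectors. If either vector
#' is (numerically) constant the correlation is undefined; the statistic is
#' returned as 0 with a warning, which downstream yields an independence
#' verdict.
#'
#' @param r_j,r_l residual vectors of equal length `n >= 3`.
#' @export
partial_correlation <- function(r_j, r_l) {
  if (length(r_j) != length(r_l)) stop("residual vectors differ in length")
  if (length(r_j) < 3) stop("need n >= 3")
  if (stats::sd(r_j) < 1e-12 || stats::sd(r_l) < 1e-12) {
    warning("constant residual vector: partial correlation undefined, using 0")
    return(0)
  }
  a <- r_j - mean(r_j); b <- r_l - mean(r_l)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Permutation test of conditional independence for mixed variables
#'
#' Computes the residual partial correlation of nodes `j` and `l` given
#' `K`, then permutes the second residual vector `B` times and recomputes
#' it. The two-sided, add-one-corrected p-value is
#' `(1 + #{b : |rho_b| >= |rho_obs|}) / (B + 1)`; the pair is declared
#' conditionally independent when `p > alpha`. The permutation seed is
#' derived deterministically from `seed` and the canonical (sorted) pair
#' and conditioning-set names, so results do not depend on argument or
#' column order.
#'
#' @param data a [mixed_data] object.
#' @param j,l node names, distinct and not in `K`.
#' @param K conditioning node names (possibly empty).
#' @param B number of permutations, `>= 1`.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return a `ci_test_result`: list with `pair`, `conditioning_set`,
#'   `rho_obs`, `pvalue`, `B`, `decision` (`"independent"`/`"dependent"`),
#'   `seed` (the derived per-test seed).
#' @export
permutation_ci_test <- function(data, j, l, K = character(), B = 200,
                                alpha = 0.05, seed = 1) {
  if (j == l) stop("j and l must differ")
  if (j %in% K || l %in% K) stop("j and l cannot be in K")
  if (B < 1) stop("B must be >= 1")
  r_j <- ci_residuals(data, j, K)
  r_l <- ci_residuals(data, l, K)
  degenerate <- stats::sd(r_j) < 1e-12 || stats::sd(r_l) < 1e-12
  test_seed <- hash_seed(seed, ci_test_key(j, l, K))
  if (degenerate) {
    rho <- suppressWarnings(partial_correlation(r_j, r_l))
    warning("degenerate residuals for pair (", j, ",", l,
            "): declaring independence")
    pval <- 1
  } else {
    a <- r_j - mean(r_j)
    b <- r_l - mean(r_l)
    rho <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    n <- length(a)
    exceed <- with_seed(test_seed, {
      cnt <- 0L
      denom_a <- sum(a^2)
      for (bb in seq_len(B)) {
        bp <- b[sample.int(n)]
        # bp keeps mean 0 (permutation of a centered vector)
        rho_b <- sum(a * bp) / sqrt(denom_a * sum(bp^2))
        if (abs(rho_b) >= abs(rho)) cnt <- cnt + 1L
      }
      cnt
    })
    pval <- (1 + exceed) / (B + 1)
  }
  structure(list(pair = sort(c(j, l)), conditioning_set = sort(K),
                 rho_obs = rho, pvalue = pval, B = B,
                 decision = if (pval > alpha) "independent" else "dependent",
                 seed = test_seed),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(x$pair[1], "_||_", x$pair[2],
      if (length(x$conditioning_set))
        paste("|", paste(x$conditioning_set, collapse = ",")) else "",
      ": rho =", format(x$rho_obs, digits = 3),
      ", p =", format(x$pvalue, digits = 3),
      paste0("(", x$decision, ")\n"))
  invisible(x)
}
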