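#' Nodewise penalized regression for Markov-blanket identification
#'
#' Each node is regressed on all remaining variables with an L1 penalty: a
#' gaussian lasso for continuous nodes and an (ungrouped) multinomial-logit
#' lasso for categorical nodes, with categorical predictors entering as
#' reference-coded indicator columns. The loss is kept in sum form,
#' -loglik + lambda * ||beta||_1, so the reported `lambda` equals `n` times
#' the per-observation penalty used internally by the solver. Multinomial
#' coefficients are re-expressed in reference coding (level-1 weight vector
#' fixed at zero) so they are identified and the L0 count is well defined.
#'
#' @param data a [mixed_data] object.
#' @param node target node name.
#' @param lambda penalty value (sum scale), `>= 0`.
#' @return a `nodewise_model`: list with `node`, `family` (`"gaussian"` or
#'   `"multinomial"`), `coefficients`, `intercept`, `sigma2` (gaussian),
#'   `lambda`, `loglik` (unpenalized log-likelihood at the fitted
#'   coefficients), `df` (number of nonzero non-intercept coefficients) and
#'   `active_set` (names of selected predictor nodes).
#' @export
fit_penalized_node <- function(data, node, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  path <- fit_node_path(data, node, lambda = lambda / data$n)
  extract_node_model(path, 1L)
}

# Fit the whole glmnet path for one node. `lambda` NULL = let glmnet pick a
# grid of `nlambda` values down to lambda_min_ratio * lambda_max.
fit_node_path <- function(data, node, lambda = NULL, nlambda = 50,
                          lambda_min_ratio = 0.01) {
  others <- setdiff(data$node_names, node)
  X <- build_design(data, others)
  if (ncol(X) < 2) {
    # glmnet needs >= 2 columns; a zero column always keeps coefficient 0
    X <- cbind(X, ".pad" = rep(0, data$n))
  }
  fam_cat <- data$node_types[[node]] == "categorical"
  y <- data$values[[node]]
  args <- list(x = X, y = if (fam_cat) factor(y) else y,
               family = if (fam_cat) "multinomial" else "gaussian",
               standardize = TRUE, thresh = 1e-9)
  if (fam_cat) args$type.multinomial <- "ungrouped"
  if (is.null(lambda)) {
    args$nlambda <- nlambda
    args$lambda.min.ratio <- lambda_min_ratio
  } else {
    # glmnet is unreliable for a single lambda; pad with a short path above
    args$lambda <- if (length(lambda) == 1 && lambda > 0) {
      sort(unique(c(lambda, lambda * c(8, 4, 2))), decreasing = TRUE)
    } else if (length(lambda) == 1) {
      c(1, 0.5, 0.1, 0.01, 0)
    } else {
      sort(lambda, decreasing = TRUE)
    }
  }
  fit <- tryCatch(do.call(glmnet::glmnet, args),
                  error = function(e) stop("penalized fit failed for node '",
                                           node, "': ", conditionMessage(e)))
  want <- if (is.null(lambda)) fit$lambda else lambda
  idx <- vapply(want, function(l) which.min(abs(fit$lambda - l)), integer(1))
  structure(list(fit = fit, data = data, node = node, X = X, y = y,
                 cat = fam_cat, others = others, lambda = fit$lambda,
                 index = idx),
            class = "mixdag_node_path")
}

# Pull the model at path position `which(index)` into a nodewise_model.
extract_node_model <- function(path, i) {
  fit <- path$fit
  k <- path$index[i]
  lam_glmnet <- fit$lambda[k]
  n <- path$data$n
  if (!path$cat) {
    beta <- as.numeric(fit$beta[, k])
    names(beta) <- rownames(fit$beta)
    beta <- zap_small(beta)
    eta <- as.numeric(fit$a0[k] + path$X %*% beta)
    rss <- sum((path$y - eta)^2)
    sigma2 <- rss / n
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    coefs <- list(beta)
    intercept <- fit$a0[k]
    df <- sum(beta != 0)
    active_cols <- names(beta)[beta != 0]
  } else {
    # reference coding: subtract the level-1 block from every level block
    raw <- lapply(fit$beta, function(b) as.numeric(b[, k]))
    a0 <- vapply(seq_along(raw), function(l) fit$a0[l, k], numeric(1))
    ref <- raw[[1]]; ref0 <- a0[1]
    coefs <- lapply(raw, function(b) zap_small(b - ref))
    intercept <- a0 - ref0
    cn <- rownames(fit$beta[[1]])
    for (l in seq_along(coefs)) names(coefs[[l]]) <- cn
    # unpenalized multiclass loglik from predicted probabilities
    pr <- predict(fit, newx = path$X, s = lam_glmnet, type = "response",
                  exact = FALSE)[, , 1]
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    lev <- as.integer(colnames(pr))
    loglik <- sum(log(pr[cbind(seq_len(n), match(path$y, lev))]))
    nz <- do.call(rbind, coefs[-1]) != 0
    df <- sum(nz)
    active_cols <- cn[colSums(nz) > 0]
    sigma2 <- NULL
  }
  active <- unique(design_owner(active_cols, path$others))
  structure(list(node = path$node,
                 family = if (path$cat) "multinomial" else "gaussian",
                 coefficients = coefs, intercept = intercept,
                 sigma2 = sigma2, lambda = lam_glmnet * n,
                 loglik = loglik, df = df,
                 active_set = intersect(path$others, active)),
            class = "nodewise_model")
}

#' Extended Bayesian information criterion for a nodewise model
#'
#' `EBIC = -2 loglik + df log(n) + 2 gamma df log(d - 1)` where `df` is the
#' number of nonzero non-intercept coefficients (counted across all level
#' blocks for multinomial models) and the log-likelihood is the unpenalized
#' log-likelihood evaluated at the fitted coefficients. With `gamma = 0`
#' this is the ordinary BIC used for edge orientation.
#'
#' @param model a `nodewise_model`.
#' @param n sample size.
#' @param d total number of variables in the dataset.
#' @param gamma EBIC constant, `>= 0`.
#' @export
ebic_score <- function(model, n, d, gamma = 0.5) {
  if (gamma < 0) stop("gamma must be >= 0")
  -2 * model$loglik + model$df * log(n) + 2 * gamma * model$df * log(d - 1)
}

#' Select the nodewise penalty by EBIC
#'
#' Fits the full descending lasso path with warm starts and returns the
#' model minimizing [ebic_score]; ties break toward the larger (sparser)
#' lambda, which comes first on the descending path.
#'
#' @inheritParams fit_penalized_node
#' @param gamma EBIC constant.
#' @param nlambda,lambda_min_ratio path grid: `nlambda` log-spaced values
#'   from the empty-model lambda down to `lambda_min_ratio` times it.
#' @param lambda_path explicit descending grid (sum scale), overriding the
#'   automatic one.
#' @return the selected `nodewise_model`, with an `ebic` field added.
#' @export
select_lambda <- function(data, node, gamma = 0.5, nlambda = 50,
                          lambda_min_ratio = 0.01, lambda_path = NULL) {
  if (!is.null(lambda_path)) {
    if (any(lambda_path <= 0) || is.unsorted(rev(lambda_path), strictly = TRUE)) {
      stop("lambda_path must be strictly positive and descending")
    }
    path <- fit_node_path(data, node, lambda = lambda_path / data$n)
  } else {
    path <- fit_node_path(data, node, nlambda = nlambda,
                          lambda_min_ratio = lambda_min_ratio)
  }
  best <- NULL; best_score <- Inf
  for (i in seq_along(path$index)) {
    m <- extract_node_model(path, i)
    sc <- ebic_score(m, data$n, data$d, gamma)
    if (sc < best_score - 1e-12) {  # strict improvement: ties keep sparser
      best <- m; best_score <- sc
    }
  }
  best$ebic <- best_score
  best
}

#' Estimate the mixed graphical model
#'
#' Runs [select_lambda] for every node and symmetrizes the nodewise active
#' sets into an undirected graph. With the default OR rule an edge {i, j} is
#' drawn when either node's regression selects the other (a categorical
#' predictor counts as selected when any of its indicator coefficients is
#' nonzero); the AND rule requires both.
#'
#' @inheritParams select_lambda
#' @param rule symmetrization rule, `"or"` (default) or `"and"`.
#' @return a `mixed_graphical_model`: list with `graph`
#'   (an `undirected_graph`), `models` (per-node `nodewise_model`s),
#'   `gamma`, `rule`.
#' @export
build_mgm <- function(data, gamma = 0.5, rule = c("or", "and"),
                      nlambda = 50, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  models <- lapply(data$node_names, function(v) {
    tryCatch(select_lambda(data, v, gamma = gamma, nlambda = nlambda,
                           lambda_min_ratio = lambda_min_ratio),
             error = function(e) stop("nodewise fit failed at node '", v,
                                      "': ", conditionMessage(e)))
  })
  names(models) <- data$node_names
  edges <- matrix(character(0), ncol = 2)
  nodes <- sort(data$node_names)
  for (a_i in seq_along(nodes)) {
    for (b_i in seq_len(a_i - 1L)) {
      a <- nodes[b_i]; b <- nodes[a_i]
      in_a <- b %in% models[[a]]$active_set
      in_b <- a %in% models[[b]]$active_set
      hit <- if (rule == "or") in_a || in_b else in_a && in_b
      if (hit) edges <- rbind(edges, c(a, b))
    }
  }
  structure(list(graph = undirected_graph(data$node_names, edges),
                 models = models, gamma = gamma, rule = rule),
            class = "mixed_graphical_model")
}

#' @export
print.mixed_graphical_model <- function(x, ...) {
  cat("Mixed graphical model: ", length(x$graph$nodes), " nodes, ",
      nrow(x$graph$edges), " edge(s) [", x$rule, " rule, gamma = ",
      x$gamma, "]\n", sep = "")
  invisible(x)
}
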