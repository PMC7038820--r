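test_that("gaussian lasso matches closed-form least squares at lambda = 0", {
  set.seed(21)
  n <- 50
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 1.2 * x + rnorm(n)
  d <- mixed_data(data.frame(X = x, Y = y),
                  c(X = "continuous", Y = "continuous"))
  m <- fit_penalized_node(d, "Y", lambda = 0)
  ols <- sum(x * y) / sum(x^2)  # closed-form univariate OLS slope
  expect_equal(unname(m$coefficients[[1]]["X"]), ols, tolerance = 1e-6)
  expect_equal(m$active_set, "X")
  expect_gt(m$sigma2, 0)
})

test_that("univariate gaussian lasso matches the soft-threshold closed form", {
  set.seed(22)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 1.5 * x + rnorm(n)
  d <- mixed_data(data.frame(X = x, Y = y),
                  c(X = "continuous", Y = "continuous"))
  ols <- sum(x * y) / sum(x^2)
  for (lam in c(20, 60, 120)) {   # sum-scale penalties
    m <- fit_penalized_node(d, "Y", lambda = lam)
    soft <- sign(ols) * max(abs(sum(x * y) / n) - lam / n, 0)
    expect_equal(unname(m$coefficients[[1]]["X"]), soft, tolerance = 1e-4)
  }
})

test_that("a huge penalty shrinks every coefficient to zero", {
  set.seed(23)
  d <- sim_vstructure(100, 23)
  m0 <- fit_penalized_node(d, "W", lambda = 0)
  lam_big <- 10 * d$n * max(abs(crossprod(scale(d$values$X),
                                          scale(d$values$W))) / d$n, 1) * 10
  m <- fit_penalized_node(d, "W", lambda = lam_big)
  expect_length(m$active_set, 0)
  expect_equal(m$df, 0)
  expect_gt(m0$df, 0)
})

test_that("ebic_score evaluates its formula exactly", {
  mk <- function(loglik, df) {
    structure(list(loglik = loglik, df = df), class = "nodewise_model")
  }
  expect_equal(ebic_score(mk(-100, 0), n = 50, d = 10, gamma = 0), 200)
  expect_equal(ebic_score(mk(-100, 3), n = 100, d = 21, gamma = 0.5),
               200 + 3 * log(100) + 3 * log(20))
  # adding one coefficient at equal loglik costs log n + 2 gamma log(d-1)
  gap <- ebic_score(mk(-50, 4), 80, 15, 0.25) -
    ebic_score(mk(-50, 3), 80, 15, 0.25)
  expect_equal(gap, log(80) + 2 * 0.25 * log(14))
  expect_error(ebic_score(mk(-1, 0), 10, 5, gamma = -1), "gamma")
})

test_that("EBIC at gamma = 0 equals the orientation BIC for the same fit", {
  set.seed(24)
  d <- sim_chain(300, 24)
  m <- fit_penalized_node(d, "X2", lambda = 0)   # unpenalized fit
  expect_equal(ebic_score(m, d$n, d$d, gamma = 0),
               node_bic(d, "X2", c("X1", "X3")), tolerance = 1e-4)
})

test_that("active-set size is non-increasing along the descending path", {
  set.seed(25)
  d <- sim_sem(list(A = NULL, B = NULL, C = NULL, Y = c("A", "B")), 150, 25)
  path <- mixdag:::fit_node_path(d, "Y", nlambda = 30)
  sizes <- vapply(seq_along(path$index), function(i) {
    mixdag:::extract_node_model(path, i)$df
  }, numeric(1))
  # descending lambda (increasing index) can only grow the active set
  expect_true(all(diff(sizes) >= 0))
})

test_that("select_lambda keeps signal and drops noise", {
  hits_signal <- 0; empty_noise <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 400
    xi <- rnorm(n); xj <- xi + rnorm(n); z <- rnorm(n)
    d <- mixed_data(data.frame(Xi = xi, Xj = xj, Z = z),
                    c(Xi = "continuous", Xj = "continuous",
                      Z = "continuous"))
    m <- select_lambda(d, "Xj")
    if ("Xi" %in% m$active_set) hits_signal <- hits_signal + 1
    m2 <- select_lambda(d, "Z")
    if (length(m2$active_set) == 0) empty_noise <- empty_noise + 1
  }
  expect_gte(hits_signal, 19)
  expect_gte(empty_noise, 18)
})

test_that("select_lambda handles degenerate single-value paths", {
  set.seed(26)
  d <- sim_chain(100, 26)
  m <- select_lambda(d, "X2", lambda_path = 5)
  expect_s3_class(m, "nodewise_model")
  expect_equal(m$lambda, 5, tolerance = 0.02)
  expect_error(select_lambda(d, "X2", lambda_path = c(1, 2)), "descending")
  expect_error(select_lambda(d, "X2", lambda_path = c(2, -1)), "positive")
})

test_that("build_mgm recovers chain edges and the moralization edge", {
  chain_ok <- 0; moral <- 0
  for (s in 1:10) {
    d <- sim_chain(800, 100 + s)
    mgm <- build_mgm(d)
    keys <- mixdag:::pair_keys(mgm$graph$edges)
    if (all(c("X1\rX2", "X2\rX3") %in% keys)) chain_ok <- chain_ok + 1
    v <- sim_vstructure(800, 200 + s)
    mv <- build_mgm(v)
    if ("X\rZ" %in% mixdag:::pair_keys(mv$graph$edges)) moral <- moral + 1
  }
  expect_gte(chain_ok, 9)
  expect_gte(moral, 7)  # co-parents are usually joined in the MGM
})

test_that("build_mgm is empty under independence and order-invariant", {
  empties <- 0
  for (s in 1:10) {
    d <- sim_independent(5, 500, 300 + s)
    mgm <- build_mgm(d)
    if (nrow(mgm$graph$edges) == 0) empties <- empties + 1
  }
  expect_gte(empties, 9)

  d <- sim_vstructure(400, 31)
  perm <- d$values[, c("W", "Z", "X")]
  d2 <- mixed_data(perm, c(W = "continuous", Z = "continuous",
                           X = "continuous"))
  expect_setequal(mixdag:::pair_keys(build_mgm(d)$graph$edges),
                  mixdag:::pair_keys(build_mgm(d2)$graph$edges))
})

test_that("the and-rule MGM is a subgraph of the or-rule MGM", {
  d <- sim_vstructure(300, 33)
  g_or <- build_mgm(d, rule = "or")$graph
  g_and <- build_mgm(d, rule = "and")$graph
  expect_true(all(mixdag:::pair_keys(g_and$edges) %in%
                    mixdag:::pair_keys(g_or$edges)))
})

test_that("multinomial nodewise fits select mixed-type neighbors", {
  hits <- 0
  for (s in 1:10) {
    d <- sim_mixed_pair(500, 400 + s, beta = 2)
    m <- select_lambda(d, "G")
    if ("X" %in% m$active_set) hits <- hits + 1
    # reference coding: level-1 block is identically zero
    expect_equal(unname(m$coefficients[[1]]), rep(0, length(m$coefficients[[1]])))
  }
  expect_gte(hits, 9)
})
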