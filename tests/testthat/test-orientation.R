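test_that("node_bic with no parents equals the closed-form gaussian BIC", {
  set.seed(71)
  d <- sim_independent(2, 80, 71)
  y <- d$values$V1
  sigma2 <- mean((y - mean(y))^2)
  loglik <- -80 / 2 * (log(2 * pi * sigma2) + 1)
  expect_equal(node_bic(d, "V1"), -2 * loglik)
  expect_error(node_bic(d, "V1", "V1"), "own parent")
})

test_that("a true parent lowers the node BIC", {
  wins <- 0
  for (s in 1:20) {
    d <- sim_chain(500, 1100 + s)
    if (node_bic(d, "X2", "X1") < node_bic(d, "X2")) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("duplicated (collinear) parents leave the score unchanged", {
  d <- sim_chain(200, 72)
  dup <- d$values
  dup$X1b <- dup$X1
  d2 <- mixed_data(dup, c(X1 = "continuous", X2 = "continuous",
                          X3 = "continuous", X1b = "continuous"))
  expect_equal(node_bic(d2, "X2", c("X1", "X1b")),
               node_bic(d2, "X2", "X1"), tolerance = 1e-9)
})

test_that("multinomial node BIC counts coefficients across level blocks", {
  set.seed(73)
  n <- 300
  x <- rnorm(n)
  p <- exp(outer(x, 1:3)); p <- p / rowSums(p)
  g <- vapply(seq_len(n), function(i) sample.int(3, 1, prob = p[i, ]),
              integer(1))
  d <- mixed_data(data.frame(X = x, G = g),
                  c(X = "continuous", G = "categorical"))
  b0 <- node_bic(d, "G")
  b1 <- node_bic(d, "G", "X")
  expect_lt(b1, b0)
  # intercept-only multinomial BIC equals the closed-form multinomial loglik
  freq <- tabulate(d$values$G, 3) / n
  expect_equal(b0, -2 * sum(tabulate(d$values$G, 3) * log(freq)),
               tolerance = 1e-6)
})

test_that("hill climb on an empty skeleton returns the empty DAG", {
  d <- sim_independent(3, 100, 74)
  sk <- list(graph = undirected_graph(d$node_names))
  res <- hill_climb(sk, d)
  expect_equal(nrow(res$graph$edges), 0)
  expect_equal(nrow(res$move_trace), 0)
  expect_equal(res$overall, sum(vapply(d$node_names,
                                       function(v) node_bic(d, v),
                                       numeric(1))), tolerance = 1e-9)
})

test_that("greedy search attains the exhaustive minimum on v-structure data", {
  hits <- 0; n_rep <- 15
  for (s in 1:n_rep) {
    d <- sim_vstructure(600, 1200 + s)
    sk <- undirected_graph(c("X", "Z", "W"),
                           rbind(c("X", "W"), c("W", "Z")))
    res <- hill_climb(list(graph = sk), d)
    cands <- all_dags_on_skeleton(sk$nodes, sk$edges)
    best <- min(vapply(cands, function(g) dag_bic(d, g), numeric(1)))
    if (isTRUE(all.equal(res$overall, best, tolerance = 1e-7))) hits <- hits + 1
    # monotone strict descent and score decomposability
    expect_true(all(res$move_trace$delta < 0))
    expect_equal(res$overall, sum(res$node_scores), tolerance = 1e-9)
    expect_equal(res$overall, dag_bic(d, res$graph), tolerance = 1e-9)
  }
  expect_gte(hits, 14)
})

test_that("termination is a verified local optimum", {
  d <- sim_vstructure(400, 75)
  sk <- undirected_graph(c("X", "Z", "W"), rbind(c("X", "W"), c("W", "Z")))
  res <- hill_climb(list(graph = sk), d)
  # every skeleton-consistent single edge flip/add/delete from the final
  # graph must not lower the total BIC
  edges <- res$graph$edges
  final <- res$overall
  for (i in seq_len(nrow(sk$edges))) {
    a <- sk$edges[i, 1]; b <- sk$edges[i, 2]
    for (alt in list(NULL, c(a, b), c(b, a))) {
      others <- edges[!(edges[, 1] %in% c(a, b) & edges[, 2] %in% c(a, b)), ,
                      drop = FALSE]
      g2 <- tryCatch(directed_graph(sk$nodes, rbind(others, alt)),
                     error = function(e) NULL)
      if (is.null(g2)) next
      expect_gte(dag_bic(d, g2), final - 1e-6)
    }
  }
})

test_that("source-only constraints are never violated and forbidden edges
          never appear", {
  for (s in 1:5) {
    set.seed(1300 + s)
    n <- 500
    snp <- sample(1:3, n, TRUE)
    gexp <- snp + rnorm(n)
    trait <- gexp + rnorm(n)
    d <- mixed_data(data.frame(S = snp, G = gexp, Y = trait),
                    c(S = "categorical", G = "continuous",
                      Y = "continuous"))
    sk <- undirected_graph(c("S", "G", "Y"),
                           rbind(c("G", "S"), c("G", "Y")))
    cons <- direction_constraints(source_only = "S")
    res <- hill_climb(list(graph = sk), d, cons)
    expect_false("S" %in% res$graph$edges[, 2])

    cons2 <- direction_constraints(forbidden = rbind(c("G", "Y")))
    res2 <- hill_climb(list(graph = sk), d, cons2)
    keys <- mixdag:::edge_keys(res2$graph$edges)
    expect_false("G\rY" %in% keys)
  }
})

test_that("directed edges always lie inside the skeleton and stay acyclic", {
  for (s in 1:3) {
    cfg <- scenario_config("custom", n = 300, d = 7, n_edges = 8,
                           frac_categorical = 0.15, seed = 1400 + s)
    inst <- simulate_scenario(cfg)
    fit <- suppressWarnings(
      mixdag(inst$data, control = mixdag_control(B = 50), seed = s))
    sk_keys <- mixdag:::pair_keys(fit$skeleton$graph$edges)
    dag_keys <- mixdag:::pair_keys(fit$dag$graph$edges)
    expect_true(all(dag_keys %in% sk_keys))
    expect_false(is.null(topological_order(fit$dag$graph)))
  }
})
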