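truth3 <- directed_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))

test_that("skeleton metrics match direct counting", {
  perfect <- graph_skeleton(truth3)
  r <- skeleton_metrics(perfect, truth3)
  expect_equal(c(r$sensitivity, r$specificity, r$fdr), c(1, 1, 0))

  est <- undirected_graph(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")))
  r2 <- skeleton_metrics(est, truth3)
  # one of two true edges found; the single true null A-C is estimated;
  # one of two estimated edges is false
  expect_equal(r2$sensitivity, 1 / 2)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$fdr, 1 / 2)

  empty <- undirected_graph(c("A", "B", "C"))
  r3 <- skeleton_metrics(empty, truth3)
  expect_equal(c(r3$sensitivity, r3$specificity, r3$fdr), c(0, 1, 0))
  expect_error(skeleton_metrics(undirected_graph(c("A", "B")), truth3),
               "node sets")
})

test_that("dag metrics respect direction and undetermined-edge exclusion", {
  r <- dag_metrics(truth3, truth3)
  expect_equal(c(r$sensitivity, r$specificity, r$fdr), c(1, 1, 0))

  est <- directed_graph(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  r2 <- dag_metrics(est, truth3)
  expect_equal(r2$sensitivity, 1 / 2)   # C->B direction mismatch
  expect_equal(r2$fdr, 1 / 2)
  expect_equal(r2$specificity, 1)       # the B-C pair is not a true null

  und <- directed_graph(c("A", "B", "C"),
                        undetermined = rbind(c("A", "B"), c("B", "C")))
  r3 <- dag_metrics(und, truth3)
  expect_equal(r3$sensitivity, 0)       # undetermined edges earn no credit
})

test_that("metrics are invariant to consistent node relabeling", {
  relab <- c(A = "N3", B = "N1", C = "N2")
  t2 <- directed_graph(unname(relab[truth3$nodes]),
                       cbind(relab[truth3$edges[, 1]],
                             relab[truth3$edges[, 2]]))
  est <- directed_graph(c("A", "B", "C"), rbind(c("A", "B")))
  est2 <- directed_graph(unname(relab[est$nodes]),
                         cbind(relab[est$edges[, 1]],
                               relab[est$edges[, 2]]))
  r1 <- dag_metrics(est, truth3)
  r2 <- dag_metrics(est2, t2)
  expect_equal(r1[c("sensitivity", "specificity", "fdr")],
               r2[c("sensitivity", "specificity", "fdr")])
})

test_that("dag sensitivity never exceeds skeleton sensitivity on the same
          fully directed estimate", {
  for (s in 1:5) {
    truth <- random_dag(8, 10, seed = 1500 + s)
    est <- random_dag(8, 10, seed = 1600 + s)
    r_sk <- skeleton_metrics(graph_skeleton(est), truth)
    r_dg <- dag_metrics(est, truth)
    expect_lte(r_dg$sensitivity, r_sk$sensitivity + 1e-12)
  }
})

test_that("count bookkeeping is internally consistent", {
  est <- undirected_graph(c("A", "B", "C"), rbind(c("A", "B")))
  r <- skeleton_metrics(est, truth3)
  expect_equal(r$counts$estimated_edges + r$counts$estimated_nulls +
                 r$counts$undetermined_edges, 3)  # d(d-1)/2
})

test_that("batch_evaluate returns a tidy reproducible table", {
  cfg <- scenario_config("custom", n = 150, d = 6, n_edges = 5,
                         frac_categorical = 0.2, seed = 99)
  ctrl <- mixdag_control(B = 30, nlambda = 20)
  t1 <- suppressWarnings(batch_evaluate(cfg, n_replicates = 2,
                                        control = ctrl))
  expect_equal(nrow(t1), 2 * 2 * 3)  # replicates x levels x metrics
  expect_setequal(unique(t1$level), c("skeleton", "dag"))
  expect_setequal(unique(t1$metric), c("sensitivity", "specificity", "fdr"))
  expect_true(all(t1$value >= 0 & t1$value <= 1))
  t2 <- suppressWarnings(batch_evaluate(cfg, n_replicates = 2,
                                        control = ctrl))
  expect_identical(t1, t2)

  t3 <- suppressWarnings(batch_evaluate(cfg, n_replicates = 1, control = ctrl,
                                        coerce_comparison = TRUE))
  expect_setequal(unique(t3$method), c("mdag", "coerced"))
})

test_that("the full pipeline recovers a v-structure end to end", {
  wins <- 0; n_rep <- 5
  for (s in 1:n_rep) {
    d <- sim_vstructure(800, 1700 + s)
    fit <- mixdag(d, control = mixdag_control(B = 100), seed = s)
    e <- fit$dag$graph$edges
    if (nrow(e) == 2 && all(e[, 2] == "W") &&
        setequal(e[, 1], c("X", "Z"))) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("write_mixdag emits the full artifact set", {
  d <- sim_vstructure(300, 77)
  fit <- mixdag(d, control = mixdag_control(B = 50), seed = 7)
  dir <- withr::local_tempdir()
  write_mixdag(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mgm.tsv", "skeleton.tsv", "dag.tsv", "ci_tests.tsv", "moves.tsv",
      "sepsets.tsv")))))
  back <- read_graph(file.path(dir, "dag.tsv"), nodes = d$node_names)
  expect_setequal(mixdag:::edge_keys(back$edges),
                  mixdag:::edge_keys(fit$dag$graph$edges))
})

test_that("coerce_continuous turns categorical columns into numeric codes", {
  d <- sim_mixed_pair(50, 88)
  cc <- coerce_continuous(d)
  expect_true(all(unlist(cc$node_types) == "continuous"))
  expect_equal(cc$values$G, as.numeric(d$values$G))
})
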