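#' Learn a mixed-data DAG
#'
#' Runs the full three-stage pipeline on a mixed dataset: (1) nodewise
#' L1-penalized GLM with EBIC tuning to identify Markov blankets
#' ([build_mgm]); (2) permutation-test pruning of the mixed graphical
#' model to the DAG skeleton inside a PC-stable loop
#' ([estimate_skeleton]); (3) greedy BIC hill climbing to orient the
#' skeleton ([hill_climb]), honoring any direction constraints.
#'
#' @param data a [mixed_data] object, or a data.frame together with
#'   `types`.
#' @param types node-type declaration (see [read_mixed_data]) when `data`
#'   is a raw data.frame.
#' @param constraints a [direction_constraints] object or `NULL`.
#' @param control a [mixdag_control] list of tuning settings.
#' @param seed integer seed driving every randomized component (the
#'   permutation tests); the fit is reproducible given (data, control,
#'   seed).
#' @return an object of class `mixdag` with components `mgm`, `skeleton`,
#'   `dag` (a `scored_dag`), `data`, `control`, `seed`.
#' @examples
#' cfg <- scenario_config("custom", n = 200, d = 6, n_edges = 5,
#'                        frac_categorical = 0.2, seed = 7)
#' inst <- simulate_scenario(cfg)
#' fit <- mixdag(inst$data, control = mixdag_control(B = 50), seed = 7)
#' print(fit)
#' skeleton_metrics(fit$skeleton$graph, inst$truth)
#' @export
mixdag <- function(data, types = NULL, constraints = NULL,
                   control = mixdag_control(), seed = 1) {
  if (!inherits(data, "mixed_data")) {
    if (is.null(types)) stop("supply a mixed_data object or types")
    data <- mixed_data(as.data.frame(data), parse_types(types))
  }
  if (!is.null(constraints)) check_constraints_nodes(constraints,
                                                    data$node_names)
  mgm <- build_mgm(data, gamma = control$gamma, rule = control$rule,
                   nlambda = control$nlambda,
                   lambda_min_ratio = control$lambda_min_ratio)
  skel <- estimate_skeleton(mgm, data, alpha = control$alpha,
                            B = control$B,
                            max_cond_size = control$max_cond_size,
                            seed = seed)
  dag <- hill_climb(skel, data, constraints)
  structure(list(mgm = mgm, skeleton = skel, dag = dag, data = data,
                 constraints = constraints, control = control, seed = seed),
            class = "mixdag")
}

#' Tuning settings for [mixdag]
#'
#' @param gamma EBIC constant for Markov-blanket selection (default 0.5,
#'   the EBIC literature default).
#' @param rule MGM symmetrization rule, `"or"` or `"and"`.
#' @param nlambda,lambda_min_ratio lasso path grid.
#' @param alpha CI-test significance level (default 0.05).
#' @param B permutations per CI test (default 200).
#' @param max_cond_size largest conditioning-set size (default 3).
#' @export
mixdag_control <- function(gamma = 0.5, rule = "or", nlambda = 50,
                           lambda_min_ratio = 0.01, alpha = 0.05, B = 200,
                           max_cond_size = 3) {
  list(gamma = gamma, rule = rule, nlambda = nlambda,
       lambda_min_ratio = lambda_min_ratio, alpha = alpha, B = B,
       max_cond_size = max_cond_size)
}

#' @export
print.mixdag <- function(x, ...) {
  cat("Mixed-data DAG fit\n")
  cat("  data:     ", x$data$n, " samples x ", x$data$d, " variables\n",
      sep = "")
  cat("  MGM:      ", nrow(x$mgm$graph$edges), " edge(s)\n", sep = "")
  cat("  skeleton: ", nrow(x$skeleton$graph$edges), " edge(s) (",
      length(x$skeleton$sepsets), " removed by CI tests)\n", sep = "")
  cat("  DAG:      ", nrow(x$dag$graph$edges),
      " directed edge(s), overall BIC = ",
      format(x$dag$overall, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mixdag <- function(object, ...) {
  x <- object
  cat("Mixed-data DAG fit (alpha = ", x$control$alpha, ", B = ",
      x$control$B, ", gamma = ", x$control$gamma, ", seed = ", x$seed,
      ")\n", sep = "")
  print(x)
  if (nrow(x$dag$graph$edges)) {
    cat("\nDirected edges:\n")
    e <- x$dag$graph$edges
    ord <- order(e[, 1], e[, 2])
    for (i in ord) cat("  ", e[i, 1], " -> ", e[i, 2], "\n", sep = "")
  }
  if (length(x$skeleton$sepsets)) {
    cat("\nSeparation sets (removed MGM edges):\n")
    for (k in sort(names(x$skeleton$sepsets))) {
      K <- x$skeleton$sepsets[[k]]
      cat("  {", sub("\\|", ", ", k), "} | {",
          paste(K, collapse = ", "), "}\n", sep = "")
    }
  }
  invisible(x)
}

#' Plot a fitted mixed-data DAG
#'
#' Uses igraph (if installed) to draw the estimated DAG, with categorical
#' nodes shaded.
#'
#' @param x a `mixdag` fit.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.mixdag <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("plotting requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(x$dag$graph$edges), directed = TRUE,
    vertices = data.frame(name = x$dag$graph$nodes))
  cols <- ifelse(unlist(x$data$node_types[igraph::V(g)$name]) == "categorical",
                 "lightsteelblue", "white")
  igraph::plot.igraph(g, vertex.color = cols, ...)
  invisible(x)
}

#' Write all artifacts of a fit to a directory
#'
#' Emits the MGM, skeleton, final DAG (edge lists), the CI-test log, the
#' hill-climb move trace, and a JSON run manifest.
#'
#' @param fit a `mixdag` object.
#' @param dir output directory (created if absent).
#' @export
write_mixdag <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_graph(fit$mgm$graph, file.path(dir, "mgm.tsv"))
  write_graph(fit$skeleton$graph, file.path(dir, "skeleton.tsv"))
  write_graph(fit$dag$graph, file.path(dir, "dag.tsv"))
  utils::write.table(fit$skeleton$test_log, file.path(dir, "ci_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$dag$move_trace, file.path(dir, "moves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sepsets <- vapply(fit$skeleton$sepsets, paste, character(1), collapse = ",")
  utils::write.table(
    data.frame(pair = names(sepsets) %||% character(0),
               sepset = unname(sepsets)),
    file.path(dir, "sepsets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest <- list(seed = fit$seed, control = fit$control,
                   n = fit$data$n, d = fit$data$d,
                   r_version = as.character(getRversion()))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(manifest)),
               file.path(dir, "manifest.txt"))
  }
  invisible(dir)
}
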