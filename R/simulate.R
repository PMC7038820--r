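#' Generate a random DAG
#'
#' Draws a uniformly random topological order over `d` nodes, then samples
#' `n_edges` distinct ordered pairs consistent with that order, uniformly
#' without replacement. The result is acyclic by construction with exactly
#' `n_edges` edges.
#'
#' @param d number of nodes (named `X1..Xd`).
#' @param n_edges number of edges; at most `d (d - 1) / 2`.
#' @param seed integer seed.
#' @export
random_dag <- function(d, n_edges, seed = 1) {
  max_edges <- d * (d - 1) / 2
  if (n_edges < 0 || n_edges > max_edges) {
    stop("n_edges must be in [0, ", max_edges, "]")
  }
  nodes <- paste0("X", seq_len(d))
  with_seed(seed, {
    ord <- sample(nodes)
    # all order-respecting pairs, then a uniform subset
    idx <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
    take <- if (n_edges > 0) sample(nrow(idx), n_edges) else integer(0)
    edges <- cbind(ord[idx[take, 1]], ord[idx[take, 2]])
    directed_graph(nodes, edges)
  })
}

#' Randomly assign node types
#'
#' Marks a uniformly random subset of `round(frac_categorical * d)` nodes
#' (round half up) as categorical with `n_levels` levels each; the rest are
#' continuous.
#'
#' @param g a `directed_graph`.
#' @param frac_categorical fraction of categorical nodes in `[0, 1]`.
#' @param n_levels levels per categorical node, `>= 2`.
#' @param seed integer seed.
#' @return named list with `node_types` (named character vector) and
#'   `n_levels`.
#' @export
assign_node_types <- function(g, frac_categorical, n_levels = 4, seed = 1) {
  stopifnot(frac_categorical >= 0, frac_categorical <= 1, n_levels >= 2)
  d <- length(g$nodes)
  n_cat <- floor(frac_categorical * d + 0.5)
  cat_nodes <- with_seed(seed, sample(g$nodes, n_cat))
  types <- stats::setNames(rep("continuous", d), g$nodes)
  types[cat_nodes] <- "categorical"
  list(node_types = types, n_levels = n_levels)
}

#' Sample mixed data from a DAG by its structural equation model
#'
#' Nodes are sampled in topological order. A parentless continuous node is
#' `N(0, 1)`; a parentless categorical node is uniform over `{1..L}`. A
#' continuous node with parents is `N(sum of parent values, 1)`, where
#' categorical parents contribute their integer level codes. A categorical
#' node with parents is `Multinomial(1, p)` with
#' `p_l` proportional to `exp(l * sum of parent values)`, `l = 1..L`,
#' computed with max-subtraction for numerical stability. Each node draws
#' from its own seed substream (keyed by node index), so adding nodes does
#' not perturb earlier nodes' draws.
#'
#' @param g a `directed_graph`.
#' @param schema node-type assignment from [assign_node_types].
#' @param n sample size.
#' @param seed integer seed.
#' @return a [mixed_data] object (categorical labels are the level codes).
#' @export
simulate_mixed_data <- function(g, schema, n, seed = 1) {
  ord <- topological_order(g)
  if (is.null(ord)) stop("graph must be acyclic")
  types <- schema$node_types
  L <- schema$n_levels
  vals <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (v in ord) {
    pa <- if (nrow(g$edges)) g$edges[g$edges[, 2] == v, 1] else character(0)
    node_seed <- hash_seed(seed, paste0("node:", match(v, g$nodes)))
    vals[[v]] <- with_seed(node_seed, {
      if (length(pa) == 0) {
        if (types[[v]] == "continuous") stats::rnorm(n)
        else sample.int(L, n, replace = TRUE)
      } else {
        psum <- Reduce(`+`, lapply(pa, function(p) as.numeric(vals[[p]])))
        if (types[[v]] == "continuous") {
          stats::rnorm(n, mean = psum, sd = 1)
        } else {
          # softmax over l * psum with max subtraction
          eta <- outer(psum, seq_len(L))       # n x L
          eta <- eta - apply(eta, 1, max)
          p <- exp(eta) / rowSums(exp(eta))
          vapply(seq_len(n),
                 function(i) sample.int(L, 1, prob = p[i, ]), integer(1))
        }
      }
    })
  }
  df <- as.data.frame(vals, check.names = FALSE)[, g$nodes, drop = FALSE]
  d <- mixed_data(df, types)
  # keep the simulator's own level codes 1..L (mixed_data recodes labels in
  # first-appearance order, which would permute them)
  for (v in names(d$levels)) {
    d$values[[v]] <- as.integer(df[[v]])
    d$levels[[v]] <- list(n_levels = L, labels = as.character(seq_len(L)))
  }
  d
}

#' Simulation scenario presets
#'
#' The study design varies sample size (100, 1000), node count (100, 500),
#' categorical fraction (10%, 20%) and edge count (100, 500), each
#' categorical node having 4 levels. The eight presets `s1..s8` are an
#' even-parity half fraction of the full 2^4 design, covering both extreme
#' corners.
#'
#' @param name preset name `"s1"`..`"s8"`, or `"custom"` together with the
#'   remaining arguments.
#' @param n,d,n_edges,frac_categorical,n_levels custom scenario settings.
#' @param seed integer seed stored in the config.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(name = "custom", n = NULL, d = NULL,
                            n_edges = NULL, frac_categorical = NULL,
                            n_levels = 4, seed = 1) {
  presets <- list(
    s1 = list(n = 100,  d = 100, n_edges = 100, frac_categorical = 0.10),
    s2 = list(n = 100,  d = 100, n_edges = 500, frac_categorical = 0.20),
    s3 = list(n = 100,  d = 500, n_edges = 100, frac_categorical = 0.20),
    s4 = list(n = 100,  d = 500, n_edges = 500, frac_categorical = 0.10),
    s5 = list(n = 1000, d = 100, n_edges = 100, frac_categorical = 0.20),
    s6 = list(n = 1000, d = 100, n_edges = 500, frac_categorical = 0.10),
    s7 = list(n = 1000, d = 500, n_edges = 100, frac_categorical = 0.10),
    s8 = list(n = 1000, d = 500, n_edges = 500, frac_categorical = 0.20))
  if (name != "custom") {
    if (!name %in% names(presets)) stop("unknown scenario preset: ", name)
    cfg <- presets[[name]]
  } else {
    cfg <- list(n = n, d = d, n_edges = n_edges,
                frac_categorical = frac_categorical)
    if (any(vapply(cfg, is.null, logical(1)))) {
      stop("custom scenarios need n, d, n_edges and frac_categorical")
    }
  }
  cfg$n_levels <- n_levels
  cfg$seed <- seed
  cfg$name <- name
  stopifnot(cfg$frac_categorical >= 0, cfg$frac_categorical <= 1,
            cfg$n_edges <= cfg$d * (cfg$d - 1) / 2, cfg$n_levels >= 2)
  structure(cfg, class = "scenario_config")
}

#' Simulate one complete scenario instance
#'
#' Draws the random DAG, assigns node types, and samples the dataset, all
#' from seeds derived from the scenario seed.
#'
#' @param config a [scenario_config].
#' @return list with `truth` (the `directed_graph`), `schema`, and `data`
#'   (a [mixed_data]).
#' @export
simulate_scenario <- function(config) {
  g <- random_dag(config$d, config$n_edges,
                  seed = hash_seed(config$seed, "dag"))
  schema <- assign_node_types(g, config$frac_categorical, config$n_levels,
                              seed = hash_seed(config$seed, "types"))
  data <- simulate_mixed_data(g, schema, config$n,
                              seed = hash_seed(config$seed, "data"))
  list(truth = g, schema = schema, data = data)
}
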