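# In-code fixtures shared across test files.

# All-continuous dataset simulated from a named structural equation list.
# eqs: named list; each element is either NULL (root ~ N(0,1)) or a
# character vector of parents (child = sum(parents) + N(0,1)).
sim_sem <- function(eqs, n, seed) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    vals <- list()
    for (v in names(eqs)) {
      pa <- eqs[[v]]
      mu <- if (is.null(pa)) 0 else Reduce(`+`, vals[pa])
      vals[[v]] <- rnorm(n, mean = mu, sd = 1)
    }
    types <- stats::setNames(rep("continuous", length(eqs)), names(eqs))
    mixed_data(as.data.frame(vals), types)
  })
}

sim_vstructure <- function(n, seed) {
  sim_sem(list(X = NULL, Z = NULL, W = c("X", "Z")), n, seed)
}

sim_chain <- function(n, seed) {
  sim_sem(list(X1 = NULL, X2 = "X1", X3 = "X2"), n, seed)
}

sim_independent <- function(d, n, seed) {
  set.seed(seed)
  vals <- as.data.frame(replicate(d, rnorm(n)))
  names(vals) <- paste0("V", seq_len(d))
  mixed_data(vals, stats::setNames(rep("continuous", d), names(vals)))
}

# Mixed dataset with one binary node depending on a continuous one.
sim_mixed_pair <- function(n, seed, beta = 1.5) {
  set.seed(seed)
  x <- rnorm(n)
  p <- 1 / (1 + exp(-beta * x))
  y <- ifelse(runif(n) < p, "yes", "no")
  mixed_data(data.frame(X = x, G = y),
             c(X = "continuous", G = "categorical"))
}

# Enumerate every DAG over `nodes` whose skeleton is a subset of the given
# undirected pairs; used as the brute-force orientation oracle.
all_dags_on_skeleton <- function(nodes, pairs) {
  n_pairs <- nrow(pairs)
  out <- list()
  # each skeleton pair is absent (0), a->b (1) or b->a (2)
  states <- expand.grid(rep(list(0:2), n_pairs))
  for (r in seq_len(nrow(states))) {
    edges <- matrix(character(0), ncol = 2)
    for (i in seq_len(n_pairs)) {
      s <- states[r, i]
      if (s == 1) edges <- rbind(edges, pairs[i, ])
      if (s == 2) edges <- rbind(edges, rev(pairs[i, ]))
    }
    g <- tryCatch(directed_graph(nodes, edges), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}
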