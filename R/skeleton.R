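#' Prune the mixed graphical model to the DAG skeleton
#'
#' Order-independent PC-stable loop restricted to the MGM's edges: for
#' conditioning-set sizes `s = 0, 1, ..., max_cond_size`, with adjacency
#' sets frozen at the start of each size level, every surviving edge
#' `{j, l}` is tested against all size-`s` subsets of `adj(j) \ {l}` and of
#' `adj(l) \ {j}` (lexicographic order) using [permutation_ci_test]. The
#' first subset certifying conditional independence removes the edge and is
#' recorded as its d-separation set. The loop ends when no frozen adjacency
#' admits a subset of the current size. This removes, in particular, the
#' moralization edges the MGM draws between co-parents of v-structures.
#'
#' @param mgm a `mixed_graphical_model` from [build_mgm] (or any object
#'   with a `$graph` that is an `undirected_graph`).
#' @param data the [mixed_data] the MGM was built on.
#' @param alpha significance level of the CI test.
#' @param B permutations per test.
#' @param max_cond_size largest conditioning-set size tried.
#' @param seed global seed; per-test seeds are derived from it and the
#'   canonical test identity, so the result is invariant to column order.
#' @return a `skeleton` object: list with `graph` (`undirected_graph`),
#'   `sepsets` (named list keyed `"a|b"` with the certifying set), and
#'   `test_log` (data.frame of every test run).
#' @export
estimate_skeleton <- function(mgm, data, alpha = 0.05, B = 200,
                              max_cond_size = 3, seed = 1) {
  if (max_cond_size < 0) stop("max_cond_size must be >= 0")
  graph <- if (inherits(mgm, "undirected_graph")) mgm else mgm$graph
  nodes <- graph$nodes
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      a <- graph$edges[i, 1]; b <- graph$edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  sepsets <- list()
  log_rows <- list()

  s <- 0L
  while (s <= max_cond_size) {
    frozen <- lapply(adj, sort)            # PC-stable: freeze this level
    # does any edge admit a size-s conditioning subset?
    edges_now <- current_edges(adj)
    if (nrow(edges_now) == 0) break
    admits <- any(apply(edges_now, 1, function(e) {
      max(length(frozen[[e[1]]]) - 1L, length(frozen[[e[2]]]) - 1L) >= s
    }))
    if (!admits) break
    for (i in seq_len(nrow(edges_now))) {
      j <- edges_now[i, 1]; l <- edges_now[i, 2]
      if (!(l %in% adj[[j]])) next         # removed earlier this level
      cand <- unique(rbind_subsets(setdiff(frozen[[j]], l),
                                   setdiff(frozen[[l]], j), s))
      for (K in cand) {
        res <- permutation_ci_test(data, j, l, K, B = B, alpha = alpha,
                                   seed = seed)
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          a = res$pair[1], b = res$pair[2],
          K = paste(res$conditioning_set, collapse = ","),
          rho = res$rho_obs, pvalue = res$pvalue, B = res$B,
          decision = res$decision, stringsAsFactors = FALSE)
        if (res$decision == "independent") {
          adj[[j]] <- setdiff(adj[[j]], l)
          adj[[l]] <- setdiff(adj[[l]], j)
          sepsets[[paste(sort(c(j, l)), collapse = "|")]] <- sort(K)
          break
        }
      }
    }
    s <- s + 1L
  }

  test_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(a = character(0), b = character(0), K = character(0),
               rho = numeric(0), pvalue = numeric(0), B = integer(0),
               decision = character(0), stringsAsFactors = FALSE)
  structure(list(graph = undirected_graph(nodes, current_edges(adj)),
                 sepsets = sepsets, test_log = test_log,
                 alpha = alpha, B = B, max_cond_size = max_cond_size,
                 seed = seed),
            class = "skeleton")
}

# canonical (sorted) edge list from an adjacency-list representation
current_edges <- function(adj) {
  rows <- list()
  for (v in sort(names(adj))) {
    for (w in sort(adj[[v]])) {
      if (v < w) rows[[length(rows) + 1L]] <- c(v, w)
    }
  }
  if (length(rows)) do.call(rbind, rows) else matrix(character(0), ncol = 2)
}

# all size-s subsets of either candidate pool, lexicographic, deduplicated
rbind_subsets <- function(pool_j, pool_l, s) {
  subs <- function(pool) {
    pool <- sort(pool)
    if (length(pool) < s) return(list())
    if (s == 0L) return(list(character(0)))
    combs <- utils::combn(pool, s, simplify = FALSE)
    combs[order(vapply(combs, paste, character(1), collapse = "\r"))]
  }
  out <- c(subs(pool_j), subs(pool_l))
  if (!length(out)) return(list())
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[!duplicated(keys)]
}

#' @export
print.skeleton <- function(x, ...) {
  cat("Estimated skeleton: ", length(x$graph$nodes), " nodes, ",
      nrow(x$graph$edges), " edge(s); ", length(x$sepsets),
      " edge(s) removed by CI tests (", nrow(x$test_log),
      " tests, alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
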