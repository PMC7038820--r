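# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (same contract as stats::simulate).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character key, mixed with an integer seed.
# Keyed on node *names* so results do not depend on column order.
hash_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(key)) {
    h <- (h * 131 + cp) %% 2147483647
  }
  as.integer(h)
}

# Canonical key for a conditional-independence test instance.
ci_test_key <- function(j, l, K) {
  pair <- sort(c(j, l))
  paste(pair[1], pair[2], paste(sort(K), collapse = ","), sep = "|")
}

zap_small <- function(x, tol = 1e-8) {
  x[abs(x) < tol] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a model matrix (without intercept column) from selected columns of a
# MixedDataset: continuous columns pass through, categorical columns expand
# to reference-coded indicators for levels 2..L. Optionally drops collinear
# columns by pivoted QR.
build_design <- function(data, vars, drop_collinear = FALSE, warn = TRUE) {
  n <- data$n
  if (length(vars) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  cols <- list()
  for (v in vars) {
    x <- data$values[[v]]
    if (data$node_types[[v]] == "continuous") {
      cols[[v]] <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      L <- data$levels[[v]]$n_levels
      if (L > 1) {
        ind <- vapply(seq(2L, L), function(l) as.numeric(x == l), numeric(n))
        colnames(ind) <- paste0(v, ".l", seq(2L, L))
        cols[[v]] <- ind
      }
    }
  }
  X <- do.call(cbind, cols)
  if (drop_collinear && ncol(X) > 1) {
    qrX <- qr(cbind(1, X))
    keep <- qrX$pivot[seq_len(qrX$rank)]
    keep <- setdiff(keep, 1L) - 1L  # drop the intercept slot, reindex
    if (length(keep) < ncol(X)) {
      if (warn) warning("dropping ", ncol(X) - length(keep),
                        " collinear design column(s)")
      X <- X[, sort(keep), drop = FALSE]
    }
  }
  X
}

# Map design column names back to owning node names ("G.l2" -> "G").
design_owner <- function(colnames, vars) {
  owner <- character(length(colnames))
  for (i in seq_along(colnames)) {
    cn <- colnames[i]
    if (cn %in% vars) {
      owner[i] <- cn
    } else {
      owner[i] <- sub("\\.l[0-9]+$", "", cn)
    }
  }
  owner
}
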