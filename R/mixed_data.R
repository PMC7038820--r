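#' Mixed-type datasets
#'
#' A `mixed_data` object holds an n x d table in which every variable is
#' declared either continuous (real-valued) or categorical (a finite set of
#' unordered levels). Categorical columns are re-coded to integer level codes
#' `1..L_j`, assigned in first-appearance order of the labels, and the
#' label/code mapping is retained. Datasets are validated on construction:
#' no missing values, at least two samples, nonzero variance in every
#' continuous column, and at least two observed levels in every categorical
#' column.
#'
#' @param values a data.frame of raw values (n rows, d columns, named).
#' @param node_types named character vector mapping every column name to
#'   `"continuous"` or `"categorical"`.
#' @return an object of class `mixed_data` with fields `values` (data.frame
#'   of numerics / integer level codes), `node_names`, `node_types`,
#'   `levels` (per categorical node: `n_levels` and `labels`), `n`, `d`.
#' @export
mixed_data <- function(values, node_types) {
  stopifnot(is.data.frame(values))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  nms <- names(values)
  if (is.null(nms) || anyDuplicated(nms)) {
    stop("columns must carry unique names")
  }
  if (is.null(names(node_types))) {
    if (length(node_types) != length(nms)) {
      stop("node_types must be named or match the column count")
    }
    names(node_types) <- nms
  }
  undeclared <- setdiff(nms, names(node_types))
  if (length(undeclared)) {
    stop("no declared type for column(s): ", paste(undeclared, collapse = ", "))
  }
  unknown <- setdiff(names(node_types), nms)
  if (length(unknown)) {
    stop("declared type for absent column(s): ", paste(unknown, collapse = ", "))
  }
  bad <- !node_types %in% c("continuous", "categorical")
  if (any(bad)) {
    stop("node types must be 'continuous' or 'categorical'; offending: ",
         paste(names(node_types)[bad], collapse = ", "))
  }
  node_types <- node_types[nms]

  n <- nrow(values)
  if (n < 2) stop("need at least 2 samples, got ", n)

  # missing-value check with row/column location
  for (v in nms) {
    miss <- which(is.na(values[[v]]) |
                    (is.character(values[[v]]) & !nzchar(trimws(values[[v]]))))
    if (length(miss)) {
      stop("missing value in column '", v, "' at row ", miss[1])
    }
  }

  levels <- list()
  out <- values
  for (v in nms) {
    if (node_types[[v]] == "continuous") {
      x <- suppressWarnings(as.numeric(values[[v]]))
      if (anyNA(x)) {
        stop("column '", v, "' declared continuous but contains non-numeric values")
      }
      if (stats::var(x) == 0) {
        stop("continuous column '", v, "' is constant")
      }
      out[[v]] <- x
    } else {
      labs <- as.character(values[[v]])
      # levels coded 1..L in first-appearance order (deterministic)
      ulabs <- unique(labs)
      if (length(ulabs) < 2) {
        stop("categorical column '", v, "' has fewer than 2 observed levels")
      }
      out[[v]] <- match(labs, ulabs)
      levels[[v]] <- list(n_levels = length(ulabs), labels = ulabs)
    }
  }

  structure(
    list(values = out, node_names = nms, node_types = as.list(node_types),
         levels = levels, n = n, d = length(nms)),
    class = "mixed_data")
}

#' Read a mixed dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row and validates it against a
#' node-type declaration. Types may be given as a named character vector, as
#' a compact string `"name1:continuous,name2:categorical,..."`, or as the
#' path to a two-column (name, type) delimited sidecar file.
#'
#' @param path path to the data file.
#' @param types node-type declaration (see Details).
#' @param sep field separator; `NULL` (default) picks TAB for `.tsv` files
#'   and comma otherwise.
#' @return a [mixed_data] object.
#' @export
read_mixed_data <- function(path, types, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mixed_data(raw, parse_types(types))
}

parse_types <- function(types) {
  if (is.character(types) && length(types) == 1 && grepl(":", types)) {
    parts <- strsplit(strsplit(types, ",")[[1]], ":")
    out <- vapply(parts, function(p) trimws(p[2]), character(1))
    names(out) <- vapply(parts, function(p) trimws(p[1]), character(1))
    return(out)
  }
  if (is.character(types) && length(types) == 1 && file.exists(types)) {
    tab <- utils::read.table(types, header = FALSE, stringsAsFactors = FALSE)
    out <- tab[[2]]
    names(out) <- tab[[1]]
    return(out)
  }
  types
}

#' Write a mixed dataset to delimited text
#'
#' Categorical columns are written using their original labels so that a
#' write/read round trip reproduces the identical values, types and level
#' codings.
#'
#' @param data a [mixed_data] object.
#' @param path output path.
#' @param sep field separator (default TAB).
#' @export
write_mixed_data <- function(data, path, sep = "\t") {
  out <- data$values
  for (v in names(data$levels)) {
    out[[v]] <- data$levels[[v]]$labels[out[[v]]]
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Direction constraints for edge orientation
#'
#' `source_only` nodes (typically SNPs or other genetic variants) may only
#' emit edges: the hill climb never orients an edge into them. `forbidden`
#' is an optional set of ordered pairs i -> j that are disallowed outright.
#'
#' @param source_only character vector of node names.
#' @param forbidden two-column character matrix or data.frame of ordered
#'   (from, to) pairs, or `NULL`.
#' @return an object of class `direction_constraints`.
#' @export
direction_constraints <- function(source_only = character(),
                                  forbidden = NULL) {
  if (!is.null(forbidden)) {
    forbidden <- as.matrix(forbidden)
    if (ncol(forbidden) != 2) stop("forbidden must have two columns (from, to)")
    storage.mode(forbidden) <- "character"
    # an edge out of a source_only node cannot also be forbidden in that
    # direction if it is the only legal one; flag contradictions early
    for (i in seq_len(nrow(forbidden))) {
      if (forbidden[i, 1] %in% source_only) {
        stop("pair (", forbidden[i, 1], ",", forbidden[i, 2],
             ") is both required-outgoing (source_only) and forbidden")
      }
    }
  } else {
    forbidden <- matrix(character(0), ncol = 2)
  }
  structure(list(source_only = unique(source_only), forbidden = forbidden),
            class = "direction_constraints")
}

check_constraints_nodes <- function(constraints, node_names) {
  bad <- setdiff(c(constraints$source_only, as.vector(constraints$forbidden)),
                 node_names)
  if (length(bad)) {
    stop("constraint references unknown node(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.mixed_data <- function(x, ...) {
  q <- length(x$levels)
  cat("Mixed dataset: ", x$n, " samples x ", x$d, " variables (",
      x$d - q, " continuous, ", q, " categorical)\n", sep = "")
  invisible(x)
}
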