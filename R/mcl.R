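#' Markov clustering (MCL) of a weighted similarity graph
#'
#' From-scratch MCL: the column-stochastic transition matrix (with
#' self-loops) is alternately expanded (matrix squaring) and inflated
#' (elementwise power, column renormalization) with pruning of tiny entries
#' until the matrix change falls below `tol`; clusters are read off as the
#' connected components of the converged matrix's non-zero structure. The
#' result is always a partition of the nodes and is deterministic.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`
#'   (similarities > 0; self-loops are added internally with the maximum
#'   incident weight, making the partition invariant to uniform weight
#'   scaling).
#' @param nodes optional character vector of node ids (isolated nodes become
#'   singleton clusters); defaults to nodes present in `edges`.
#' @param inflation inflation exponent (> 1, default 2).
#' @param prune_threshold entries below this are dropped each iteration.
#' @param max_iterations iteration cap; non-convergence is an error carrying
#'   the iteration trace.
#' @param convergence_tol maximum absolute matrix change defining
#'   convergence.
#' @return named character vector: node id -> cluster label ("1", "2", ...;
#'   labels ordered by decreasing cluster size, ties by smallest member id).
#' @export
mcl <- function(edges, nodes = NULL, inflation = 2, prune_threshold = 1e-6,
                max_iterations = 200, convergence_tol = 1e-8) {
  stopifnot(inflation > 1)
  edges <- as.data.frame(edges)
  if (nrow(edges) && any(edges$weight <= 0)) stop("edge weights must be > 0")
  if (nrow(edges) && any(edges$from == edges$to))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  i <- match(edges$from, nodes)
  j <- match(edges$to, nodes)
  w <- as.numeric(edges$weight)
  # Symmetric adjacency + self loops at the max incident weight.
  loop <- rep(if (length(w)) max(w) else 1, n)
  inc_max <- rep(0, n)
  if (length(w)) {
    for (k in seq_along(w)) {
      inc_max[i[k]] <- max(inc_max[i[k]], w[k])
      inc_max[j[k]] <- max(inc_max[j[k]], w[k])
    }
    loop <- ifelse(inc_max > 0, inc_max, max(w))
  }
  M <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(w, w, loop), dims = c(n, n))
  normalize_cols <- function(M) {
    cs <- Matrix::colSums(M)
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize_cols(M)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    M_prev <- M
    M <- M %*% M                       # expansion
    M@x <- M@x^inflation               # inflation
    M <- Matrix::drop0(M, tol = prune_threshold)
    M <- normalize_cols(M)
    delta <- max(abs(M - M_prev))
    trace <- c(trace, delta)
    if (delta < convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    err <- simpleError(sprintf("MCL did not converge in %d iterations",
                               max_iterations))
    err$trace <- trace
    stop(err)
  }
  # Clusters: connected components of the non-zero structure.
  Msym <- (M + Matrix::t(M)) > prune_threshold
  comp <- components_unionfind(Msym)
  labels_by_size(setNames(comp, nodes))
}

# Union-find connected components over a sparse logical/numeric matrix.
components_unionfind <- function(M) {
  n <- nrow(M)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  Mt <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  ii <- Mt@i + 1L
  jj <- Mt@j + 1L
  for (k in seq_along(ii)) {
    ri <- find(ii[k]); rj <- find(jj[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# Relabel a membership vector so cluster "1" is the largest (ties broken by
# the lexicographically smallest member name).
labels_by_size <- function(membership) {
  stopifnot(!is.null(names(membership)))
  split_members <- split(names(membership), membership)
  ord <- order(-vapply(split_members, length, integer(1)),
               vapply(split_members, min, character(1)))
  relabel <- setNames(as.character(seq_along(ord)), names(split_members)[ord])
  setNames(unname(relabel[as.character(membership)]), names(membership))
}
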