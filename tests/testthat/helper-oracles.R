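# Independent oracles used to cross-check the compiled implementations.
# These are deliberately plain, loop-based R implementations.

# Textbook semi-global (overlap) Gotoh alignment. Free terminal gaps in
# both sequences; the aligned core starts and ends with a diagonal column.
# Same scoring and tie-break conventions as the package aligner: diagonal
# over gap-in-a over gap-in-b on equal score; end cell chosen as the first
# strict maximum scanning the last row left-to-right then the last column
# top-to-bottom. Returns identity over aligned core columns (X never a
# match), coverages, and the optimal score.
oracle_align <- function(a, b, gap_open = 11, gap_ext = 1) {
  smat <- get_blosum62_test()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  go <- gap_open + gap_ext; ge <- gap_ext
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- smat[av[i], bv[j]]
      prev <- max(M[i, j], X[i, j], Y[i, j])
      if ((i == 1 || j == 1) && prev < 0) prev <- 0
      M[i + 1, j + 1] <- s + prev
      X[i + 1, j + 1] <- max(M[i + 1, j] - go, X[i + 1, j] - ge,
                             Y[i + 1, j] - go)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - go, Y[i, j + 1] - ge,
                             X[i, j + 1] - go)
    }
  }
  best <- NEG; ie <- -1; je <- -1
  for (j in 1:m) if (M[n + 1, j + 1] > best + 1e-9) {
    best <- M[n + 1, j + 1]; ie <- n; je <- j
  }
  for (i in 1:n) if (M[i + 1, m + 1] > best + 1e-9) {
    best <- M[i + 1, m + 1]; ie <- i; je <- m
  }
  i <- ie; j <- je; state <- "M"
  ncols <- 0L; matches <- 0L; is <- ie; js <- je
  repeat {
    if (state == "M") {
      ncols <- ncols + 1L
      if (av[i] == bv[j] && av[i] != "X") matches <- matches + 1L
      is <- i; js <- j
      prev <- M[i + 1, j + 1] - smat[av[i], bv[j]]
      if (i > 1 && j > 1 && abs(M[i, j] - prev) < 1e-9) {
        i <- i - 1; j <- j - 1; state <- "M"
      } else if (i > 1 && j > 1 && abs(X[i, j] - prev) < 1e-9) {
        i <- i - 1; j <- j - 1; state <- "X"
      } else if (i > 1 && j > 1 && abs(Y[i, j] - prev) < 1e-9) {
        i <- i - 1; j <- j - 1; state <- "Y"
      } else if (abs(prev) < 1e-9) break
      else stop("oracle traceback failed")
    } else if (state == "X") {
      ncols <- ncols + 1L
      cur <- X[i + 1, j + 1]
      if (abs(M[i + 1, j] - go - cur) < 1e-9) { j <- j - 1; state <- "M" }
      else if (abs(X[i + 1, j] - ge - cur) < 1e-9) { j <- j - 1; state <- "X" }
      else if (abs(Y[i + 1, j] - go - cur) < 1e-9) { j <- j - 1; state <- "Y" }
      else stop("oracle traceback failed (X)")
    } else {
      ncols <- ncols + 1L
      cur <- Y[i + 1, j + 1]
      if (abs(M[i, j + 1] - go - cur) < 1e-9) { i <- i - 1; state <- "M" }
      else if (abs(Y[i, j + 1] - ge - cur) < 1e-9) { i <- i - 1; state <- "Y" }
      else if (abs(X[i, j + 1] - go - cur) < 1e-9) { i <- i - 1; state <- "X" }
      else stop("oracle traceback failed (Y)")
    }
  }
  list(score = best, identity = matches / ncols,
       coverage_a = (ie - is + 1) / n, coverage_b = (je - js + 1) / m,
       ncols = ncols, matches = matches)
}

get_blosum62_test <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

# Naive per-codon walk for TTA scanning.
oracle_scan_tta <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  idx <- integer(0)
  i <- 1L; codon_no <- 1L
  while (i + 2 <= n) {
    if (substr(cds, i, i + 2) == "TTA") idx <- c(idx, codon_no)
    i <- i + 3L
    codon_no <- codon_no + 1L
  }
  idx
}

# Exhaustive hypergeometric tails from binomial coefficients.
oracle_hypergeom <- function(N, K, n, k) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  c(p_over = sum(probs[ks >= k]), p_under = sum(probs[ks <= k]))
}

# Dense-matrix MCL, independent of the package's sparse implementation.
oracle_mcl_dense <- function(edges, nodes, inflation = 2,
                             prune = 1e-6, max_iter = 200, tol = 1e-8) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- edges$weight[r]
    A[edges$to[r], edges$from[r]] <- edges$weight[r]
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- if (nrow(edges)) max(edges$weight) else 1
  diag(A) <- loop
  A <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Ap <- A
    A <- A %*% A
    A <- A^inflation
    A[A < prune] <- 0
    A <- sweep(A, 2, colSums(A), "/")
    if (max(abs(A - Ap)) < tol) break
  }
  S <- (A + t(A)) > prune
  # components by repeated BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(S[v, ] & is.na(comp)))
    }
  }
  setNames(comp, nodes)
}

# Random protein of length n (uniform letters, X excluded).
random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n,
               replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  paste(sample(bases, 3 * n_codons, replace = TRUE), collapse = "")
}

# Two partitions agree iff their co-membership relations coincide.
same_partition <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  b <- b[names(a)]
  rand_index(unname(a), unname(b)) == 1
}
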