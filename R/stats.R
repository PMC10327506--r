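#' Exact hypergeometric tail probabilities
#'
#' Both tails of the hypergeometric distribution for drawing `k` marked items
#' in a sample of `n` from a universe of `N` items of which `K` are marked:
#' `p_over = P(X >= k)` and `p_under = P(X <= k)`. Computed with
#' [stats::phyper()] (log-gamma arithmetic, exact to double precision).
#'
#' @param N universe size.
#' @param K marked items in the universe.
#' @param n sample size.
#' @param k marked items observed in the sample.
#' @return named numeric vector `c(p_over, p_under)`.
#' @examples
#' hypergeom_tails(10, 4, 5, 4)
#' @export
hypergeom_tails <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > n || n > N || K > N || k > K ||
      k < max(0, n - (N - K)))
    stop("infeasible hypergeometric configuration (N=", N, ", K=", K,
         ", n=", n, ", k=", k, ")")
  c(p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_under = phyper(k, K, N - K, n))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, `adj_(i) = min_{j >= i} (m * p_(j) / j)` capped
#' at 1 and mapped back to input order. Delegates to
#' [stats::p.adjust()] after validating the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag Z-score outliers against a reference group
#'
#' The reference mean and sample (n-1) standard deviation define
#' `z = (x - mu) / sigma`; values with `|z| > 2` (strict) are flagged with
#' their direction.
#'
#' @param values numeric vector to test.
#' @param reference numeric reference group (>= 3 values).
#' @param threshold flagging threshold on `|z|` (default 2, strict
#'   inequality).
#' @return data.frame with `value`, `z`, `flag` (`"+"`, `"-"` or `""`), plus
#'   attributes `mu`, `sigma`.
#' @export
z_outliers <- function(values, reference, threshold = 2) {
  stopifnot(is.numeric(values), is.numeric(reference))
  if (length(reference) < 3) stop("reference needs >= 3 values")
  mu <- mean(reference)
  sigma <- sd(reference)
  if (sigma == 0) {
    if (any(values != mu)) warning("degenerate reference (sigma = 0)")
    z <- ifelse(values == mu, 0, NA_real_)
  } else {
    z <- (values - mu) / sigma
  }
  flag <- rep("", length(values))
  flag[!is.na(z) & z > threshold] <- "+"
  flag[!is.na(z) & z < -threshold] <- "-"
  flag[is.na(z)] <- "degenerate reference"
  out <- data.frame(value = values, z = z, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Jaccard distance between two sets
#'
#' `1 - |A intersect B| / |A union B|`, with the convention that the distance
#' between two empty sets is 0.
#'
#' @param a,b vectors treated as sets.
#' @return numeric distance in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Intra-species feature-content variability
#'
#' Mean pairwise Jaccard distance of per-genome feature sets within a
#' species, computed over complete genomes only (draft assemblies cannot
#' guarantee feature integrity). Species with fewer than two complete
#' genomes are skipped with a log entry.
#'
#' @param genomes list of [genome()] objects of one species.
#' @param feature_extractor function(genome) -> character vector (the
#'   feature set); defaults to the genome's feature labels.
#' @return list with `mean_distance`, `pairs` (data.frame of pairwise
#'   distances), `n_genomes_used`, `skipped` (logical) and `log`.
#' @export
intra_species_variability <- function(genomes,
                                      feature_extractor = function(g)
                                        unique(g$labels$label)) {
  complete <- Filter(function(g) g$assembly_level == "complete", genomes)
  if (length(complete) < 2) {
    return(list(mean_distance = NA_real_,
                pairs = data.frame(genome_a = character(),
                                   genome_b = character(),
                                   distance = numeric()),
                n_genomes_used = length(complete), skipped = TRUE,
                log = sprintf("skipped: %d complete genome(s) < 2",
                              length(complete))))
  }
  sets <- lapply(complete, feature_extractor)
  ids <- vapply(complete, function(g) g$genome_id, character(1))
  cmb <- utils::combn(length(sets), 2)
  d <- apply(cmb, 2, function(ij) jaccard_distance(sets[[ij[1]]],
                                                   sets[[ij[2]]]))
  list(mean_distance = mean(d),
       pairs = data.frame(genome_a = ids[cmb[1, ]], genome_b = ids[cmb[2, ]],
                          distance = d, stringsAsFactors = FALSE),
       n_genomes_used = length(complete), skipped = FALSE,
       log = sprintf("used %d complete genomes", length(complete)))
}

#' Species accumulation curve
#'
#' Cumulative number of distinct species recovered as genomes accrue. With
#' `order`, genomes are taken in that order (e.g. a release_order rank);
#' otherwise `orderings` random orderings are averaged under `seed`.
#'
#' @param species character/factor vector, one species assignment per genome.
#' @param order optional integer permutation giving the accrual order.
#' @param orderings number of random orderings to average when `order` is
#'   `NULL`.
#' @param seed RNG seed for random orderings.
#' @return data.frame with `x` (genomes) and `y` (species; mean over
#'   orderings when randomized).
#' @export
species_accumulation <- function(species, order = NULL, orderings = 1,
                                 seed = 1) {
  n <- length(species)
  stopifnot(n >= 1)
  one_curve <- function(idx) {
    sp <- species[idx]
    cumsum(!duplicated(sp))
  }
  if (!is.null(order)) {
    stopifnot(setequal(order, seq_len(n)))
    y <- one_curve(order)
  } else {
    y <- with_seed(seed, {
      rowMeans(vapply(seq_len(orderings),
                      function(i) one_curve(sample.int(n)),
                      numeric(n)))
    })
  }
  data.frame(x = seq_len(n), y = y)
}

#' Fit the exponential-recovery saturation curve
#'
#' Least-squares fit of `y = a * (1 - exp(-x / b))` to an accumulation
#' curve, the asymptote `a` estimating total species richness. The sum of
#' squared errors is minimized by multi-start Nelder-Mead on a fixed
#' deterministic start grid (`a` in `max(y) * c(1, 2, 4, 8)`, `b` in
#' `max(x) * c(0.1, 0.3, 1, 3)`), optimizing `log(a)`, `log(b)` to enforce
#' positivity.
#'
#' @param x,y curve points (x increasing, y non-negative).
#' @return list of class `"saturation_fit"` with `a`, `b`, `sse`,
#'   `n_points`, and `trace` (per-start SSE and convergence flag).
#' @export
fit_saturation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, all(diff(x) > 0),
            all(y >= 0))
  if (all(y == 0)) stop("degenerate curve: all y are zero")
  sse <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((y - a * (1 - exp(-x / b)))^2)
  }
  starts <- expand.grid(a = max(y) * c(1, 2, 4, 8),
                        b = max(x) * c(0.1, 0.3, 1, 3))
  trace <- data.frame(a_start = starts$a, b_start = starts$b,
                      sse_start = NA_real_, sse = NA_real_, a = NA_real_,
                      b = NA_real_, converged = NA)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(c(starts$a[i], starts$b[i]))
    fit <- optim(p0, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    trace$sse_start[i] <- sse(p0)
    trace$sse[i] <- fit$value
    trace$a[i] <- exp(fit$par[1])
    trace$b[i] <- exp(fit$par[2])
    trace$converged[i] <- fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(a = exp(best$par[1]), b = exp(best$par[2]),
                 sse = best$value, n_points = length(x), trace = trace),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "<saturation_fit> y = a(1 - exp(-x/b)): a = %.3f, b = %.3f (sse %.4g, %d points)\n",
    x$a, x$b, x$sse, x$n_points))
  invisible(x)
}

#' Pairwise Pearson correlations with BH correction
#'
#' Pearson r and two-sided p (exact t-transform, n-2 df) for every column
#' pair of a per-species feature count table, BH-adjusted across all pairs
#' tested in the call. Constant columns yield `NA` correlations and are
#' excluded from the BH family.
#'
#' @param counts numeric data.frame/matrix, one row per species, one column
#'   per feature.
#' @return data.frame with `feature_x`, `feature_y`, `r`, `p`, `p_adj`.
#' @export
feature_correlations <- function(counts) {
  counts <- as.data.frame(counts)
  if (!all(vapply(counts, is.numeric, logical(1))))
    stop("all columns must be numeric")
  if (nrow(counts) < 3) stop("need >= 3 rows (species)")
  nm <- names(counts)
  cmb <- utils::combn(length(nm), 2)
  res <- data.frame(feature_x = nm[cmb[1, ]], feature_y = nm[cmb[2, ]],
                    r = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    xv <- counts[[cmb[1, i]]]; yv <- counts[[cmb[2, i]]]
    if (sd(xv) == 0 || sd(yv) == 0) next
    ct <- cor.test(xv, yv, method = "pearson")
    res$r[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  tested <- !is.na(res$p)
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res
}
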