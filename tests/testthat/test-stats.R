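test_that("hypergeometric tails match exhaustive enumeration", {
  expect_equal(unname(hypergeom_tails(10, 4, 5, 4)["p_over"]), 6 / 252,
               tolerance = 1e-12)
  # boundary: k at its maximum
  t <- hypergeom_tails(10, 4, 5, 4)
  expect_equal(unname(t["p_over"]),
               unname(oracle_hypergeom(10, 4, 5, 4)["p_over"]))
  # K = N forces all successes
  expect_equal(unname(hypergeom_tails(8, 8, 3, 3)["p_over"]), 1)
  expect_error(hypergeom_tails(10, 4, 5, 5), "infeasible")
  expect_error(hypergeom_tails(10, 12, 5, 3), "infeasible")
  # spot grid against the enumeration oracle
  withr::local_seed(61)
  for (i in 1:200) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    klo <- max(0, n - (N - K)); khi <- min(n, K)
    k <- if (klo == khi) klo else sample(seq(klo, khi), 1)
    got <- hypergeom_tails(N, K, n, k)
    exp <- oracle_hypergeom(N, K, n, k)
    expect_equal(unname(got), unname(exp), tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::local_seed(62)
  p <- runif(25)
  adj <- bh_adjust(p)
  # step-up validity: adjusted in [p, 1], monotone in rank order
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("z-score outliers use the sample sd and a strict threshold", {
  ref <- c(rep(1, 9), 11)
  out <- z_outliers(c(11, 2), ref)
  expect_equal(attr(out, "mu"), 2)
  expect_equal(attr(out, "sigma"), sqrt(10), tolerance = 1e-12)
  expect_equal(out$z[1], 9 / sqrt(10), tolerance = 1e-12)
  expect_equal(out$flag[1], "+")
  expect_equal(out$flag[2], "")          # value at the mean
  # |z| of exactly 2 is not flagged (strict threshold)
  ref2 <- c(1, 2, 3)                     # mu 2, sample sd exactly 1
  expect_equal(z_outliers(4, ref2)$flag, "")
  expect_equal(z_outliers(4.0000001, ref2)$flag, "+")
  expect_equal(z_outliers(-20, ref)$flag, "-")
  expect_warning(z_outliers(5, c(3, 3, 3)), "degenerate")
  expect_error(z_outliers(1, c(1, 2)), ">= 3")
})

test_that("jaccard distance satisfies its axioms", {
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  # triangle inequality on random sets
  withr::local_seed(63)
  pool <- letters
  for (i in 1:50) {
    A <- sample(pool, sample(0:10, 1))
    B <- sample(pool, sample(0:10, 1))
    C <- sample(pool, sample(0:10, 1))
    expect_lte(jaccard_distance(A, C),
               jaccard_distance(A, B) + jaccard_distance(B, C) + 1e-12)
  }
})

test_that("intra-species variability uses complete genomes and matches brute force", {
  mk <- function(id, labels, level = "complete") {
    toy_genome(data.frame(gene_id = paste0(id, "_g"), replicon_id = "chr",
                          start = 0, end = 6, strand = "+", cds = "ATGTGA",
                          protein = "M", stringsAsFactors = FALSE),
               strrep("ACGT", 10), genome_id = id,
               assembly_level = level,
               labels = if (length(labels))
                 data.frame(gene_id = paste0(id, "_g"), label = labels,
                            stringsAsFactors = FALSE) else NULL)
  }
  same <- lapply(1:5, function(i) mk(paste0("g", i), c("NRPS", "GH13")))
  expect_equal(intra_species_variability(same)$mean_distance, 0)
  disj <- list(mk("a", "NRPS"), mk("b", "GH13"))
  expect_equal(intra_species_variability(disj)$mean_distance, 1)
  # draft genomes are excluded; fewer than 2 complete genomes skips
  skip <- list(mk("a", "NRPS"), mk("b", "GH13", level = "draft"))
  r <- intra_species_variability(skip)
  expect_true(r$skipped)
  expect_true(is.na(r$mean_distance))
  # brute-force recomputation on random sets
  withr::local_seed(64)
  sets <- lapply(1:5, function(i) sample(LETTERS[1:20], sample(2:8, 1)))
  gl <- lapply(1:5, function(i) mk(paste0("g", i), sets[[i]]))
  got <- intra_species_variability(gl)$mean_distance
  cmb <- combn(5, 2)
  exp <- mean(apply(cmb, 2, function(ij)
    1 - length(intersect(sets[[ij[1]]], sets[[ij[2]]])) /
      length(union(sets[[ij[1]]], sets[[ij[2]]]))))
  expect_equal(got, exp)
})

test_that("species accumulation is monotone with the right endpoints", {
  sp <- c("x", "x", "y", "y", "z", "z")
  cur <- species_accumulation(sp, order = 1:6)
  expect_equal(cur$y, c(1, 1, 2, 2, 3, 3))
  expect_equal(species_accumulation(rep("only", 4), order = 1:4)$y,
               rep(1, 4))
  # final y equals the number of distinct species for any ordering
  withr::local_seed(65)
  for (i in 1:5) {
    o <- sample(6)
    expect_equal(tail(species_accumulation(sp, order = o)$y, 1), 3)
  }
  # randomized mean curves from different seeds agree within MC error
  sp2 <- rep(letters[1:8], times = c(8, 5, 4, 3, 2, 2, 1, 1))
  m1 <- species_accumulation(sp2, orderings = 200, seed = 1)$y
  m2 <- species_accumulation(sp2, orderings = 200, seed = 2)$y
  expect_lt(max(abs(m1 - m2)), 0.5)
  expect_true(all(diff(m1) >= -1e-9))
})

test_that("saturation fitting recovers parameters and respects its contract", {
  x <- 1:100
  y <- 100 * (1 - exp(-x / 20))
  f <- fit_saturation(x, y)
  expect_lt(abs(f$a - 100) / 100, 0.001)
  expect_lt(abs(f$b - 20) / 20, 0.005)
  # SSE at the optimum is never above any grid start
  expect_true(all(f$sse <= f$trace$sse_start + 1e-9))
  # already-saturated curve: a tends to the constant, sse to 0
  fc <- fit_saturation(1:20, rep(50, 20))
  expect_equal(fc$a, 50, tolerance = 0.01)
  expect_lt(fc$sse, 1e-4)
  expect_error(fit_saturation(1:10, rep(0, 10)), "degenerate")
  expect_error(fit_saturation(c(1, 1, 2), c(1, 2, 3)))
})

test_that("saturation fitting tolerates gaussian noise", {
  withr::local_seed(66)
  rel_err <- replicate(30, {
    x <- 1:50
    y <- pmax(0, 100 * (1 - exp(-x / 20)) + rnorm(50, 0, 2))
    f <- fit_saturation(x, y)
    abs(f$a - 100) / 100
  })
  expect_lt(median(rel_err), 0.1)
})

test_that("feature correlations report r, exact p and BH-adjusted p", {
  x <- c(1, 3, 5, 7, 11, 13)
  d <- data.frame(a = x, b = 2 * x, c = c(2, 1, 4, 3, 7, 6))
  fc <- feature_correlations(d)
  expect_equal(fc$r[fc$feature_x == "a" & fc$feature_y == "b"], 1)
  expect_true(all(fc$p_adj >= fc$p - 1e-12, na.rm = TRUE))
  # constant columns yield NA and are excluded from the family
  d2 <- data.frame(a = x, k = rep(4, 6))
  fc2 <- feature_correlations(d2)
  expect_true(is.na(fc2$r))
  expect_error(feature_correlations(data.frame(a = letters[1:5])),
               "numeric")
  # null simulation: BH-significant fraction stays near the nominal level
  withr::local_seed(67)
  sig <- replicate(30, {
    m <- as.data.frame(matrix(rpois(60 * 4, 10), ncol = 4))
    f <- feature_correlations(m)
    mean(f$p_adj < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(sig), 0.05 + 0.03)
  # planted linear coupling is detected
  hits <- replicate(20, {
    n <- 40
    sdr <- rpois(n, 6)
    m <- data.frame(cazyme = 3 * sdr + rpois(n, 4), siderophore = sdr,
                    other = rpois(n, 8))
    f <- feature_correlations(m)
    f$p_adj[f$feature_x == "cazyme" & f$feature_y == "siderophore"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})
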