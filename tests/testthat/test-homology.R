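test_that("aligner identity behaves on identity, substitution and edge cases", {
  r <- align_proteins("MKVL", "MKVL")
  expect_equal(r$identity, 1)
  expect_equal(r$coverage_a, 1)
  expect_equal(r$coverage_b, 1)
  expect_equal(align_proteins("MKVL", "MKIL")$identity, 0.75)
  # X is tolerated but never a match
  expect_lt(align_proteins("MKXL", "MKXL")$identity, 1)
  expect_error(align_proteins("", "MKVL"), "empty")
  expect_error(align_proteins("MK1L", "MKVL"), "illegal character")
  # symmetry of identity and swapped coverages
  a <- "MKVLTTAGWERT"; b <- "MKVLGWERT"
  r1 <- align_proteins(a, b); r2 <- align_proteins(b, a)
  expect_equal(r1$identity, r2$identity)
  expect_equal(r1$coverage_a, r2$coverage_b)
})

test_that("aligner equals the textbook DP oracle exactly on random pairs", {
  withr::local_seed(11)
  for (i in 1:30) {
    na <- sample(30:120, 1); nb <- sample(30:120, 1)
    a <- random_protein(na)
    b <- if (i %% 3 == 0) {
      bs <- strsplit(a, "")[[1]]
      s <- sample(na, round(na * 0.3))
      bs[s] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                      length(s), TRUE)
      paste(bs, collapse = "")
    } else random_protein(nb)
    got <- align_proteins(a, b)
    exp <- oracle_align(a, b)
    expect_identical(got$score, exp$score)
    expect_identical(got$identity, exp$identity)
    expect_identical(got$coverage_a, exp$coverage_a)
    expect_identical(got$coverage_b, exp$coverage_b)
  }
})

test_that("within-genome homolog search finds pairs and respects thresholds", {
  withr::local_seed(2)
  p1 <- random_protein(120)
  genes <- data.frame(
    gene_id = c("a", "b", "c"), replicon_id = "chr",
    start = c(0, 400, 800), end = c(363, 763, 1163), strand = "+",
    cds = "ATGTGA", protein = c(p1, p1, random_protein(120)),
    stringsAsFactors = FALSE)
  g <- toy_genome(genes, paste(rep("A", 1200), collapse = ""))
  h <- within_genome_homologs(g)
  expect_equal(nrow(h$pairs), 1)
  expect_equal(sort(c(h$pairs$gene_a, h$pairs$gene_b)), c("a", "b"))
  expect_equal(h$pairs$identity, 1)
  # n proteins give at most C(n,2) pairs
  expect_lte(nrow(within_genome_homologs(g, min_identity = 0)$pairs), 3)
  # unrelated random proteins share ~5% identity, far below 0.5
  expect_true(is.na(h$best_hit[["c"]]) || h$best_hit[["c"]] < 0.5)
  # raising min_identity never increases the pair count
  n1 <- nrow(within_genome_homologs(g, min_identity = 0.3)$pairs)
  n2 <- nrow(within_genome_homologs(g, min_identity = 0.9)$pairs)
  expect_lte(n2, n1)
})

test_that("identity bins are lower-exclusive upper-inclusive with singleton floor", {
  # craft proteins with controlled best-hit identity: 60 matching of 100
  withr::local_seed(3)
  base <- random_protein(100)
  mutate_to <- function(p, identity) {
    v <- strsplit(p, "")[[1]]
    n <- length(v)
    k <- round((1 - identity) * n)
    pos <- sample(n, k)
    for (i in pos) {
      v[i] <- setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], v[i])[1]
    }
    paste(v, collapse = "")
  }
  p60 <- mutate_to(base, 0.60)
  genes <- data.frame(
    gene_id = c("a", "b"), replicon_id = "chr",
    start = c(0, 400), end = c(303, 703), strand = "+",
    cds = "ATGTGA", protein = c(base, p60), stringsAsFactors = FALSE)
  g <- toy_genome(genes, paste(rep("A", 800), collapse = ""))
  prof <- identity_bin_profile(g)
  hit <- within_genome_homologs(g, min_identity = 0)$best_hit[["a"]]
  # best hit exactly in (0.5, 0.6] falls in the 51-60 bin
  if (hit > 0.5 && hit <= 0.6)
    expect_equal(prof$count[prof$bin == "51-60"], 2)
  expect_equal(sum(prof$fraction), 1)
  # two unrelated proteins are both singletons
  g2 <- toy_genome(data.frame(
    gene_id = c("a", "b"), replicon_id = "chr",
    start = c(0, 400), end = c(303, 703), strand = "+",
    cds = "ATGTGA", protein = c(random_protein(100), random_protein(100)),
    stringsAsFactors = FALSE), paste(rep("A", 800), collapse = ""))
  prof2 <- identity_bin_profile(g2)
  expect_equal(prof2$fraction[prof2$bin == "singleton"], 1)
  # a genome of identical twins is all 91-100
  g3 <- toy_genome(data.frame(
    gene_id = c("a", "b"), replicon_id = "chr",
    start = c(0, 400), end = c(303, 703), strand = "+",
    cds = "ATGTGA", protein = c(base, base), stringsAsFactors = FALSE),
    paste(rep("A", 800), collapse = ""))
  expect_equal(identity_bin_profile(g3)$fraction[7], 1)
})

test_that("bin fractions are invariant under gene-order permutation", {
  g <- tiny_sim()$genomes[[1]]
  p1 <- identity_bin_profile(g)
  g2 <- g
  g2$genes <- g$genes[rev(seq_len(nrow(g$genes))), ]
  p2 <- identity_bin_profile(g2)
  expect_equal(p1$fraction, p2$fraction)
})

test_that("cross-species close-homolog rule requires identity and length jointly", {
  withr::local_seed(4)
  q <- random_protein(100)
  # exact copy in another species
  expect_true(cross_species_close_homolog_exists(q, c(q, random_protein(80))))
  # unrelated background only
  expect_false(cross_species_close_homolog_exists(
    q, vapply(1:5, function(i) random_protein(100), character(1))))
  # full identity but covering only 40% of the query fails the dual rule
  frag <- substr(q, 1, 40)
  expect_false(cross_species_close_homolog_exists(q, frag))
  expect_true(cross_species_close_homolog_exists(q, frag,
                                                 min_length_frac = 0.3))
})

test_that("k-mer prefilter matches the exhaustive search on small instances", {
  sim <- tiny_sim()
  prot <- all_proteins(sim$genomes[1:3])
  prot <- prot[1:min(50, length(prot))]
  pre <- homolog_pairs(prot, 0.5, 0.5, exhaustive = FALSE)
  exh <- homolog_pairs(prot, 0.5, 0.5, exhaustive = TRUE)
  key <- function(d) paste(pmin(d$gene_a, d$gene_b),
                           pmax(d$gene_a, d$gene_b))
  expect_setequal(key(pre), key(exh))
  expect_equal(pre$identity[order(key(pre))],
               exh$identity[order(key(exh))])
})
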