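test_that("scan_tta counts whole in-frame codons only", {
  g <- list(gene_id = "g", cds = "ATGTTATTATAA", translatable = TRUE)
  r <- scan_tta(g)
  expect_equal(r$codon_indices, c(2, 3))
  expect_equal(r$count, 2)
  # TTA substring spanning a codon boundary is not a TTA codon
  expect_null(scan_tta(list(gene_id = "g", cds = "ATGCTTATTTAA",
                            translatable = TRUE)))
  # non-translatable genes are skipped
  expect_null(scan_tta(list(gene_id = "g", cds = "ATGTTATTATAA",
                            translatable = FALSE)))
})

test_that("scan_tta equals the naive codon-walk oracle on random CDS", {
  withr::local_seed(51)
  for (i in 1:200) {
    cds <- random_cds(sample(10:80, 1))
    got <- scan_tta(list(gene_id = "g", cds = cds, translatable = TRUE))
    exp <- oracle_scan_tta(cds)
    if (length(exp) == 0) expect_null(got)
    else expect_identical(got$codon_indices, as.integer(exp))
  }
})

test_that("minus-strand genes are scanned on the coding strand", {
  # genomic forward strand lacks TTA; coding strand carries one
  cds <- "ATGTTATGA"
  chrom <- paste0("CC", revcomp(cds), "CC")
  g <- toy_genome(data.frame(
    gene_id = "g1", replicon_id = "chr", start = 2, end = 11,
    strand = "-", cds = cds, protein = "ML", stringsAsFactors = FALSE),
    chrom)
  expect_false(grepl("TTA", chrom, fixed = TRUE))
  s <- genome_tta_summary(g)
  expect_equal(s$n_tta_genes, 1)
})

test_that("genome summary counts TTA genes and the single-TTA fraction", {
  genes <- data.frame(
    gene_id = c("a", "b", "c"), replicon_id = "chr",
    start = c(0, 20, 40), end = c(12, 32, 49), strand = "+",
    cds = c("ATGTTATTATGA", "ATGTTAAAATGA", "ATGAAAAAATGA"),
    protein = c("MLL", "MLK", "MKK"), stringsAsFactors = FALSE)
  g <- toy_genome(genes, strrep("A", 60))
  s <- genome_tta_summary(g)
  expect_equal(s$n_tta_genes, 2)
  expect_equal(s$single_tta_fraction, 0.5)
  # zero planted TTA
  g0 <- toy_genome(genes[3, ], strrep("A", 60))
  expect_equal(genome_tta_summary(g0)$n_tta_genes, 0)
})

test_that("conservation recovers planted any-position and site-specific fractions", {
  sim <- tiny_sim()
  og <- tiny_orthogroups()
  cl <- tiny_clusters()
  tta <- sim$truth$tta
  fam_of <- setNames(sim$truth$genes$family_id, sim$truth$genes$gene_id)
  ns <- sim$config$n_species
  for (i in seq_len(nrow(tta))) {
    genes <- sim$truth$genes$gene_id[
      sim$truth$genes$family_id == tta$family_id[i]]
    ogid <- unique(og$members$og_id[og$members$gene_id %in% genes])
    expect_length(ogid, 1)
    tc <- tta_conservation(ogid, og, cl, sim$genomes)
    planted_frac <- length(strsplit(tta$species[i], ",")[[1]]) / ns
    expect_equal(tc$species_with_og, ns)
    expect_lte(abs(tc$any_fraction - planted_frac), 1 / ns)
    expect_true(tta$codon_index[i] %in% tc$conserved_sites)
    expect_equal(unname(tc$site_fractions[
      as.character(tta$codon_index[i])]), tc$any_fraction)
  }
})

test_that("TTA at non-homologous positions yields any-conservation without site conservation", {
  sim <- tiny_sim()
  fam <- sim$truth$families$family_id[
    sim$truth$families$class == "genus_core" & !sim$truth$families$tta][1]
  anc <- sim$internal$anc_aa[[fam]]
  lpos <- which(anc == "L"); lpos <- lpos[lpos > 1]
  # need two distinct leucine sites
  expect_gte(length(lpos), 2)
  sim2 <- plant_tta(sim, fam, lpos[1], "sp01")
  sim2 <- plant_tta(sim2, fam, lpos[2], c("sp02", "sp03"))
  og <- build_orthogroups(sim2$genomes)
  cl <- demarcate_species(sim2$genomes, fragment_length = 500)
  genes <- sim2$truth$genes$gene_id[sim2$truth$genes$family_id == fam]
  ogid <- unique(og$members$og_id[og$members$gene_id %in% genes])
  tc <- tta_conservation(ogid, og, cl, sim2$genomes)
  expect_equal(tc$any_fraction, 1)
  # sites split 1/3 and 2/3: only the second meets the 50% rule
  expect_equal(tc$conserved_sites, lpos[2])
  # an orthogroup confined to one species is a contract error
  sc_fam <- sim$truth$families$family_id[
    sim$truth$families$class == "fingerprint"][1]
  sc_genes <- sim$truth$genes$gene_id[
    sim$truth$genes$family_id == sc_fam]
  sc_og <- unique(og$members$og_id[og$members$gene_id %in% sc_genes])
  expect_error(tta_conservation(sc_og, og, cl, sim2$genomes),
               "fewer than 2 species")
})

test_that("category enrichment is calibrated under the null and powered under planted bias", {
  withr::local_seed(53)
  n_genes <- 300
  n_draws <- 80
  cats <- sample(LETTERS[1:10], n_genes, replace = TRUE)
  make_genome <- function(tta_flags) {
    genes <- data.frame(
      gene_id = sprintf("g%03d", 1:n_genes), replicon_id = "chr",
      start = seq(0, by = 20, length.out = n_genes),
      end = seq(0, by = 20, length.out = n_genes) + 12,
      strand = "+",
      cds = ifelse(tta_flags, "ATGTTAAAATGA", "ATGCTGAAATGA"),
      protein = "MLK", category = cats, stringsAsFactors = FALSE)
    toy_genome(genes, strrep("A", 20 * n_genes + 20))
  }
  # null: TTA drawn uniformly; count significant over-verdicts over seeds
  fp <- 0; n_seeds <- 20
  for (s in 1:n_seeds) {
    tta_flags <- seq_len(n_genes) %in% sample(n_genes, n_draws)
    enr <- tta_category_enrichment(make_genome(tta_flags))
    fp <- fp + sum(enr$verdict == "over")
  }
  expect_lte(fp / (n_seeds * 10), 0.1)
  # planted: category A three times as likely among TTA genes
  hits <- 0
  for (s in 1:n_seeds) {
    w <- ifelse(cats == "A", 3, 1)
    tta_flags <- seq_len(n_genes) %in%
      sample(n_genes, n_draws, prob = w)
    enr <- tta_category_enrichment(make_genome(tta_flags))
    hits <- hits + (enr$verdict[enr$category == "A"] == "over")
  }
  expect_gte(hits / n_seeds, 0.9)
  # fold change is zero when observed equals background
  enr0 <- tta_category_enrichment(make_genome(rep(c(TRUE, FALSE),
                                                  n_genes / 2)))
  even <- enr0[abs(enr0$k / enr0$n - enr0$K / enr0$N) < 1e-9, ]
  if (nrow(even)) expect_true(all(abs(even$log2_fc) < 1e-9))
})
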