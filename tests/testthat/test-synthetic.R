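test_that("generator yields the configured genome count and planted structure", {
  sim <- tiny_sim()
  cfg <- sim$config
  expect_length(sim$genomes, 9)
  expect_equal(nrow(sim$truth$partition), 9)
  fam <- sim$truth$families
  expect_equal(sum(fam$class == "genus_core"), 8)
  expect_equal(sum(fam$class == "fingerprint"), 6)
  # fingerprint families occur in all strains of their species and nowhere else
  for (i in which(fam$class == "fingerprint")) {
    tg <- sim$truth$genes[sim$truth$genes$family_id == fam$family_id[i], ]
    sp <- sim$truth$partition$species_id[
      match(tg$genome_id, sim$truth$partition$genome_id)]
    expect_setequal(unique(sp), fam$species[i])
    expect_equal(nrow(tg), 3)
  }
  # every generated gene maps to exactly one family
  expect_false(anyDuplicated(sim$truth$genes$gene_id) > 0)
})

test_that("fixed seed reproduces byte-identical output", {
  cfg <- sim_config(n_species = 2, strains_per_species = 2,
                    n_genus_core_families = 4,
                    n_species_core_families_per_species = 1,
                    n_fingerprint_families_per_species = 1,
                    accessory_family_pool = 4,
                    mean_protein_length = 100, seed = 99)
  s1 <- generate_pangenome(cfg, verify_ani = FALSE)
  s2 <- generate_pangenome(cfg, verify_ani = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pangenome(s1, d1); write_pangenome(s2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("realized within-species protein identity hits its target", {
  withr::local_seed(1)
  sim <- tiny_sim()
  target <- sim$config$within_species_protein_identity
  tg <- sim$truth$genes
  fams <- sample(unique(tg$family_id), 20)
  prot <- all_proteins(sim$genomes)
  part <- setNames(sim$truth$partition$species_id,
                   sim$truth$partition$genome_id)
  ids <- NULL
  for (f in fams) {
    m <- tg[tg$family_id == f & !grepl("_p2$", tg$gene_id), ]
    m <- m[order(m$gene_id), ]
    sp <- part[m$genome_id]
    for (s in unique(sp)) {
      gg <- m$gene_id[sp == s]
      if (length(gg) >= 2) {
        cmb <- combn(gg, 2)
        for (p in seq_len(ncol(cmb)))
          ids <- c(ids, align_proteins(prot[[cmb[1, p]]],
                                       prot[[cmb[2, p]]])$identity)
      }
    }
  }
  expect_gt(mean(ids), target - 0.01)
  expect_lt(mean(ids), target + 0.01)
})

test_that("chromosomes hit the GC target and genes never overlap", {
  sim <- tiny_sim()
  for (g in sim$genomes[1:3]) {
    chrom <- g$seqs[[chromosome_id(g)]]
    chars <- strsplit(chrom, "")[[1]]
    gc <- mean(chars %in% c("G", "C"))
    expect_lt(abs(gc - sim$config$gc_content), 0.02)
    genes <- g$genes[order(g$genes$start), ]
    expect_true(all(genes$start[-1] >= head(genes$end, -1)))
  }
})

test_that("planted TTA codons land at the planted index in the planted species", {
  sim <- tiny_sim()
  tta <- sim$truth$tta
  expect_gt(nrow(tta), 0)
  part <- setNames(sim$truth$partition$species_id,
                   sim$truth$partition$genome_id)
  for (i in seq_len(nrow(tta))) {
    planted_sp <- strsplit(tta$species[i], ",")[[1]]
    tg <- sim$truth$genes[sim$truth$genes$family_id == tta$family_id[i] &
                            !grepl("_p2$", sim$truth$genes$gene_id), ]
    for (r in seq_len(nrow(tg))) {
      g <- sim$genomes[[tg$genome_id[r]]]
      row <- g$genes[g$genes$gene_id == tg$gene_id[r], ]
      rec <- scan_tta(row)
      if (part[[tg$genome_id[r]]] %in% planted_sp) {
        expect_equal(rec$codon_indices, tta$codon_index[i])
      } else {
        expect_null(rec)
      }
    }
  }
})

test_that("plant_tta validates its contract and modifies all members coherently", {
  sim <- tiny_sim()
  fam <- sim$truth$families$family_id[sim$truth$families$class ==
                                        "genus_core" &
                                        !sim$truth$families$tta][1]
  anc <- sim$internal$anc_aa[[fam]]
  lpos <- which(anc == "L")
  lpos <- lpos[lpos > 1][1]
  expect_false(is.na(lpos))
  notl <- which(anc != "L" & seq_along(anc) > 1)[1]
  expect_error(plant_tta(sim, fam, notl, "sp01"), "leucine")
  expect_error(plant_tta(sim, fam, length(anc) + 10, "sp01"),
               "out of range")
  sim2 <- plant_tta(sim, fam, lpos, c("sp01", "sp02"))
  tg <- sim2$truth$genes[sim2$truth$genes$family_id == fam &
                           !grepl("_p2$", sim2$truth$genes$gene_id), ]
  part <- setNames(sim2$truth$partition$species_id,
                   sim2$truth$partition$genome_id)
  for (r in seq_len(nrow(tg))) {
    g <- sim2$genomes[[tg$genome_id[r]]]
    row <- g$genes[g$genes$gene_id == tg$gene_id[r], ]
    codon <- substr(row$cds, 3 * (lpos - 1) + 1, 3 * lpos)
    expect_equal(codon,
                 if (part[[tg$genome_id[r]]] %in% c("sp01", "sp02"))
                   "TTA" else "CTG")
    # chromosome sequence stays consistent with the cds
    chrom <- g$seqs[[row$replicon_id]]
    seg <- substr(chrom, row$start + 1, row$end)
    expect_equal(if (row$strand == "+") seg else revcomp(seg), row$cds)
    expect_equal(substr(row$protein, lpos, lpos), "L")
  }
})

test_that("truth_report flattens classes, plants and the partition", {
  sim <- tiny_sim()
  rep <- truth_report(sim$truth)
  expect_named(rep, c("families", "tta_plants", "partition", "genes"))
  fp <- rep$families[rep$families$class == "fingerprint", ]
  expect_equal(nrow(fp), 6)
  expect_equal(sort(unique(fp$species)), c("sp01", "sp02", "sp03"))
  expect_equal(nrow(rep$partition), length(sim$genomes))
})

test_that("an explicitly infeasible chromosome length is rejected", {
  cfg <- sim_config(n_species = 2, strains_per_species = 2,
                    n_genus_core_families = 30,
                    mean_protein_length = 300,
                    chromosome_length = 20000, seed = 1)
  expect_error(generate_pangenome(cfg, verify_ani = FALSE), "infeasible")
})
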