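make_clusters <- function(assign) {
  structure(list(
    clusters = data.frame(cluster_id = unname(assign),
                          genome_id = names(assign),
                          stringsAsFactors = FALSE),
    representatives = tapply(names(assign), unname(assign), min)),
    class = "species_clusters")
}

test_that("normalization caps at five with complete-assembly priority", {
  ids <- sprintf("g%02d", 1:9)
  cl <- make_clusters(setNames(rep("C0", 9), ids))
  md <- data.frame(genome_id = ids,
                   assembly_level = c(rep("complete", 3), rep("draft", 6)),
                   stringsAsFactors = FALSE)
  nd <- normalize_dataset(cl, md)
  expect_equal(nd$selected$genome_id,
               c("g01", "g02", "g03", "g04", "g05"))
  expect_true(all(grepl("selected", nd$log$decision[1:5])))
  expect_true(all(grepl("rejected", nd$log$decision[6:9])))
  # 9 complete genomes: first five by id
  md2 <- md; md2$assembly_level <- "complete"
  expect_equal(normalize_dataset(cl, md2)$selected$genome_id, ids[1:5])
  # fewer genomes than the cap: all selected
  cl2 <- make_clusters(c(a = "C0", b = "C0"))
  md3 <- data.frame(genome_id = c("a", "b"), assembly_level = "draft")
  expect_equal(normalize_dataset(cl2, md3)$selected$genome_id, c("a", "b"))
})

fake_og <- function(presence) {
  # presence: logical matrix og x genome; fabricate one member per TRUE
  members <- do.call(rbind, lapply(rownames(presence), function(og) {
    gs <- colnames(presence)[presence[og, ]]
    if (!length(gs)) return(NULL)
    data.frame(og_id = og, gene_id = paste0(gs, "_", og), genome_id = gs,
               stringsAsFactors = FALSE)
  }))
  structure(list(members = members, presence = presence * 1L,
                 edges = NULL), class = "orthogroups")
}

test_that("genus core thresholds are boundary-inclusive with exact arithmetic", {
  gids <- sprintf("g%02d", 1:20)
  pres <- matrix(TRUE, 3, 20, dimnames = list(c("o1", "o2", "o3"), gids))
  pres["o2", 20] <- FALSE           # 19/20 = 0.95 exactly
  pres["o3", 19:20] <- FALSE        # 18/20 = 0.90 exactly
  og <- fake_og(pres)
  cs <- genus_core(gids, og)
  expect_setequal(cs$cores$core_100, "o1")
  expect_setequal(cs$cores$core_95, c("o1", "o2"))
  expect_setequal(cs$cores$core_90, c("o1", "o2", "o3"))
  # nesting invariant
  expect_true(all(cs$cores$core_100 %in% cs$cores$core_95))
  expect_true(all(cs$cores$core_95 %in% cs$cores$core_90))
  expect_error(genus_core(gids, og, thresholds = c(0.9, 0.95, 1)),
               "descending")
})

test_that("species core and accessory partition the species' orthogroups", {
  sim <- tiny_sim()
  og <- tiny_orthogroups()
  cl <- tiny_clusters()
  nd <- tiny_dataset()
  for (cid in unique(nd$selected$cluster_id)) {
    ca <- species_core_accessory(cid, cl, nd, og)
    ids <- nd$selected$genome_id[nd$selected$cluster_id == cid]
    pres <- og$presence[, ids, drop = FALSE] > 0
    all_ogs <- rownames(pres)[rowSums(pres) > 0]
    expect_setequal(c(ca$core, ca$accessory), all_ogs)
    expect_length(intersect(ca$core, ca$accessory), 0)
  }
})

test_that("removing a genome can only grow a species core", {
  sim <- tiny_sim()
  og <- tiny_orthogroups()
  cl <- tiny_clusters()
  nd <- tiny_dataset()
  cid <- nd$selected$cluster_id[1]
  full <- species_core_accessory(cid, cl, nd, og)
  nd2 <- nd
  drop_id <- nd$selected$genome_id[nd$selected$cluster_id == cid][1]
  nd2$selected <- nd2$selected[nd2$selected$genome_id != drop_id, ]
  reduced <- species_core_accessory(cid, cl, nd2, og)
  expect_true(all(full$core %in% reduced$core))
})

test_that("fingerprint definition excludes spill-over families and strictness removes homologs", {
  sim <- tiny_sim()
  og <- tiny_orthogroups()
  cl <- tiny_clusters()
  nd <- tiny_dataset()
  truth <- sim$truth
  part <- setNames(truth$partition$species_id, truth$partition$genome_id)
  # cluster <-> species mapping via membership
  cmap <- tapply(part[cl$clusters$genome_id], cl$clusters$cluster_id,
                 function(v) unique(v))
  all_fp <- character(0)
  for (cid in names(cmap)) {
    fp <- detect_fingerprints(cid, cl, nd, og, sim$genomes)
    expect_true(all(fp$strict %in% fp$relaxed))
    planted <- truth$families$family_id[
      truth$families$class == "fingerprint" &
        truth$families$species == cmap[[cid]]]
    # map ogs back to families through member genes
    fam_of <- setNames(truth$genes$family_id, truth$genes$gene_id)
    got_fam <- vapply(fp$relaxed, function(o)
      unique(fam_of[og$members$gene_id[og$members$og_id == o]])[1],
      character(1))
    expect_setequal(unname(got_fam), planted)
    expect_length(fp$strict, length(planted))
    all_fp <- c(all_fp, fp$relaxed)
  }
  # fingerprint sets of different species are disjoint
  expect_false(anyDuplicated(all_fp) > 0)
})

test_that("a family in all strains of A plus one strain of B is no fingerprint, and a planted cross-homolog demotes strict", {
  gids <- c("a1", "a2", "b1", "b2")
  cl <- make_clusters(c(a1 = "CA", a2 = "CA", b1 = "CB", b2 = "CB"))
  md <- data.frame(genome_id = gids, assembly_level = "complete",
                   stringsAsFactors = FALSE)
  nd <- normalize_dataset(cl, md)
  pres <- matrix(FALSE, 3, 4, dimnames = list(c("o1", "o2", "o3"), gids))
  pres["o1", c("a1", "a2")] <- TRUE               # true fingerprint of CA
  pres["o2", c("a1", "a2", "b1")] <- TRUE          # leaks into CB
  pres["o3", gids] <- TRUE                         # core everywhere
  og <- fake_og(pres)
  withr::local_seed(6)
  p_fp <- random_protein(100)
  prot_of <- function(gid) {
    if (grepl("o1", gid)) p_fp
    else if (grepl("o2", gid)) random_protein(90)
    else random_protein(80)
  }
  genomes <- lapply(gids, function(g) {
    gs <- og$members$gene_id[og$members$genome_id == g]
    n <- length(gs)
    toy_genome(data.frame(
      gene_id = gs, replicon_id = "chr",
      start = seq(0, by = 400, length.out = n),
      end = seq(0, by = 400, length.out = n) + 303,
      strand = "+", cds = "ATGTGA",
      protein = vapply(gs, prot_of, character(1)),
      stringsAsFactors = FALSE), strrep("A", 400 * n + 400),
      genome_id = g)
  })
  names(genomes) <- gids
  fp <- detect_fingerprints("CA", cl, nd, og, genomes)
  expect_setequal(fp$relaxed, "o1")
  expect_setequal(fp$strict, "o1")
  # plant a close homolog of the fingerprint in species B (outside its og)
  genomes$b2$genes$protein[1] <- p_fp
  fp2 <- detect_fingerprints("CA", cl, nd, og, genomes)
  expect_setequal(fp2$relaxed, "o1")
  expect_length(fp2$strict, 0)
})

test_that("the per-species summary table is coherent", {
  sim <- tiny_sim()
  st <- species_summary_table(tiny_clusters(), tiny_dataset(),
                              tiny_orthogroups(), sim$genomes)
  expect_equal(nrow(st), 3)
  expect_true(all(st$strict_fingerprints <= st$relaxed_fingerprints))
  expect_true(all(st$core_orthogroups + st$accessory_orthogroups > 0))
  expect_true(all(st$n_genomes == 3))
})
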