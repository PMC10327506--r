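# Shared small synthetic datasets, generated once per test run.

.sim_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# 3 species x 3 strains, desk-minimal family structure.
tiny_sim <- function() memo("tiny", {
  generate_pangenome(sim_config(
    n_species = 3, strains_per_species = 3,
    n_genus_core_families = 8,
    n_species_core_families_per_species = 2,
    n_fingerprint_families_per_species = 2,
    accessory_family_pool = 10,
    mean_protein_length = 150,
    tta_orthogroup_fraction = 0.5,
    seed = 5), verify_ani = FALSE)
})

tiny_orthogroups <- function() memo("tiny_og", {
  build_orthogroups(tiny_sim()$genomes)
})

tiny_clusters <- function() memo("tiny_cl", {
  demarcate_species(tiny_sim()$genomes, fragment_length = 500)
})

tiny_dataset <- function() memo("tiny_nd", {
  normalize_dataset(tiny_clusters(), tiny_sim()$metadata)
})

# Hand-built single-replicon genome for unit tests.
toy_genome <- function(genes, chrom, genome_id = "gX",
                       assembly_level = "complete", labels = NULL,
                       topology = "linear") {
  genome(genome_id = genome_id, species_label = "toy",
         assembly_level = assembly_level,
         replicons = data.frame(replicon_id = "chr", topology = topology,
                                stringsAsFactors = FALSE),
         seqs = c(chr = chrom), genes = genes, labels = labels)
}

# A minimal genome whose chromosome is plain background with genes at
# chosen midpoints (cds content irrelevant for zone tests).
zone_toy <- function(midpoints, L = 1000, protein = "MKLV") {
  cds <- "ATGAAACTTGTGTGA"
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_along(midpoints)),
    replicon_id = "chr",
    start = as.integer(midpoints - 7L),
    end = as.integer(midpoints + 8L),
    strand = "+", cds = cds, protein = protein,
    stringsAsFactors = FALSE)
  chrom <- paste(rep("A", L), collapse = "")
  toy_genome(genes, chrom)
}
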