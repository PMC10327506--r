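#' Normalize a genome collection to at most `cap` genomes per species
#'
#' For each species cluster, selects up to `cap` genomes: all complete
#' assemblies first (in lexicographic genome-id order), then drafts by
#' lexicographic id, logging every decision. Sequencing effort is heavily
#' biased toward a few species, so capping the per-species sample makes
#' core/fingerprint statistics comparable across species.
#'
#' @param clusters a [demarcate_species()] result.
#' @param metadata data.frame with `genome_id`, `assembly_level`.
#' @param cap maximum genomes per species (default 5).
#' @return object of class `"normalized_dataset"`: list with `selected`
#'   (data.frame `cluster_id`, `genome_id`, `assembly_level`) and
#'   `log` (data.frame of per-genome decisions).
#' @export
normalize_dataset <- function(clusters, metadata, cap = 5) {
  cl <- clusters$clusters
  level <- setNames(metadata$assembly_level, metadata$genome_id)
  sel_rows <- list(); log_rows <- list()
  for (cid in sort(unique(cl$cluster_id))) {
    members <- sort(cl$genome_id[cl$cluster_id == cid])
    lv <- level[members]
    ordered <- c(sort(members[lv == "complete"]),
                 sort(members[lv != "complete"]))
    chosen <- head(ordered, cap)
    sel_rows[[cid]] <- data.frame(cluster_id = cid, genome_id = chosen,
                                  assembly_level = unname(level[chosen]),
                                  stringsAsFactors = FALSE)
    log_rows[[cid]] <- data.frame(
      cluster_id = cid, genome_id = ordered,
      assembly_level = unname(level[ordered]),
      decision = ifelse(ordered %in% chosen,
                        ifelse(level[ordered] == "complete",
                               "selected (complete priority)",
                               "selected (draft)"),
                        "rejected (cap reached)"),
      stringsAsFactors = FALSE)
  }
  structure(list(selected = do.call(rbind, c(sel_rows,
                                             make.row.names = FALSE)),
                 log = do.call(rbind, c(log_rows, make.row.names = FALSE))),
            class = "normalized_dataset")
}

# Exact-rational presence threshold: count/total >= t with t expressed in
# hundredths, avoiding float boundary errors at e.g. 19/20 vs 0.95.
presence_meets <- function(count, total, t) {
  count * 100L >= round(t * 100) * total
}

#' Genus-level hard and soft core orthogroups
#'
#' An orthogroup belongs to the level-`t` core iff it is present (>= 1
#' member gene) in at least a fraction `t` of the normalized genomes;
#' thresholds are compared with exact integer arithmetic so that e.g.
#' presence in 19 of 20 genomes meets the 0.95 level. Core sets are nested:
#' hard (100 %) within soft-95 within soft-90.
#'
#' @param dataset a [normalize_dataset()] result (or a character vector of
#'   genome ids).
#' @param orthogroups a [build_orthogroups()] result over exactly those
#'   genomes.
#' @param thresholds descending presence fractions (default 1, 0.95, 0.90).
#' @return object of class `"core_sets"`: list with `scope = "genus"`,
#'   `cores` (named list of og-id vectors per threshold), and
#'   `presence_fraction` (named numeric per og).
#' @export
genus_core <- function(dataset, orthogroups,
                       thresholds = c(1.00, 0.95, 0.90)) {
  if (any(diff(thresholds) >= 0)) stop("thresholds must be descending")
  ids <- if (inherits(dataset, "normalized_dataset"))
    dataset$selected$genome_id else dataset
  pres <- presence_logical(orthogroups)[, ids, drop = FALSE]
  count <- rowSums(pres)
  total <- length(ids)
  cores <- lapply(thresholds, function(t)
    rownames(pres)[presence_meets(count, total, t)])
  names(cores) <- sprintf("core_%d", round(thresholds * 100))
  for (i in seq_along(cores)[-1])
    stopifnot(all(cores[[i - 1]] %in% cores[[i]]))  # nesting invariant
  structure(list(scope = "genus", cores = cores,
                 presence_fraction = setNames(count / total, rownames(pres)),
                 n_genomes = total),
            class = "core_sets")
}

#' Species-level core and accessory orthogroups
#'
#' Within one species cluster (its selected genomes), the core is the set
#' of orthogroups present in 100 % of genomes and the accessory those
#' present in at least one but not all. Protein-level counts in the
#' species' representative genome are also reported. A species with a
#' single selected genome gets its whole proteome as core (flagged
#' low-confidence).
#'
#' @param cluster_id species cluster id.
#' @param clusters a [demarcate_species()] result.
#' @param dataset a [normalize_dataset()] result.
#' @param orthogroups a [build_orthogroups()] result.
#' @return object of class `"core_sets"` with `scope = "species"`, fields
#'   `core`, `accessory` (og-id vectors), `core_proteins`,
#'   `accessory_proteins` (gene counts in the representative genome),
#'   `n_genomes`, `low_confidence`.
#' @export
species_core_accessory <- function(cluster_id, clusters, dataset,
                                   orthogroups) {
  sel <- dataset$selected
  ids <- sel$genome_id[sel$cluster_id == cluster_id]
  if (!length(ids)) stop("unknown or empty cluster: ", cluster_id)
  pres <- presence_logical(orthogroups)[, ids, drop = FALSE]
  count <- rowSums(pres)
  core <- rownames(pres)[count == length(ids)]
  accessory <- rownames(pres)[count >= 1 & count < length(ids)]
  rep_g <- clusters$representatives[[cluster_id]]
  mem <- orthogroups$members
  rep_counts <- table(mem$og_id[mem$genome_id == rep_g])
  structure(list(scope = "species", cluster_id = cluster_id,
                 core = core, accessory = accessory,
                 core_proteins = sum(rep_counts[core], na.rm = TRUE),
                 accessory_proteins = sum(rep_counts[accessory],
                                          na.rm = TRUE),
                 n_genomes = length(ids),
                 low_confidence = length(ids) < 2),
            class = "core_sets")
}

#' Detect species fingerprint orthogroups
#'
#' Relaxed fingerprints of a species are orthogroups present in 100 % of
#' its selected genomes and in zero genomes of every other species in the
#' normalized dataset. Strict fingerprints additionally lack any
#' cross-species close homolog: the fingerprint's representative protein
#' must have no hit at >= 50 % identity over >= 50 % of its length among
#' the proteins of all other species' genomes.
#'
#' @param cluster_id species cluster id.
#' @param clusters a [demarcate_species()] result.
#' @param dataset a [normalize_dataset()] result.
#' @param orthogroups a [build_orthogroups()] result over the normalized
#'   genomes.
#' @param genomes named list of [genome()] objects (for protein lookup).
#' @param min_identity,min_length_frac strict-homolog thresholds.
#' @param exhaustive passed to the cross-species homolog search.
#' @return object of class `"fingerprint_set"`: list with `cluster_id`,
#'   `relaxed`, `strict` (og-id vectors, `strict` a subset of `relaxed`),
#'   and `representative` (named character og_id -> gene_id).
#' @export
detect_fingerprints <- function(cluster_id, clusters, dataset, orthogroups,
                                genomes, min_identity = 0.5,
                                min_length_frac = 0.5, exhaustive = FALSE) {
  sel <- dataset$selected
  ids <- sel$genome_id[sel$cluster_id == cluster_id]
  other_ids <- sel$genome_id[sel$cluster_id != cluster_id]
  if (!length(ids)) stop("unknown or empty cluster: ", cluster_id)
  pres <- presence_logical(orthogroups)
  in_all_own <- rowSums(pres[, ids, drop = FALSE]) == length(ids)
  in_none_other <- rowSums(pres[, other_ids, drop = FALSE]) == 0
  relaxed <- rownames(pres)[in_all_own & in_none_other]

  # Representative gene: member in the species' representative genome
  # (smallest gene id), falling back to the smallest member id.
  rep_g <- clusters$representatives[[cluster_id]]
  mem <- orthogroups$members[orthogroups$members$og_id %in% relaxed, ,
                             drop = FALSE]
  rep_gene <- vapply(relaxed, function(og) {
    m <- mem[mem$og_id == og, ]
    in_rep <- m$gene_id[m$genome_id == rep_g]
    if (length(in_rep)) min(in_rep) else min(m$gene_id)
  }, character(1))

  strict <- character(0)
  if (length(relaxed)) {
    prot <- all_proteins(genomes)
    g_of <- gene_genome_map(genomes)
    other_prot <- prot[names(prot) %in%
                         names(g_of)[g_of %in% other_ids]]
    queries <- setNames(prot[rep_gene], names(rep_gene))
    hits <- cross_homolog_hits(queries, other_prot, min_identity,
                               min_length_frac, exhaustive)
    strict <- relaxed[!unlist(hits[relaxed])]
  }
  structure(list(cluster_id = cluster_id, relaxed = relaxed,
                 strict = strict, representative = rep_gene),
            class = "fingerprint_set")
}

#' Per-species pan-genome summary table
#'
#' One row per species cluster: chromosomal protein count of the
#' representative genome, core and accessory orthogroup and protein counts,
#' and relaxed/strict fingerprint counts.
#'
#' @param clusters a [demarcate_species()] result.
#' @param dataset a [normalize_dataset()] result.
#' @param orthogroups a [build_orthogroups()] result.
#' @param genomes named list of [genome()] objects.
#' @param ... passed to [detect_fingerprints()].
#' @return data.frame, one row per species cluster.
#' @export
species_summary_table <- function(clusters, dataset, orthogroups, genomes,
                                  ...) {
  by_id <- setNames(genomes, vapply(genomes, function(g) g$genome_id,
                                    character(1)))
  rows <- lapply(sort(unique(dataset$selected$cluster_id)), function(cid) {
    ca <- species_core_accessory(cid, clusters, dataset, orthogroups)
    fp <- detect_fingerprints(cid, clusters, dataset, orthogroups, genomes,
                              ...)
    rep_g <- by_id[[clusters$representatives[[cid]]]]
    data.frame(cluster_id = cid,
               representative = rep_g$genome_id,
               n_genomes = ca$n_genomes,
               chromosomal_proteins = nrow(chromosome_genes(rep_g)),
               core_orthogroups = length(ca$core),
               core_proteins = ca$core_proteins,
               accessory_orthogroups = length(ca$accessory),
               accessory_proteins = ca$accessory_proteins,
               relaxed_fingerprints = length(fp$relaxed),
               strict_fingerprints = length(fp$strict),
               low_confidence = ca$low_confidence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
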