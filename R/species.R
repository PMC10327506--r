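#' Demarcate species by ANI and Markov clustering
#'
#' Builds a genome graph with an edge wherever pairwise ANI meets the
#' species cutoff (conventionally 95 %), weighted by the raw ANI value, and
#' partitions it with [mcl()]. Undefined ANI values are absent edges, never
#' zero. Cluster ids are `C0, C1, ...` by descending member count (ties by
#' lexicographically smallest genome id); each cluster's representative is
#' its complete-assembly genome with the smallest id, falling back to the
#' smallest id overall.
#'
#' @param genomes named list of [genome()] objects.
#' @param ani_cutoff minimum ANI for an edge (default 0.95).
#' @param ani_table optional precomputed [ani_matrix()] output; computed on
#'   the fly when `NULL`.
#' @param inflation,prune_threshold,max_iterations,convergence_tol MCL
#'   parameters, see [mcl()].
#' @param ... passed to [ani_matrix()] when `ani_table` is `NULL`.
#' @return object of class `"species_clusters"`: list with `clusters`
#'   (data.frame `cluster_id`, `genome_id`), `representatives` (named
#'   character, cluster_id -> genome_id) and `ani_table`.
#' @export
demarcate_species <- function(genomes, ani_cutoff = 0.95, ani_table = NULL,
                              inflation = 2, prune_threshold = 1e-6,
                              max_iterations = 200, convergence_tol = 1e-8,
                              ...) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (is.null(ani_table)) ani_table <- ani_matrix(genomes, ...)
  keep <- !is.na(ani_table$ani) & ani_table$ani >= ani_cutoff
  edges <- data.frame(from = ani_table$genome_a[keep],
                      to = ani_table$genome_b[keep],
                      weight = ani_table$ani[keep], stringsAsFactors = FALSE)
  part <- mcl(edges, nodes = ids, inflation = inflation,
              prune_threshold = prune_threshold,
              max_iterations = max_iterations,
              convergence_tol = convergence_tol)
  # Relabel to C0, C1, ... by size (mcl already orders by size).
  cluster_id <- paste0("C", as.integer(part) - 1L)
  clusters <- data.frame(cluster_id = cluster_id,
                         genome_id = names(part), stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id, clusters$genome_id), ]
  rownames(clusters) <- NULL
  level <- setNames(vapply(genomes, function(g) g$assembly_level,
                           character(1)), ids)
  reps <- vapply(split(clusters$genome_id, clusters$cluster_id),
                 function(members) {
                   complete <- members[level[members] == "complete"]
                   if (length(complete)) min(complete) else min(members)
                 }, character(1))
  structure(list(clusters = clusters, representatives = reps,
                 ani_table = ani_table),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  sizes <- table(x$clusters$cluster_id)
  cat(sprintf("<species_clusters> %d genomes in %d clusters\n",
              nrow(x$clusters), length(sizes)))
  invisible(x)
}

#' Flag species-name misannotations against ANI clusters
#'
#' Reports (a) species labels split across two or more clusters and (b)
#' clusters containing two or more distinct species labels.
#'
#' @param clusters a [demarcate_species()] result.
#' @param metadata data.frame with `genome_id`, `species_label`.
#' @return list with data.frames `split_labels` (`species_label`,
#'   `clusters`) and `mixed_clusters` (`cluster_id`, `labels`).
#' @export
flag_misannotations <- function(clusters, metadata) {
  cl <- clusters$clusters
  lab <- setNames(metadata$species_label, metadata$genome_id)
  cl$label <- unname(lab[cl$genome_id])
  by_label <- split(cl$cluster_id, cl$label)
  split_lab <- Filter(function(v) length(unique(v)) > 1, by_label)
  by_cluster <- split(cl$label, cl$cluster_id)
  mixed <- Filter(function(v) length(unique(v)) > 1, by_cluster)
  list(split_labels = data.frame(
         species_label = names(split_lab),
         clusters = vapply(split_lab, function(v)
           paste(sort(unique(v)), collapse = ","), character(1)),
         stringsAsFactors = FALSE, row.names = NULL),
       mixed_clusters = data.frame(
         cluster_id = names(mixed),
         labels = vapply(mixed, function(v)
           paste(sort(unique(v)), collapse = ","), character(1)),
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Is a set of genomes monophyletic on a tree?
#'
#' TRUE iff the smallest clade of the rooted tree containing `genome_ids`
#' contains no other leaves (via [ape::is.monophyletic()]).
#'
#' @param tree an [ape::phylo] tree (treated as rooted, as given).
#' @param genome_ids leaf labels to test; all must be present in the tree.
#' @return logical scalar.
#' @export
check_monophyly <- function(tree, genome_ids) {
  missing <- setdiff(genome_ids, tree$tip.label)
  if (length(missing))
    stop("leaves missing from tree: ", paste(missing, collapse = ", "))
  if (length(genome_ids) == length(tree$tip.label)) return(TRUE)
  ape::is.monophyletic(tree, genome_ids)
}
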