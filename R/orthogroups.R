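#' Build orthogroups across genomes
#'
#' Constructs the all-vs-all protein homology graph (edges where identity
#' and coverage-of-the-shorter-protein meet the thresholds, weighted by
#' identity) and partitions it with [mcl()]. Proteins left unclustered
#' become singleton orthogroups. Orthogroup ids `og00001, og00002, ...` are
#' assigned by decreasing member count (ties by smallest gene id), making
#' the construction invariant to genome input order.
#'
#' @param genomes named list of [genome()] objects (>= 2).
#' @param min_identity,min_coverage edge thresholds (defaults 0.5/0.5, the
#'   close-homolog rule).
#' @param inflation MCL inflation.
#' @param exhaustive if FALSE (default) a shared-k-mer prefilter skips
#'   hopeless protein pairs before alignment.
#' @return object of class `"orthogroups"`: list with `members`
#'   (data.frame `og_id`, `gene_id`, `genome_id`), `presence` (integer
#'   matrix orthogroups x genomes of member counts), and `edges`.
#' @export
build_orthogroups <- function(genomes, min_identity = 0.5,
                              min_coverage = 0.5, inflation = 2,
                              exhaustive = FALSE) {
  stopifnot(length(genomes) >= 2)
  prot <- all_proteins(genomes)
  g_of <- gene_genome_map(genomes)
  pairs <- homolog_pairs(prot, min_identity, min_coverage,
                         exhaustive = exhaustive)
  part <- mcl(data.frame(from = pairs$gene_a, to = pairs$gene_b,
                         weight = pairs$identity,
                         stringsAsFactors = FALSE),
              nodes = names(prot), inflation = inflation)
  og_id <- sprintf("og%05d", as.integer(part))
  members <- data.frame(og_id = og_id, gene_id = names(part),
                        genome_id = unname(g_of[names(part)]),
                        stringsAsFactors = FALSE)
  members <- members[order(members$og_id, members$gene_id), ]
  rownames(members) <- NULL
  genome_ids <- sort(vapply(genomes, function(g) g$genome_id, character(1)))
  presence <- table(factor(members$og_id),
                    factor(members$genome_id, levels = genome_ids))
  presence <- matrix(as.integer(presence), nrow = nrow(presence),
                     dimnames = dimnames(presence))
  structure(list(members = members, presence = presence, edges = pairs),
            class = "orthogroups")
}

#' @export
print.orthogroups <- function(x, ...) {
  cat(sprintf("<orthogroups> %d orthogroups over %d genes in %d genomes\n",
              nrow(x$presence), nrow(x$members), ncol(x$presence)))
  invisible(x)
}

# Logical presence (>= 1 member) matrix.
presence_logical <- function(orthogroups) {
  orthogroups$presence > 0
}
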