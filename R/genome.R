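#' Construct a genome object
#'
#' The central container for one annotated assembly: replicon sequences plus
#' a gene table. Internal gene coordinates are 0-based half-open on the
#' replicon; `cds` is always stored coding-strand oriented, so downstream
#' codon analyses never consult `strand`. The chromosome of a genome is
#' defined as its longest replicon.
#'
#' @param genome_id unique identifier.
#' @param species_label species name as annotated (may be wrong).
#' @param assembly_level `"complete"` or `"draft"`.
#' @param replicons data.frame with columns `replicon_id`, `topology`
#'   (`"linear"`/`"circular"`).
#' @param seqs named character vector of replicon sequences
#'   (names = `replicon_id`).
#' @param genes data.frame with columns `gene_id`, `replicon_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `cds`, `protein`,
#'   and optionally `category` (COG letter or `NA`) and `translatable`.
#' @param labels optional data.frame of feature labels with columns
#'   `gene_id`, `label` (e.g. smBGC type or CAZyme family).
#' @param isolation_source optional string.
#' @return an object of class `"genome"`.
#' @export
genome <- function(genome_id, species_label, assembly_level, replicons, seqs,
                   genes, labels = NULL, isolation_source = NA_character_) {
  assembly_level <- match.arg(assembly_level, c("complete", "draft"))
  stopifnot(is.data.frame(replicons),
            all(c("replicon_id", "topology") %in% names(replicons)),
            is.character(seqs), !is.null(names(seqs)),
            setequal(names(seqs), replicons$replicon_id))
  need <- c("gene_id", "replicon_id", "start", "end", "strand", "cds",
            "protein")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in genome ", genome_id)
  bad_rep <- setdiff(unique(genes$replicon_id), replicons$replicon_id)
  if (length(bad_rep))
    stop("genes reference unknown replicons: ", paste(bad_rep, collapse = ", "))
  rl <- nchar(seqs)[genes$replicon_id]
  if (any(genes$start < 0 | genes$start >= genes$end | genes$end > rl))
    stop("gene coordinates out of replicon bounds in genome ", genome_id)
  if (is.null(genes$category)) genes$category <- NA_character_
  if (is.null(genes$translatable))
    genes$translatable <- nchar(genes$cds) %% 3 == 0
  if (is.null(labels))
    labels <- data.frame(gene_id = character(), label = character(),
                         stringsAsFactors = FALSE)
  structure(list(genome_id = genome_id,
                 species_label = species_label,
                 assembly_level = assembly_level,
                 isolation_source = isolation_source,
                 replicons = replicons,
                 seqs = seqs,
                 genes = genes,
                 labels = labels),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s (%s, %s)\n", x$genome_id, x$species_label,
              x$assembly_level))
  cat(sprintf("  %d replicon(s), %d genes, chromosome %s (%d bp)\n",
              nrow(x$replicons), nrow(x$genes), chromosome_id(x),
              nchar(x$seqs[[chromosome_id(x)]])))
  invisible(x)
}

#' Identify the chromosome of a genome
#'
#' The chromosome is the longest replicon; plasmids and other replicons are
#' excluded from per-chromosome statistics.
#'
#' @param genome a [genome()] object.
#' @return replicon_id of the chromosome.
#' @export
chromosome_id <- function(genome) {
  lens <- nchar(genome$seqs)
  names(lens)[which.max(lens)]
}

# Genes located on the chromosome, in coordinate order.
chromosome_genes <- function(genome) {
  g <- genome$genes[genome$genes$replicon_id == chromosome_id(genome), ,
                    drop = FALSE]
  g[order(g$start), , drop = FALSE]
}

# Named character vector of proteins for a set of genomes.
all_proteins <- function(genomes) {
  do.call(c, unname(lapply(genomes, function(g)
    setNames(g$genes$protein, g$genes$gene_id))))
}

# gene_id -> genome_id map for a list of genomes.
gene_genome_map <- function(genomes) {
  do.call(c, unname(lapply(genomes, function(g)
    setNames(rep(g$genome_id, nrow(g$genes)), g$genes$gene_id))))
}
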