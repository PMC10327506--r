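# Rare TTA leucine codon analysis: scanning, per-genome summaries,
# orthogroup conservation and functional-category enrichment.

#' Scan a coding sequence for in-frame TTA codons
#'
#' The reading frame is fixed at position 0 of the coding-strand `cds`;
#' only whole-codon TTA matches count (a TTA substring spanning a codon
#' boundary does not). Codon 1 is the initiator; the terminal stop codon
#' can never match. Returns `NULL` when the gene carries no TTA or is
#' flagged non-translatable.
#'
#' @param gene one row of a genome's gene table (or a list with `gene_id`,
#'   `cds`, and optionally `translatable`).
#' @return `NULL`, or a list with `gene_id`, `codon_indices` (1-based) and
#'   `count`.
#' @export
scan_tta <- function(gene) {
  if (!is.null(gene$translatable) && !isTRUE(gene$translatable))
    return(NULL)
  cds <- gene$cds
  if (nchar(cds) %% 3 != 0) return(NULL)
  hits <- gregexpr("TTA", cds, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NULL)
  in_frame <- hits[(hits - 1L) %% 3L == 0L]
  if (!length(in_frame)) return(NULL)
  idx <- (in_frame - 1L) %/% 3L + 1L
  list(gene_id = gene$gene_id, codon_indices = idx, count = length(idx))
}

#' Per-genome TTA summary
#'
#' Counts TTA-bearing ORFs on translatable genes and the fraction of them
#' carrying exactly one TTA codon.
#'
#' @param genome a [genome()] object.
#' @return list with `records` (data.frame `gene_id`, `codon_index` with
#'   one row per TTA site), `n_tta_genes`, `single_tta_fraction`,
#'   `skipped` (gene ids skipped as non-translatable).
#' @export
genome_tta_summary <- function(genome) {
  recs <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    if (!isTRUE(g$translatable)) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    r <- scan_tta(g)
    if (!is.null(r))
      recs[[length(recs) + 1L]] <-
        data.frame(gene_id = r$gene_id, codon_index = r$codon_indices)
  }
  records <- if (length(recs)) do.call(rbind, c(recs,
                                                make.row.names = FALSE))
             else data.frame(gene_id = character(), codon_index = integer())
  counts <- table(records$gene_id)
  list(records = records,
       n_tta_genes = length(counts),
       single_tta_fraction = if (length(counts)) mean(counts == 1)
                             else NA_real_,
       skipped = skipped)
}

#' Orthogroup-level TTA conservation
#'
#' Measures, over one representative member per species, (i) the
#' any-position fraction: species whose member carries at least one TTA
#' over species carrying the orthogroup, and (ii) position-specific
#' conservation: each member is aligned pairwise to the orthogroup
#' reference (the member from the lexicographically smallest species
#' cluster) and its TTA codons are mapped to reference codon positions;
#' a reference site is conserved when at least `conserved_min` of the
#' species with the orthogroup have a TTA mapped there.
#'
#' @param og_id orthogroup id.
#' @param orthogroups a [build_orthogroups()] result.
#' @param clusters a [demarcate_species()] result.
#' @param genomes named list of [genome()] objects.
#' @param conserved_min site conservation threshold (default 0.5).
#' @param min_map_coverage members aligning to the reference below this
#'   coverage are excluded from position mapping (kept in the any-position
#'   fraction) and logged.
#' @return list with `og_id`, `species_with_og`, `species_with_tta_any`,
#'   `any_fraction`, `site_fractions` (named numeric, reference codon ->
#'   conserved fraction), `conserved_sites`, `log`.
#' @export
tta_conservation <- function(og_id, orthogroups, clusters, genomes,
                             conserved_min = 0.5, min_map_coverage = 0.3) {
  by_id <- setNames(genomes, vapply(genomes, function(g) g$genome_id,
                                    character(1)))
  mem <- orthogroups$members[orthogroups$members$og_id == og_id, ,
                             drop = FALSE]
  if (!nrow(mem)) stop("unknown orthogroup: ", og_id)
  cl <- clusters$clusters
  cluster_of <- setNames(cl$cluster_id, cl$genome_id)
  # One representative member per species: the member gene from the
  # species' representative genome (smallest gene id); species without a
  # member in its representative genome fall back to the smallest member.
  mem$cluster <- unname(cluster_of[mem$genome_id])
  species <- sort(unique(mem$cluster))
  if (length(species) < 2)
    stop("orthogroup ", og_id, " present in fewer than 2 species")
  rep_members <- vapply(species, function(cid) {
    m <- mem[mem$cluster == cid, ]
    in_rep <- m$gene_id[m$genome_id == clusters$representatives[[cid]]]
    if (length(in_rep)) min(in_rep) else min(m$gene_id)
  }, character(1))

  gene_row <- function(gid) {
    gm <- by_id[[gene_genome_map(genomes)[[gid]]]]
    gm$genes[gm$genes$gene_id == gid, ]
  }
  rows <- lapply(rep_members, gene_row)
  names(rows) <- species
  tta <- lapply(rows, scan_tta)
  has_tta <- vapply(tta, Negate(is.null), logical(1))
  any_fraction <- mean(has_tta)

  # Position mapping through pairwise alignment to the reference member.
  ref_species <- species[1]
  ref <- rows[[ref_species]]
  logs <- character(0)
  site_votes <- integer(0)
  for (sp in species) {
    rec <- tta[[sp]]
    if (is.null(rec)) next
    if (sp == ref_species) {
      mapped <- rec$codon_indices
    } else {
      mapped <- map_codons_to_reference(rows[[sp]]$protein, ref$protein,
                                        rec$codon_indices)
      if (is.null(mapped)) {
        logs <- c(logs, sprintf(
          "%s: member unalignable to reference (coverage < %.2f), excluded from position mapping",
          sp, min_map_coverage))
        next
      }
      mapped <- mapped[!is.na(mapped)]
    }
    for (m in unique(mapped)) {
      key <- as.character(m)
      site_votes[key] <- (if (key %in% names(site_votes))
                            site_votes[[key]] else 0L) + 1L
    }
  }
  site_fractions <- if (length(site_votes))
    sort(setNames(as.numeric(site_votes) / length(species),
                  names(site_votes))) else numeric(0)
  list(og_id = og_id,
       species_with_og = length(species),
       species_with_tta_any = sum(has_tta),
       any_fraction = any_fraction,
       site_fractions = site_fractions,
       conserved_sites = as.integer(
         names(site_fractions)[site_fractions >= conserved_min]),
       log = logs)
}

# Map codon indices of a member protein to reference codon indices through
# the semi-global alignment of the two proteins. Returns NULL when the
# member aligns at < 0.3 coverage; unmapped positions are NA.
map_codons_to_reference <- function(member_protein, ref_protein,
                                    codon_indices, min_coverage = 0.3) {
  aln <- align_with_path(member_protein, ref_protein)
  if (aln$coverage_a < min_coverage) return(NULL)
  # aln$path: two integer vectors of aligned positions (NA for gaps).
  map <- rep(NA_integer_, nchar(member_protein))
  ok <- !is.na(aln$path$a) & !is.na(aln$path$b)
  map[aln$path$a[ok]] <- aln$path$b[ok]
  map[codon_indices[codon_indices <= length(map)]]
}

# Alignment with explicit column path (1-based aligned positions, 0 = gap).
align_with_path <- function(a, b, gap_open = 11, gap_ext = 1) {
  smat <- get_blosum62()
  alphabet <- paste(rownames(smat), collapse = "")
  xsym <- which(rownames(smat) == "X") - 1L
  r <- cpp_align_path(a, b, smat, alphabet, gap_open, gap_ext, xsym)
  list(coverage_a = r$coverage_a,
       path = list(a = ifelse(r$a_pos == 0, NA_integer_, r$a_pos),
                   b = ifelse(r$b_pos == 0, NA_integer_, r$b_pos)))
}

#' COG-category enrichment of TTA-bearing genes
#'
#' Per functional category, exact hypergeometric over/under tails with the
#' universe being the categorized chromosome genes of the genome, successes
#' the category members, and draws the TTA-bearing categorized genes;
#' uncategorized genes are excluded. The log2 fold-change of observed vs
#' background frequency is reported.
#'
#' @param genome a [genome()] object whose genes carry `category`.
#' @param alpha significance cutoff on either tail (default 0.05).
#' @return data.frame with one row per category present in the genome:
#'   `category`, `k`, `n`, `K`, `N`, `log2_fc`, `p_over`, `p_under`,
#'   `verdict`.
#' @export
tta_category_enrichment <- function(genome, alpha = 0.05) {
  g <- chromosome_genes(genome)
  g <- g[!is.na(g$category) & g$category != "", , drop = FALSE]
  if (!nrow(g)) stop("no categorized chromosome genes")
  tta_gene <- vapply(seq_len(nrow(g)), function(i)
    !is.null(scan_tta(g[i, ])), logical(1))
  N <- nrow(g)
  n <- sum(tta_gene)
  rows <- lapply(sort(unique(g$category)), function(cat) {
    in_cat <- g$category == cat
    K <- sum(in_cat)
    k <- sum(in_cat & tta_gene)
    tails <- hypergeom_tails(N, K, n, k)
    bg <- K / N
    obs <- if (n > 0) k / n else NA_real_
    verdict <- "none"
    if (!is.na(obs)) {
      if (tails["p_over"] < alpha && obs > bg) verdict <- "over"
      if (tails["p_under"] < alpha && obs < bg) verdict <- "under"
    }
    data.frame(category = cat, k = k, n = n, K = K, N = N,
               log2_fc = if (!is.na(obs) && obs > 0 && bg > 0)
                 log2(obs / bg) else NA_real_,
               p_over = unname(tails["p_over"]),
               p_under = unname(tails["p_under"]),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
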