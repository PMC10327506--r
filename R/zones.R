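#' Arm/centre zones of a linear chromosome
#'
#' Splits the chromosome into the two arms (25 % of total length each) and
#' the centre in-between (50 %): left arm `[0, 0.25L)`, centre
#' `[0.25L, 0.75L)`, right arm `[0.75L, L)`. Circular chromosomes are
#' rejected: the arm/centre geometry only makes sense on linear replicons.
#'
#' @param genome a [genome()] object.
#' @return list with `chromosome`, `length`, and the three half-open
#'   interval bounds.
#' @export
chromosome_zones <- function(genome) {
  chrom <- chromosome_id(genome)
  topo <- genome$replicons$topology[genome$replicons$replicon_id == chrom]
  if (identical(topo, "circular"))
    stop("chromosome ", chrom, " is circular; arm/centre zones are only ",
         "defined for linear chromosomes")
  L <- nchar(genome$seqs[[chrom]])
  stopifnot(L > 0)
  b1 <- L %/% 4
  b2 <- L - L %/% 4
  list(chromosome = chrom, length = L,
       left_arm = c(0, b1), centre = c(b1, b2), right_arm = c(b2, L))
}

#' Assign chromosome genes to zones
#'
#' A gene's zone is decided by its midpoint `(start + end) %/% 2`; a
#' midpoint exactly on the 25 % boundary belongs to the centre, and exactly
#' on the 75 % boundary to the right arm (half-open intervals). Every
#' chromosome gene gets exactly one zone.
#'
#' @param genome a [genome()] object.
#' @param zones optional precomputed [chromosome_zones()].
#' @return named character vector gene_id -> `"left_arm"`, `"centre"` or
#'   `"right_arm"` (chromosome genes only; genes on other replicons are an
#'   error if passed explicitly via `gene_ids`).
#' @param gene_ids optional subset of gene ids to assign.
#' @export
assign_zone <- function(genome, gene_ids = NULL, zones = NULL) {
  zones <- zones %||% chromosome_zones(genome)
  g <- genome$genes[genome$genes$replicon_id == zones$chromosome, ,
                    drop = FALSE]
  if (!is.null(gene_ids)) {
    off <- setdiff(gene_ids, g$gene_id)
    if (length(off))
      stop("gene(s) not on the chromosome: ", paste(off, collapse = ", "))
    g <- g[g$gene_id %in% gene_ids, , drop = FALSE]
  }
  mid <- (g$start + g$end) %/% 2L
  zone <- ifelse(mid < zones$left_arm[2], "left_arm",
                 ifelse(mid < zones$centre[2], "centre", "right_arm"))
  setNames(zone, g$gene_id)
}

#' Hypergeometric arm/centre enrichment of a gene set
#'
#' Tests whether a gene set is over/under-represented in a chromosomal zone
#' (`"arms"` = both arms jointly, or `"centre"`), with the universe being
#' all chromosome protein-coding genes of that genome. Both exact
#' hypergeometric tails are always reported; the verdict applies the dual
#' rule: `over` iff `p_over < alpha` and the observed frequency exceeds the
#' background by at least `min_delta` (absolute percentage points by
#' default), `under` symmetrically, else `none`.
#'
#' @param genome a [genome()] object.
#' @param gene_ids the gene set (must be chromosome genes, n >= 1).
#' @param zone `"arms"` or `"centre"`.
#' @param alpha p-value cutoff (default 0.05).
#' @param min_delta minimum frequency change (default 0.05).
#' @param relative if TRUE, `min_delta` is interpreted as a relative change
#'   `|obs - bg| / bg` instead of an absolute difference.
#' @param set_name label carried into the output.
#' @return one-row data.frame with `genome_id`, `set_name`, `zone`, `k`,
#'   `n`, `K`, `N`, `background_freq`, `observed_freq`, `delta`, `p_over`,
#'   `p_under`, `verdict`.
#' @export
zone_enrichment <- function(genome, gene_ids, zone = c("arms", "centre"),
                            alpha = 0.05, min_delta = 0.05,
                            relative = FALSE, set_name = "set") {
  zone <- match.arg(zone)
  if (!length(gene_ids)) stop("empty gene set")
  zl <- assign_zone(genome)
  miss <- setdiff(gene_ids, names(zl))
  if (length(miss))
    stop("gene set contains non-chromosome gene(s): ",
         paste(miss, collapse = ", "))
  in_zone <- if (zone == "arms") zl %in% c("left_arm", "right_arm")
             else zl == "centre"
  N <- length(zl)
  K <- sum(in_zone)
  n <- length(gene_ids)
  k <- sum(in_zone[match(gene_ids, names(zl))])
  tails <- hypergeom_tails(N, K, n, k)
  bg <- K / N
  obs <- k / n
  delta <- obs - bg
  crit <- if (relative && bg > 0) abs(delta) / bg else abs(delta)
  verdict <- "none"
  if (tails["p_over"] < alpha && delta > 0 && crit >= min_delta)
    verdict <- "over"
  if (tails["p_under"] < alpha && delta < 0 && crit >= min_delta)
    verdict <- "under"
  data.frame(genome_id = genome$genome_id, set_name = set_name,
             zone = zone, k = k, n = n, K = K, N = N,
             background_freq = bg, observed_freq = obs, delta = delta,
             p_over = unname(tails["p_over"]),
             p_under = unname(tails["p_under"]),
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Zone localization report over genomes and named gene sets
#'
#' One [zone_enrichment()] row per genome x gene set x zone (arms and
#' centre), plus a genus-level summary counting genomes with each verdict
#' per set and zone.
#'
#' @param genomes named list of [genome()] objects.
#' @param gene_sets function(genome) -> named list of gene-id vectors, or a
#'   static named list of per-genome named lists.
#' @param ... passed to [zone_enrichment()].
#' @return list with `table` (all rows) and `summary` (verdict counts).
#' @export
localization_report <- function(genomes, gene_sets, ...) {
  rows <- list()
  for (g in genomes) {
    sets <- if (is.function(gene_sets)) gene_sets(g)
            else gene_sets[[g$genome_id]]
    for (nm in names(sets)) {
      ids <- sets[[nm]]
      if (!length(ids)) next
      for (z in c("arms", "centre"))
        rows[[length(rows) + 1L]] <-
          zone_enrichment(g, ids, zone = z, set_name = nm, ...)
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  summary <- NULL
  if (!is.null(tab)) {
    agg <- aggregate(genome_id ~ set_name + zone + verdict, data = tab,
                     FUN = length)
    names(agg)[names(agg) == "genome_id"] <- "n_genomes"
    summary <- agg[order(agg$set_name, agg$zone, agg$verdict), ]
    rownames(summary) <- NULL
  }
  list(table = tab, summary = summary)
}
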