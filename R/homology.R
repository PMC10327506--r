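# Protein homology: semi-global alignment, identity, within-genome paralog
# profiling and cross-species close-homolog search.

.pkg_cache <- new.env(parent = emptyenv())

get_blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .pkg_cache$BLOSUM62 <- env$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# Batch semi-global alignment of sequence pairs (indices into `seqs`).
align_pairs <- function(seqs, ia, ib, gap_open = 11, gap_ext = 1) {
  if (length(ia) == 0)
    return(data.frame(score = numeric(), identity = numeric(),
                      coverage_a = numeric(), coverage_b = numeric(),
                      ncols = numeric(), matches = numeric()))
  smat <- get_blosum62()
  alphabet <- paste(rownames(smat), collapse = "")
  xsym <- which(rownames(smat) == "X") - 1L
  as.data.frame(cpp_align_batch(as.character(seqs), as.integer(ia),
                                as.integer(ib), smat, alphabet,
                                gap_open, gap_ext, xsym, -1L, 0L))
}

#' Align two proteins semi-globally and report identity
#'
#' Global alignment with free terminal gaps (semi-global/overlap mode),
#' BLOSUM62 scoring with affine gaps (defaults: open 11, extend 1).
#' Identity is matches over aligned columns excluding terminal-gap columns;
#' `X` is tolerated but never counted as a match. Tie-breaking is
#' deterministic (diagonal over gap-in-a over gap-in-b on equal score).
#'
#' @param a,b protein sequences (non-empty, 20-letter alphabet plus X).
#' @param gap_open,gap_ext affine gap parameters.
#' @return one-row data.frame with `identity`, `coverage_a`, `coverage_b`
#'   (aligned-span fraction of each protein), `score`, `ncols`, `matches`.
#' @examples
#' align_proteins("MKVL", "MKIL")$identity  # 0.75
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_ext = 1) {
  stopifnot(is.character(a), is.character(b), length(a) == 1,
            length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  align_pairs(c(a, b), 1L, 2L, gap_open, gap_ext)
}

# Candidate homolog pairs over a set of proteins. With exhaustive = TRUE all
# pairs are returned; otherwise a shared-k-mer prefilter proposes pairs.
candidate_pairs <- function(proteins, exhaustive = FALSE, k = 5,
                            min_shared = 4, max_bucket = 2000) {
  n <- length(proteins)
  if (n < 2) return(matrix(integer(), ncol = 2))
  if (exhaustive) {
    cmb <- utils::combn(n, 2)
    return(t(cmb))
  }
  cpp_kmer_candidates(as.character(proteins), as.integer(k),
                      as.integer(min_shared), as.integer(max_bucket))
}

# All-vs-all homolog pairs over named proteins, thresholded.
homolog_pairs <- function(proteins, min_identity, min_coverage,
                          exhaustive = FALSE, k = 5, min_shared = 4) {
  stopifnot(!is.null(names(proteins)))
  cand <- candidate_pairs(proteins, exhaustive = exhaustive, k = k,
                          min_shared = min_shared)
  if (nrow(cand) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric(), coverage_a = numeric(),
                      coverage_b = numeric(), coverage_short = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  aln <- align_pairs(proteins, cand[, 1], cand[, 2])
  len_a <- nchar(proteins[cand[, 1]])
  len_b <- nchar(proteins[cand[, 2]])
  cov_short <- ifelse(len_a <= len_b, aln$coverage_a, aln$coverage_b)
  out <- data.frame(gene_a = names(proteins)[cand[, 1]],
                    gene_b = names(proteins)[cand[, 2]],
                    identity = aln$identity,
                    coverage_a = aln$coverage_a,
                    coverage_b = aln$coverage_b,
                    coverage_short = cov_short,
                    score = aln$score, stringsAsFactors = FALSE)
  out[out$identity >= min_identity & out$coverage_short >= min_coverage, ,
      drop = FALSE]
}

#' Within-genome homolog pairs
#'
#' All unordered protein pairs of one genome meeting the identity and
#' coverage thresholds (coverage evaluated on the shorter protein), plus
#' each protein's best within-genome hit identity (among pairs meeting the
#' coverage threshold at any identity). The search is exhaustive.
#'
#' @param genome a [genome()] object with at least one protein.
#' @param min_identity minimum identity for a reported pair (default 0.5,
#'   the close-homolog criterion).
#' @param min_coverage minimum aligned coverage of the shorter protein.
#' @return list with `pairs` (thresholded data.frame) and `best_hit`
#'   (named numeric, best identity per protein; `NA` when no pair meets the
#'   coverage rule).
#' @export
within_genome_homologs <- function(genome, min_identity = 0.5,
                                   min_coverage = 0.5) {
  prot <- setNames(genome$genes$protein, genome$genes$gene_id)
  stopifnot(length(prot) >= 1)
  best <- setNames(rep(NA_real_, length(prot)), names(prot))
  if (length(prot) < 2)
    return(list(pairs = homolog_pairs(prot, min_identity, min_coverage,
                                      exhaustive = TRUE),
                best_hit = best))
  all_pairs <- homolog_pairs(prot, min_identity = 0, min_coverage = 0,
                             exhaustive = TRUE)
  covered <- all_pairs[all_pairs$coverage_short >= min_coverage, ,
                       drop = FALSE]
  if (nrow(covered)) {
    for (side in c("gene_a", "gene_b")) {
      agg <- tapply(covered$identity, covered[[side]], max)
      idx <- match(names(agg), names(best))
      best[idx] <- pmax(best[idx], as.numeric(agg), na.rm = TRUE)
    }
  }
  pairs <- covered[covered$identity >= min_identity, , drop = FALSE]
  list(pairs = pairs, best_hit = best)
}

#' Per-genome identity-bin paralog profile
#'
#' Assigns every protein to the identity bin of its best within-genome
#' homolog, using the five bins 51-60, 61-70, 71-80, 81-90 and 91-100 %
#' (half-open: lower-exclusive, upper-inclusive, so a best hit of exactly
#' 0.60 falls in 51-60). Proteins with no hit at or above the singleton
#' cutoff are singletons; hits between the cutoff and 50 % form the
#' "below-51" class. Fractions over all proteins sum to 1.
#'
#' @param genome a [genome()] object.
#' @param singleton_identity identity floor below which a protein is a
#'   singleton (default 0.30; a deterministic stand-in for an e-value
#'   cutoff, see the methods vignette).
#' @param singleton_coverage coverage (of the shorter protein) required for
#'   a hit to count.
#' @return data.frame with one row per class (`bin`, `count`, `fraction`).
#' @export
identity_bin_profile <- function(genome, singleton_identity = 0.3,
                                 singleton_coverage = 0.5) {
  hits <- within_genome_homologs(genome, min_identity = 0,
                                 min_coverage = singleton_coverage)$best_hit
  n <- length(hits)
  bins <- c("singleton", "below-51", "51-60", "61-70", "71-80", "81-90",
            "91-100")
  cls <- character(n)
  for (i in seq_len(n)) {
    h <- hits[i]
    cls[i] <- if (is.na(h) || h < singleton_identity) "singleton"
      else if (h <= 0.5) "below-51"
      else if (h <= 0.6) "51-60"
      else if (h <= 0.7) "61-70"
      else if (h <= 0.8) "71-80"
      else if (h <= 0.9) "81-90"
      else "91-100"
  }
  counts <- table(factor(cls, levels = bins))
  data.frame(bin = bins, count = as.integer(counts),
             fraction = as.numeric(counts) / n, stringsAsFactors = FALSE)
}

#' Does a protein have a close homolog in another species?
#'
#' TRUE iff any protein of any other species aligns to the query at
#' `>= min_identity` identity over `>= min_length_frac` of the query's
#' length (both conditions required; the strict-fingerprint homology rule).
#'
#' @param protein query protein sequence (length-1 character).
#' @param other_proteomes character vector of proteins from other species.
#' @param min_identity identity threshold (default 0.5).
#' @param min_length_frac minimum aligned fraction of the query length.
#' @param exhaustive if FALSE (default), a shared-k-mer prefilter skips
#'   hopeless pairs.
#' @return logical scalar.
#' @export
cross_species_close_homolog_exists <- function(protein, other_proteomes,
                                               min_identity = 0.5,
                                               min_length_frac = 0.5,
                                               exhaustive = FALSE) {
  stopifnot(length(protein) == 1)
  hits <- cross_homolog_hits(setNames(protein, "query"), other_proteomes,
                             min_identity, min_length_frac, exhaustive)
  length(hits$query) > 0 && hits$query
}

# Vectorized cross-homolog existence check: returns named logical over
# queries. Prefilter mode proposes query-target candidates via shared
# 5-mers (>= 2 shared); at the 50 % identity / 50 % length rule a true hit
# shares several 5-mers in expectation, and the exhaustive mode verifies
# the heuristic in tests.
cross_homolog_hits <- function(queries, targets, min_identity = 0.5,
                               min_length_frac = 0.5, exhaustive = FALSE) {
  stopifnot(!is.null(names(queries)))
  res <- setNames(rep(FALSE, length(queries)), names(queries))
  if (length(targets) == 0 || length(queries) == 0) return(as.list(res))
  nq <- length(queries)
  seqs <- c(unname(queries), unname(targets))
  if (exhaustive) {
    cand <- cbind(rep(seq_len(nq), each = length(targets)),
                  rep(nq + seq_along(targets), times = nq))
  } else {
    cand <- cpp_kmer_query_candidates(unname(queries), unname(targets),
                                      5L, 2L, 100000L)
    if (nrow(cand)) cand[, 2] <- cand[, 2] + nq
  }
  if (nrow(cand) == 0) return(as.list(res))
  aln <- align_pairs(seqs, cand[, 1], cand[, 2])
  ok <- aln$identity >= min_identity & aln$coverage_a >= min_length_frac
  hit_q <- unique(cand[ok, 1])
  res[hit_q] <- TRUE
  as.list(res)
}
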