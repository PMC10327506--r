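#' Average nucleotide identity between two genomes
#'
#' Seeded-fragment ANI approximation: the chromosome of each genome is
#' chopped into non-overlapping fragments; each fragment's best window in
#' the partner chromosome is located by exact 15-mer diagonal voting
#' (strand-aware) and its contiguous seeded span aligned with a banded
#' semi-global nucleotide alignment. ANI is the mean identity over
#' qualifying fragments (identity >= 0.7 over >= 0.5 fragment coverage),
#' symmetrized as the mean of both directions. When either direction has
#' fewer than `min_fragments` qualifying fragments the ANI is undefined and
#' reported as `NA` (never 0).
#'
#' @param genome_a,genome_b [genome()] objects; both chromosomes must be at
#'   least `2 * fragment_length` long.
#' @param fragment_length fragment size in nt (default 1000).
#' @param min_identity,min_coverage per-fragment qualification thresholds.
#' @param min_fragments minimum qualifying fragments per direction
#'   (default 5).
#' @param band alignment band half-width in nt.
#' @param stride seed sampling stride in nt (seeds every `stride`
#'   positions; smaller is more sensitive near the identity floor).
#' @return numeric ANI in \[0, 1\], or `NA` when undefined; the number of
#'   qualifying fragments is attached as attribute `fragments_used`.
#' @export
ani <- function(genome_a, genome_b, fragment_length = 1000,
                min_identity = 0.7, min_coverage = 0.5, min_fragments = 5,
                band = 12, stride = 3) {
  ca <- genome_a$seqs[[chromosome_id(genome_a)]]
  cb <- genome_b$seqs[[chromosome_id(genome_b)]]
  if (nchar(ca) < 2 * fragment_length || nchar(cb) < 2 * fragment_length)
    stop("both chromosomes must be >= 2 * fragment_length")
  d1 <- cpp_ani_rows(ca, cb, as.integer(fragment_length), 15L,
                     as.integer(band), 3L, as.integer(stride), 1, -1, 3, 1,
                     50L, min_identity, min_coverage)
  d2 <- cpp_ani_rows(cb, ca, as.integer(fragment_length), 15L,
                     as.integer(band), 3L, as.integer(stride), 1, -1, 3, 1,
                     50L, min_identity, min_coverage)
  ok <- d1[1, "n_qualified"] >= min_fragments &&
    d2[1, "n_qualified"] >= min_fragments
  out <- if (ok) (d1[1, "mean_identity"] + d2[1, "mean_identity"]) / 2
         else NA_real_
  attr(out, "fragments_used") <- as.integer(d1[1, "n_qualified"] +
                                              d2[1, "n_qualified"])
  out
}

#' All-pairs ANI table for a genome collection
#'
#' Computes [ani()] for every unordered genome pair, building each
#' chromosome's k-mer index once.
#'
#' @param genomes named list of [genome()] objects.
#' @param fragment_length,min_identity,min_coverage,min_fragments,band,stride
#'   see [ani()].
#' @return data.frame with `genome_a`, `genome_b`, `ani`, `fragments_used`
#'   (one row per unordered pair; `ani` is `NA` when undefined).
#' @export
ani_matrix <- function(genomes, fragment_length = 1000, min_identity = 0.7,
                       min_coverage = 0.5, min_fragments = 5, band = 12,
                       stride = 3) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  n <- length(genomes)
  stopifnot(n >= 2)
  chroms <- vapply(genomes, function(g) g$seqs[[chromosome_id(g)]],
                   character(1))
  if (any(nchar(chroms) < 2 * fragment_length))
    stop("all chromosomes must be >= 2 * fragment_length")
  # direction means: dir[i, j] = mean identity of fragments of i vs j
  mean_id <- matrix(NA_real_, n, n)
  n_qual <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    qi <- setdiff(seq_len(n), j)
    rows <- cpp_ani_rows(unname(chroms[qi]), chroms[[j]],
                         as.integer(fragment_length), 15L,
                         as.integer(band), 3L, as.integer(stride),
                         1, -1, 3, 1, 50L, min_identity, min_coverage)
    mean_id[qi, j] <- rows[, "mean_identity"]
    n_qual[qi, j] <- as.integer(rows[, "n_qualified"])
  }
  cmb <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(cmb)), function(p) {
    a <- cmb[1, p]; b <- cmb[2, p]
    ok <- n_qual[a, b] >= min_fragments && n_qual[b, a] >= min_fragments
    data.frame(genome_a = ids[a], genome_b = ids[b],
               ani = if (ok) (mean_id[a, b] + mean_id[b, a]) / 2
                     else NA_real_,
               fragments_used = n_qual[a, b] + n_qual[b, a],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
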