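`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("CAT")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Run code with a locally-seeded RNG, restoring global RNG state on exit.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (both together or
#' both apart). 1 means identical partitions.
#'
#' @param a,b cluster labels, equal length, aligned element-wise.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2), c("x", "x", "y"))
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1)) {
    sa <- a[i] == a[(i + 1):n]
    sb <- b[i] == b[(i + 1):n]
    agree <- agree + sum(sa == sb)
  }
  agree / choose(n, 2)
}

# Translate a coding-strand CDS (with or without trailing stop) to protein.
translate_cds <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    n <- nchar(s)
    stopifnot(n %% 3 == 0)
    codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

gc_content <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}
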