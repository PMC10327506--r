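#' Read one genome from its FASTA/GFF3/protein bundle
#'
#' Assembles the internal genome representation from a nucleotide FASTA (one
#' record per replicon), a GFF3 file of CDS features (the `ID` attribute is
#' the gene id), and a protein FASTA whose record ids match the GFF gene ids.
#' GFF3 coordinates (1-based inclusive) are converted to internal 0-based
#' half-open coordinates; minus-strand CDS are reverse-complemented so that
#' `cds` is coding-strand oriented.
#'
#' Genes whose CDS length is not divisible by 3 are retained for pan-genome
#' analysis but flagged `translatable = FALSE` (with a warning) and excluded
#' from TTA scanning.
#'
#' @param fasta_path nucleotide FASTA path.
#' @param gff_path GFF3 path (CDS features are used).
#' @param protein_fasta_path protein FASTA path.
#' @param metadata_row one-row data.frame (or named list) with `genome_id`,
#'   `species_label`, `assembly_level`, and optionally `isolation_source`.
#' @param labels_path optional TSV with columns `gene_id`, `category`,
#'   `feature_label` (repeated `gene_id` rows allowed for multiple labels).
#' @return a [genome()] object.
#' @export
read_genome_bundle <- function(fasta_path, gff_path, protein_fasta_path,
                               metadata_row, labels_path = NULL) {
  for (p in c(fasta_path, gff_path, protein_fasta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  seqs_x <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs_x))
  topo <- ifelse(grepl("topology=circular", names(seqs_x)), "circular",
                 "linear")
  seqs <- setNames(as.character(seqs_x), ids)
  replicons <- data.frame(replicon_id = ids, topology = topo,
                          stringsAsFactors = FALSE)

  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[gff$type == "CDS"]
  if (!length(gff)) stop("no CDS features in ", gff_path)
  gene_id <- as.character(gff$ID)
  if (anyNA(gene_id) || any(gene_id == ""))
    stop("CDS features without ID attribute in ", gff_path)
  if (anyDuplicated(gene_id))
    stop("duplicate CDS IDs in ", gff_path)
  repl <- as.character(GenomicRanges::seqnames(gff))
  start1 <- GenomicRanges::start(gff)      # 1-based inclusive
  end1 <- GenomicRanges::end(gff)
  strand <- as.character(GenomicRanges::strand(gff))
  strand[strand == "*"] <- "+"

  prot_x <- Biostrings::readAAStringSet(protein_fasta_path)
  prot <- setNames(as.character(prot_x), sub("\\s.*$", "", names(prot_x)))
  missing_prot <- setdiff(gene_id, names(prot))
  if (length(missing_prot))
    stop("protein FASTA is missing GFF gene(s): ",
         paste(missing_prot, collapse = ", "))
  orphans <- setdiff(names(prot), gene_id)
  if (length(orphans))
    stop("protein FASTA has records absent from the GFF: ",
         paste(orphans, collapse = ", "))

  # 1-based inclusive -> 0-based half-open.
  start0 <- start1 - 1L
  end0 <- end1
  cds <- substring(seqs[repl], start1, end1)
  minus <- strand == "-"
  cds[minus] <- revcomp(cds[minus])
  translatable <- nchar(cds) %% 3 == 0
  if (any(!translatable))
    warning(sum(!translatable), " gene(s) with CDS length not divisible by",
            " 3 retained but flagged non-translatable")

  genes <- data.frame(gene_id = gene_id, replicon_id = repl,
                      start = start0, end = end0, strand = strand,
                      cds = unname(cds), protein = unname(prot[gene_id]),
                      category = NA_character_, translatable = translatable,
                      stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.null(labels_path) && file.exists(labels_path)) {
    lt <- read.delim(labels_path, stringsAsFactors = FALSE)
    if ("category" %in% names(lt)) {
      cat_map <- lt[!is.na(lt$category) & lt$category != "", ]
      idx <- match(genes$gene_id, cat_map$gene_id)
      genes$category <- cat_map$category[idx]
    }
    if ("feature_label" %in% names(lt)) {
      fl <- lt[!is.na(lt$feature_label) & lt$feature_label != "", ]
      labels <- data.frame(gene_id = fl$gene_id, label = fl$feature_label,
                           stringsAsFactors = FALSE)
    }
  }
  md <- as.list(metadata_row)
  genome(genome_id = md$genome_id, species_label = md$species_label,
         assembly_level = md$assembly_level, replicons = replicons,
         seqs = seqs, genes = genes, labels = labels,
         isolation_source = md$isolation_source %||% NA_character_)
}

#' Write a genome back to a FASTA/GFF3/protein bundle
#'
#' Emits the same file set [read_genome_bundle()] consumes:
#' `<genome_id>.fna`, `<genome_id>.gff3`, `<genome_id>.faa` and
#' `<genome_id>_labels.tsv`. Coordinates are converted back to 1-based
#' inclusive GFF3 convention. Output is deterministic.
#'
#' @param genome a [genome()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_genome_bundle <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- genome$genome_id
  paths <- c(fna = file.path(dir, paste0(id, ".fna")),
             gff = file.path(dir, paste0(id, ".gff3")),
             faa = file.path(dir, paste0(id, ".faa")),
             labels = file.path(dir, paste0(id, "_labels.tsv")))
  hdr <- ifelse(genome$replicons$topology == "circular",
                paste0(genome$replicons$replicon_id, " topology=circular"),
                genome$replicons$replicon_id)
  dna <- Biostrings::DNAStringSet(genome$seqs[genome$replicons$replicon_id])
  names(dna) <- hdr
  Biostrings::writeXStringSet(dna, paths["fna"], width = 80)

  g <- genome$genes[order(genome$genes$replicon_id, genome$genes$start), ,
                    drop = FALSE]
  gff_lines <- sprintf("%s\tpanstrep\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       g$replicon_id, g$start + 1L, g$end, g$strand,
                       g$gene_id)
  writeLines(c("##gff-version 3", gff_lines), paths["gff"])

  aa <- Biostrings::AAStringSet(setNames(g$protein, g$gene_id))
  Biostrings::writeXStringSet(aa, paths["faa"], width = 80)

  lab <- merge(data.frame(gene_id = g$gene_id,
                          category = g$category,
                          stringsAsFactors = FALSE),
               if (nrow(genome$labels))
                 data.frame(gene_id = genome$labels$gene_id,
                            feature_label = genome$labels$label,
                            stringsAsFactors = FALSE)
               else data.frame(gene_id = character(),
                               feature_label = character(),
                               stringsAsFactors = FALSE),
               by = "gene_id", all.x = TRUE)
  lab <- lab[order(lab$gene_id, lab$feature_label), , drop = FALSE]
  write_tsv_det(lab, paths["labels"])
  invisible(paths)
}

# Deterministic TSV writer: fixed column order as given, no quotes, no
# rownames, NA as empty string.
write_tsv_det <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
}

#' Write result tables as deterministic, sorted TSV files
#'
#' Each element of `results` is written as `<name>.tsv` with rows sorted by
#' all columns left to right, so re-running on the same inputs (in any row
#' order) produces byte-identical files.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(names(results) != ""))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    if (nrow(df) > 1)
      df <- df[do.call(order, unname(as.list(df))), , drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_det(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a rooted tree from a Newick file
#'
#' Thin validation wrapper over [ape::read.tree()]: requires unique leaf
#' labels and a parseable Newick string.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("invalid Newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("invalid Newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in ", path, ": ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Read a genome metadata table
#'
#' TSV with columns `genome_id`, `species_label`, `assembly_level`, and
#' optionally `isolation_source` and `release_order`. When present,
#' `release_order` must be a permutation rank of the rows.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species_label", "assembly_level")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$genome_id)) stop("duplicate genome_id in metadata")
  if ("release_order" %in% names(md) && !all(is.na(md$release_order))) {
    ro <- md$release_order[!is.na(md$release_order)]
    if (!setequal(ro, seq_along(ro)))
      stop("release_order must be a permutation rank")
  }
  md
}
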