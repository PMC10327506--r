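# Synthetic multi-species pan-genome generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream analyses
# assume: an ANI-separable species partition, genus-core / species-core /
# fingerprint / accessory gene-family stratification, positional bias of
# volatile families toward the chromosome arms, in-frame TTA codons with
# controlled cross-species conservation, and category/feature labels with
# controlled enrichment. See the methods vignette for the mutation model
# and the calibration algebra.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# High-GC actinobacterial proteome-like amino-acid composition.
AA_COMP <- local({
  x <- c(A = 0.120, R = 0.070, N = 0.020, D = 0.060, C = 0.008, Q = 0.025,
         E = 0.055, G = 0.090, H = 0.022, I = 0.030, L = 0.100, K = 0.020,
         M = 0.017, F = 0.030, P = 0.060, S = 0.050, T = 0.060, W = 0.015,
         Y = 0.020, V = 0.085)
  x / sum(x)
})

#' Configuration for the synthetic pan-genome generator
#'
#' Defaults define the package's reference desk-scale study conditions:
#' 10 species x 5 strains, 300 gene families (40 genus-core, 8 species-core
#' and 5 fingerprint families per species, a 130-family accessory pool),
#' 300-aa mean proteins, within-species protein identity 0.98 / ANI 0.97,
#' between-species (shared families) protein identity and ANI 0.85,
#' arm bias 0.8, GC 0.72.
#'
#' @param n_species number of species (>= 2).
#' @param strains_per_species integer or per-species vector.
#' @param n_genus_core_families families present in every genome.
#' @param n_species_core_families_per_species families private to one
#'   species, in all its strains.
#' @param n_fingerprint_families_per_species like species-core but counted
#'   as planted fingerprints (unique ancestors, no cross-species homolog).
#' @param accessory_family_pool size of the shared accessory family pool.
#' @param accessory_presence_prob per-genome presence probability of an
#'   accessory family (patterns covering all strains of a species are
#'   resampled so accessory families never masquerade as species cores).
#' @param mean_protein_length mean ancestral protein length (aa).
#' @param within_species_protein_identity,between_species_protein_identity
#'   target pairwise protein identities (between applies to shared,
#'   genus-core families; species-specific families are unrelated).
#' @param within_species_ani,between_species_ani target nucleotide
#'   identities; defaults straddle the 95 % species boundary.
#' @param arm_bias probability that a volatile family (fingerprint,
#'   accessory, TTA-planted) is placed on a chromosome arm; core-class
#'   families go to an arm with probability `1 - arm_bias`, so 0.5 is an
#'   exact positional null.
#' @param tta_orthogroup_fraction fraction of genus-core families receiving
#'   a planted in-frame TTA codon.
#' @param tta_site_conservation fraction of species carrying the planted
#'   TTA at the homologous site (others carry CTG there).
#' @param gc_content target chromosomal GC fraction.
#' @param category_weights named list of per-class COG-letter weight
#'   vectors (classes `genus_core`, `species_core`, `fingerprint`,
#'   `accessory`, `tta`).
#' @param uncategorized_prob probability a family carries no COG letter.
#' @param feature_label_prob probability a volatile family carries an smBGC
#'   (and, independently, a CAZyme) label.
#' @param draft_fraction probability a genome is labelled draft.
#' @param n_paralog_pairs tandem within-genome duplicate pairs planted per
#'   genome.
#' @param paralog_identity target identity of planted paralog copies.
#' @param mislabel_fraction fraction of genomes given another species'
#'   annotation label (for misannotation-flagging exercises).
#' @param chromosome_length optional fixed chromosome length; an error is
#'   raised when the gene content does not fit. `NULL` (default) sizes the
#'   chromosome automatically.
#' @param seed RNG seed; fixes every generated byte.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 10,
                       strains_per_species = 5,
                       n_genus_core_families = 40,
                       n_species_core_families_per_species = 8,
                       n_fingerprint_families_per_species = 5,
                       accessory_family_pool = 130,
                       accessory_presence_prob = 0.25,
                       mean_protein_length = 300,
                       within_species_protein_identity = 0.98,
                       between_species_protein_identity = 0.85,
                       within_species_ani = 0.97,
                       between_species_ani = 0.85,
                       arm_bias = 0.8,
                       tta_orthogroup_fraction = 0.2,
                       tta_site_conservation = 0.5,
                       gc_content = 0.72,
                       category_weights = NULL,
                       uncategorized_prob = 0.15,
                       feature_label_prob = 0.25,
                       draft_fraction = 0.2,
                       n_paralog_pairs = 0,
                       paralog_identity = 0.95,
                       mislabel_fraction = 0,
                       chromosome_length = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c("accessory_presence_prob", "within_species_protein_identity",
             "between_species_protein_identity", "within_species_ani",
             "between_species_ani", "arm_bias", "tta_orthogroup_fraction",
             "tta_site_conservation", "gc_content", "uncategorized_prob",
             "feature_label_prob", "draft_fraction", "paralog_identity",
             "mislabel_fraction")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]")
  if (n_species < 2) stop("n_species must be >= 2")
  if (within_species_protein_identity <= between_species_protein_identity)
    stop("within-species identity must exceed between-species identity")
  if (within_species_ani <= between_species_ani)
    stop("within-species ANI must exceed between-species ANI")
  cfg$strains_per_species <- rep(strains_per_species,
                                 length.out = n_species)
  if (is.null(category_weights)) {
    base <- c(C = 1, E = 1, F = 1, G = 1, H = 1, J = 1, K = 1, L = 1,
              M = 1, O = 1, P = 1, Q = 1, T = 1, S = 2)
    boost <- function(v, by) { w <- base; w[names(by)] <- w[names(by)] * by; w }
    cfg$category_weights <- list(
      genus_core = boost(base, c(J = 4, H = 3, F = 3, C = 3, O = 3)),
      species_core = base,
      fingerprint = boost(base, c(S = 6)),
      accessory = boost(base, c(S = 4)),
      tta = boost(base, c(K = 4, T = 4, Q = 3, L = 3)))
  }
  structure(cfg, class = "sim_config")
}

# ---- rate and codon machinery ------------------------------------------

# Per-branch amino-acid substitution probability (replacement uniform over
# the 20 letters) giving a target pairwise identity for a star pair:
# identity = (1-r)^2 + 2(1-r)r/20 + r^2/20.
solve_aa_rate <- function(target) {
  disc <- 3.61 - 3.8 * (1 - target)
  if (disc < 0) stop("unreachable identity target ", target)
  (1.9 - sqrt(disc)) / 1.9
}

# Per-branch nucleotide substitution probability (replacement uniform over
# 4) giving a target star-pair identity.
solve_nt_rate <- function(target) {
  disc <- 2.25 - 3 * (1 - target)
  if (disc < 0) stop("unreachable nucleotide identity target ", target)
  (1.5 - sqrt(disc)) / 1.5
}

# Codon machinery: sense codons excluding TTA (reserved for plants), with
# GC-biased usage weights.
codon_setup <- function(gc_target) {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)[code != "*"]
  codons <- setdiff(codons, "TTA")
  codon_aa <- code[codons]
  gc_frac <- vapply(strsplit(codons, ""), function(ch)
    mean(ch %in% c("G", "C")), numeric(1))
  names(gc_frac) <- codons
  weights_for <- function(gamma) {
    w <- exp(gamma * gc_frac * 3)
    lapply(split(seq_along(codons), codon_aa), function(idx)
      setNames(w[idx] / sum(w[idx]), codons[idx]))
  }
  expected_gc <- function(gamma) {
    W <- weights_for(gamma)
    sum(vapply(names(AA_COMP), function(aa)
      AA_COMP[[aa]] * sum(W[[aa]] * gc_frac[names(W[[aa]])]),
      numeric(1)))
  }
  lo <- expected_gc(-6); hi <- expected_gc(6)
  gamma <- if (gc_target <= lo) -6 else if (gc_target >= hi) 6 else
    stats::uniroot(function(g) expected_gc(g) - gc_target, c(-6, 6),
                   tol = 1e-8)$root
  W <- weights_for(gamma)
  # Codon-pair positional match fractions for the calibration algebra.
  mm <- matrix(0, length(codons), length(codons),
               dimnames = list(codons, codons))
  sp <- strsplit(codons, "")
  for (i in seq_along(codons))
    for (j in seq_along(codons))
      mm[i, j] <- mean(sp[[i]] == sp[[j]])
  list(codons = codons, codon_aa = codon_aa, weights = W, match = mm,
       gamma = gamma)
}

# Exact expected genic pairwise nucleotide identity for a star pair whose
# lineages apply amino-acid substitution probability r (uniform-20
# replacement) and synonymous codon resampling probability p from the
# GC-biased usage weights. Enumerates the full lineage codon distribution.
genic_pair_identity <- function(r, p, cs) {
  codons <- cs$codons
  nc <- length(codons)
  Waa <- matrix(0, 20, nc, dimnames = list(AA20, codons))
  for (aa in AA20) Waa[aa, names(cs$weights[[aa]])] <- cs$weights[[aa]]
  Wsum <- colSums(Waa)
  qx_of <- function(r) (1 - r) + r / 20
  total <- 0
  for (aa in AA20) {
    wcs <- cs$weights[[aa]]
    for (cc in names(wcs)) {
      v <- qx_of(r) * ((1 - p) * (codons == cc) + p * Waa[aa, ]) +
        (r / 20) * (Wsum - Waa[aa, ])
      total <- total + AA_COMP[[aa]] * wcs[[cc]] *
        drop(v %*% cs$match %*% v)
    }
  }
  total
}

# Solve the synonymous resampling probability so genic pair identity hits
# the target; returns the clamped value and the identity it realizes.
solve_syn_rate <- function(r, target, cs) {
  f0 <- genic_pair_identity(r, 0, cs)
  f1 <- genic_pair_identity(r, 1, cs)
  if (target >= f0) return(list(p = 0, realized = f0))
  if (target <= f1) return(list(p = 1, realized = f1))
  p <- stats::uniroot(function(p) genic_pair_identity(r, p, cs) - target,
                      c(0, 1), tol = 1e-6)$root
  list(p = p, realized = target)
}

sample_codons <- function(aa_vec, W) {
  out <- character(length(aa_vec))
  for (aa in unique(aa_vec)) {
    idx <- which(aa_vec == aa)
    w <- W[[aa]]
    out[idx] <- sample(names(w), length(idx), replace = TRUE, prob = w)
  }
  out
}

mutate_aa <- function(aa_vec, r, frozen = integer(0)) {
  mut <- which(stats::runif(length(aa_vec)) < r)
  mut <- setdiff(mut, frozen)
  out <- aa_vec
  if (length(mut)) out[mut] <- sample(AA20, length(mut), replace = TRUE)
  out
}

derive_codons <- function(old_cod, old_aa, new_aa, p, W,
                          frozen = integer(0)) {
  out <- old_cod
  changed <- which(new_aa != old_aa)
  if (length(changed)) out[changed] <- sample_codons(new_aa[changed], W)
  syn <- which(new_aa == old_aa & stats::runif(length(new_aa)) < p)
  syn <- setdiff(syn, frozen)
  if (length(syn)) out[syn] <- sample_codons(new_aa[syn], W)
  out
}

random_nt <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

mutate_nt <- function(nt_vec, s) {
  mut <- which(stats::runif(length(nt_vec)) < s)
  out <- nt_vec
  if (length(mut))
    out[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
  out
}

# ---- generation ---------------------------------------------------------

#' Generate a synthetic pan-genome with planted ground truth
#'
#' Produces a deterministic (seed-fixed) multi-species strain collection:
#' linear chromosomes with non-overlapping genes, family stratification
#' (genus-core / species-core / fingerprint / accessory), ANI and protein
#' identity calibrated to the configured targets, arm/centre positional
#' bias, planted in-frame TTA codons with controlled conservation, and
#' category/feature labels. The returned truth key records every plant.
#'
#' @param config a [sim_config()].
#' @param verify_ani if TRUE (default), the realized ANI of a sampled
#'   within-species and between-species pair is measured and a warning is
#'   emitted when more than 1 percentage point off target.
#' @return object of class `"pangenome_sim"`: list with `genomes` (named
#'   list of [genome()] objects), `truth` (see [truth_report()]),
#'   `metadata` (data.frame), `config`, and `internal` (ancestral states
#'   used by [plant_tta()]).
#' @export
generate_pangenome <- function(config, verify_ani = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  sim <- with_seed(config$seed, generate_pangenome_impl(config))
  if (verify_ani) {
    part <- split(sim$metadata$genome_id, sim$metadata$species_id)
    wpair <- part[[1]][1:2]
    bpair <- c(part[[1]][1], part[[2]][1])
    wa <- as.numeric(ani(sim$genomes[[wpair[1]]], sim$genomes[[wpair[2]]]))
    ba <- as.numeric(ani(sim$genomes[[bpair[1]]], sim$genomes[[bpair[2]]]))
    if (!is.na(wa) && abs(wa - config$within_species_ani) > 0.01)
      warning(sprintf("realized within-species ANI %.3f is > 1 point from target %.3f",
                      wa, config$within_species_ani))
    if (!is.na(ba) && abs(ba - config$between_species_ani) > 0.02)
      warning(sprintf("realized between-species ANI %.3f is > 2 points from target %.3f",
                      ba, config$between_species_ani))
    sim$realized_ani <- c(within = wa, between = ba)
  }
  sim
}

generate_pangenome_impl <- function(config) {
  cfg <- config
  ns <- cfg$n_species
  species_ids <- sprintf("sp%02d", seq_len(ns))
  strains <- cfg$strains_per_species
  genome_ids <- unlist(lapply(seq_len(ns), function(s)
    sprintf("%s_g%02d", species_ids[s], seq_len(strains[s]))))
  species_of_genome <- rep(species_ids, strains)
  names(species_of_genome) <- genome_ids

  # --- family table ------------------------------------------------------
  fam <- list()
  add_fam <- function(class, species) {
    n <- length(fam) + 1L
    fam[[n]] <<- list(family_id = sprintf("fam%04d", n), class = class,
                      species = species)
  }
  for (i in seq_len(cfg$n_genus_core_families)) add_fam("genus_core", NA)
  for (s in species_ids) {
    for (i in seq_len(cfg$n_species_core_families_per_species))
      add_fam("species_core", s)
    for (i in seq_len(cfg$n_fingerprint_families_per_species))
      add_fam("fingerprint", s)
  }
  for (i in seq_len(cfg$accessory_family_pool)) add_fam("accessory", NA)
  families <- do.call(rbind, lapply(fam, function(f)
    data.frame(family_id = f$family_id, class = f$class,
               species = ifelse(is.na(f$species), NA_character_,
                                f$species),
               stringsAsFactors = FALSE)))
  nf <- nrow(families)

  # --- TTA plants (genus-core families only) -----------------------------
  gc_rows <- which(families$class == "genus_core")
  n_tta <- round(cfg$tta_orthogroup_fraction * length(gc_rows))
  tta_rows <- if (n_tta > 0) sort(sample(gc_rows, n_tta)) else integer(0)
  families$tta <- seq_len(nf) %in% tta_rows
  n_tta_species <- max(1, round(cfg$tta_site_conservation * ns))

  # --- ancestral proteins ------------------------------------------------
  lens <- pmax(60L, round(stats::rnorm(nf, cfg$mean_protein_length,
                                       cfg$mean_protein_length * 0.15)))
  anc_aa <- vector("list", nf)
  tta_index <- rep(NA_integer_, nf)
  tta_species <- vector("list", nf)
  for (i in seq_len(nf)) {
    aa <- c("M", sample(AA20, lens[i] - 1, replace = TRUE, prob = AA_COMP))
    if (families$tta[i]) {
      idx <- sample(5:(lens[i] - 5), 1)
      aa[idx] <- "L"
      tta_index[i] <- idx
      tta_species[[i]] <- sort(sample(species_ids, n_tta_species))
    }
    anc_aa[[i]] <- aa
  }

  # --- divergence calibration -------------------------------------------
  cs <- codon_setup(cfg$gc_content)
  r1 <- solve_aa_rate(cfg$within_species_protein_identity)
  r_eff_b <- solve_aa_rate(cfg$between_species_protein_identity)
  if (r_eff_b <= r1)
    stop("between-species protein identity must be below within-species")
  r2 <- 1 - (1 - r_eff_b) / (1 - r1)
  syn_w <- solve_syn_rate(r1, cfg$within_species_ani, cs)
  p1 <- syn_w$p
  syn_b <- solve_syn_rate(r_eff_b, cfg$between_species_ani, cs)
  p_eff <- syn_b$p
  p2 <- max(0, 1 - (1 - p_eff) / (1 - p1))
  s1 <- solve_nt_rate(cfg$within_species_ani)

  # --- presence ----------------------------------------------------------
  presence <- matrix(FALSE, nf, length(genome_ids),
                     dimnames = list(families$family_id, genome_ids))
  presence[families$class == "genus_core", ] <- TRUE
  for (i in which(families$class %in% c("species_core", "fingerprint")))
    presence[i, species_of_genome == families$species[i]] <- TRUE
  # Accessory families are scattered; species-core families additionally
  # spill over into other species the same way (a species core need not be
  # exclusive - exclusivity is what distinguishes a fingerprint).
  for (i in which(families$class %in% c("accessory", "species_core"))) {
    own <- families$species[i]
    scatter <- is.na(own) | species_of_genome != own
    pres <- presence[i, ]
    pres[scatter] <- stats::runif(sum(scatter)) < cfg$accessory_presence_prob
    # never let a scattered family cover a whole foreign species
    for (s in species_ids) {
      if (!is.na(own) && s == own) next
      in_sp <- which(species_of_genome == s)
      if (length(in_sp) > 1 && all(pres[in_sp]))
        pres[sample(in_sp, 1)] <- FALSE
    }
    # a species core must not masquerade as a fingerprint: guarantee at
    # least one foreign occurrence (prefer multi-strain foreign species so
    # the no-full-coverage rule stays satisfiable)
    if (!is.na(own) && !any(pres[scatter])) {
      cand <- which(scatter)
      multi <- cand[species_of_genome[cand] %in%
                      species_ids[tabulate(factor(species_of_genome,
                                                  species_ids)) > 1]]
      pick <- if (length(multi)) multi else cand
      pres[if (length(pick) == 1) pick else sample(pick, 1)] <- TRUE
    }
    presence[i, ] <- pres
  }

  # --- categories and feature labels -------------------------------------
  families$category <- NA_character_
  families$smbgc <- NA_character_
  families$cazyme <- NA_character_
  smbgc_pool <- c("NRPS", "PKS-I", "PKS-II", "terpene", "siderophore",
                  "lanthipeptide", "RiPP-like", "butyrolactone")
  cazyme_pool <- c("GH13", "GH3", "GT2", "GT4", "CE1", "PL1", "CBM13",
                   "AA3")
  for (i in seq_len(nf)) {
    if (stats::runif(1) >= cfg$uncategorized_prob) {
      wclass <- if (families$tta[i]) "tta" else families$class[i]
      w <- cfg$category_weights[[wclass]]
      families$category[i] <- sample(names(w), 1, prob = w)
    }
    if (families$class[i] %in% c("fingerprint", "accessory")) {
      if (stats::runif(1) < cfg$feature_label_prob)
        families$smbgc[i] <- sample(smbgc_pool, 1)
      if (stats::runif(1) < cfg$feature_label_prob)
        families$cazyme[i] <- sample(cazyme_pool, 1)
    }
  }

  # --- per-species layout -------------------------------------------------
  volatile <- families$class %in% c("fingerprint", "accessory") |
    families$tta
  layouts <- list()
  for (s in species_ids) {
    in_sp <- which(species_of_genome == s)
    fam_rows <- which(rowSums(presence[, in_sp, drop = FALSE]) > 0)
    p_arm <- ifelse(volatile[fam_rows], cfg$arm_bias, 1 - cfg$arm_bias)
    on_arm <- stats::runif(length(fam_rows)) < p_arm
    side <- ifelse(on_arm,
                   ifelse(stats::runif(length(fam_rows)) < 0.5,
                          "left_arm", "right_arm"),
                   "centre")
    strand <- sample(c("+", "-"), length(fam_rows), replace = TRUE)
    spacer <- sample(100:200, length(fam_rows), replace = TRUE)
    ord <- sample(length(fam_rows))   # shuffle within zones below
    df <- data.frame(fam_row = fam_rows, zone = side, strand = strand,
                     spacer = spacer, stringsAsFactors = FALSE)[ord, ]
    df <- df[order(match(df$zone, c("left_arm", "centre", "right_arm"))), ]
    gene_len <- 3 * (lens[df$fam_row] + 1)
    df$content <- df$spacer + gene_len
    need <- tapply(df$content, factor(df$zone,
                                      levels = c("left_arm", "centre",
                                                 "right_arm")), sum)
    need[is.na(need)] <- 0
    # worst case all tandem-duplicate plants land in one zone
    need <- need + cfg$n_paralog_pairs * (3 * (max(lens) + 1) + 50)
    L <- ceiling(1.15 * max(4 * need[["left_arm"]], 2 * need[["centre"]],
                            4 * need[["right_arm"]], 8000))
    if (!is.null(cfg$chromosome_length)) {
      L_fixed <- cfg$chromosome_length
      if (max(4 * need[["left_arm"]], 2 * need[["centre"]],
              4 * need[["right_arm"]]) > L_fixed)
        stop("infeasible layout: gene content does not fit a chromosome ",
             "of length ", L_fixed)
      L <- L_fixed
    }
    L <- 4 * ceiling(L / 4)
    targets <- c(left_arm = L / 4, centre = L / 2, right_arm = L / 4)
    filler_anc <- lapply(targets, function(tl) random_nt(tl,
                                                         cfg$gc_content))
    spacer_anc <- lapply(seq_len(nrow(df)), function(i)
      random_nt(df$spacer[i], cfg$gc_content))
    layouts[[s]] <- list(df = df, L = L, targets = targets,
                         filler_anc = filler_anc, spacer_anc = spacer_anc)
  }

  # --- sequence evolution -------------------------------------------------
  # Species-level templates per (family, species), then strain sequences.
  sp_templates <- list()  # [[family]][[species]] = list(aa, cod)
  for (i in seq_len(nf)) {
    frozen <- c(1L, if (!is.na(tta_index[i])) tta_index[i])
    anc_cod <- sample_codons(anc_aa[[i]], cs$weights)
    per_sp <- list()
    for (s in species_ids) {
      in_sp <- which(species_of_genome == s)
      if (!any(presence[i, in_sp])) next
      sp_aa <- mutate_aa(anc_aa[[i]], r2, frozen)
      sp_cod <- derive_codons(anc_cod, anc_aa[[i]], sp_aa, p2,
                              cs$weights, frozen)
      per_sp[[s]] <- list(aa = sp_aa, cod = sp_cod)
    }
    sp_templates[[families$family_id[i]]] <- per_sp
  }

  strain_genes <- list()  # [[genome_id]][[family_id]] = list(aa, cod)
  for (g in genome_ids) {
    s <- species_of_genome[[g]]
    fams_here <- which(presence[, g])
    per_fam <- list()
    for (i in fams_here) {
      fid <- families$family_id[i]
      tpl <- sp_templates[[fid]][[s]]
      frozen <- c(1L, if (!is.na(tta_index[i])) tta_index[i])
      st_aa <- mutate_aa(tpl$aa, r1, frozen)
      st_cod <- derive_codons(tpl$cod, tpl$aa, st_aa, p1, cs$weights,
                              frozen)
      if (families$tta[i]) {
        idx <- tta_index[i]
        st_cod[idx] <- if (s %in% tta_species[[i]]) "TTA" else "CTG"
      }
      per_fam[[fid]] <- list(aa = st_aa, cod = st_cod)
    }
    strain_genes[[g]] <- per_fam
  }

  # --- assembly -----------------------------------------------------------
  draft <- stats::runif(length(genome_ids)) < cfg$draft_fraction
  names(draft) <- genome_ids
  iso_pool <- c("soil", "marine sediment", "rhizosphere", "compost")
  iso <- sample(iso_pool, length(genome_ids), replace = TRUE)
  names(iso) <- genome_ids

  # paralog plants: chosen per genome among its present families
  paralog_of <- lapply(genome_ids, function(g) {
    fams_here <- families$family_id[presence[, g]]
    if (cfg$n_paralog_pairs > 0 && length(fams_here))
      sort(sample(fams_here, min(cfg$n_paralog_pairs, length(fams_here))))
    else character(0)
  })
  names(paralog_of) <- genome_ids
  r_par <- solve_aa_rate(cfg$paralog_identity)

  genomes <- list()
  truth_genes <- list()
  for (g in genome_ids) {
    s <- species_of_genome[[g]]
    ly <- layouts[[s]]
    segs <- character(0)
    pos <- 0L
    rows <- list()
    for (zone in c("left_arm", "centre", "right_arm")) {
      zrows <- which(ly$df$zone == zone)
      present_z <- zrows[presence[ly$df$fam_row[zrows], g]]
      content <- if (length(present_z)) {
        extra <- sum(vapply(present_z, function(zi) {
          fid <- families$family_id[ly$df$fam_row[zi]]
          if (fid %in% paralog_of[[g]])
            50L + 3L * (lens[ly$df$fam_row[zi]] + 1L) else 0L
        }, numeric(1)))
        sum(ly$df$content[present_z]) + extra
      } else 0
      filler_len <- ly$targets[[zone]] - content
      if (filler_len < 0)
        stop("infeasible layout: zone ", zone, " overflows in ", g)
      if (filler_len > 0) {
        fl <- mutate_nt(ly$filler_anc[[zone]][seq_len(filler_len)], s1)
        segs <- c(segs, paste(fl, collapse = ""))
        pos <- pos + filler_len
      }
      for (zi in present_z) {
        i <- ly$df$fam_row[zi]
        fid <- families$family_id[i]
        sp_nt <- mutate_nt(ly$spacer_anc[[zi]], s1)
        segs <- c(segs, paste(sp_nt, collapse = ""))
        pos <- pos + length(sp_nt)
        gene <- strain_genes[[g]][[fid]]
        cds <- paste(c(gene$cod, "TGA"), collapse = "")
        glen <- nchar(cds)
        strand <- ly$df$strand[zi]
        segs <- c(segs, if (strand == "+") cds else revcomp(cds))
        gid <- paste0(g, "_", fid)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, replicon_id = "chr", start = pos,
          end = pos + glen, strand = strand, cds = cds,
          protein = paste(gene$aa, collapse = ""),
          category = families$category[i], translatable = TRUE,
          stringsAsFactors = FALSE)
        truth_genes[[length(truth_genes) + 1L]] <- data.frame(
          gene_id = gid, genome_id = g, family_id = fid,
          stringsAsFactors = FALSE)
        pos <- pos + glen
        if (fid %in% paralog_of[[g]]) {
          # tandem duplicate: mutated copy right after the original
          dup_aa <- mutate_aa(gene$aa, r_par, 1L)
          dup_cod <- derive_codons(gene$cod, gene$aa, dup_aa, p1,
                                   cs$weights)
          dup_cds <- paste(c(dup_cod, "TGA"), collapse = "")
          spac <- random_nt(50, cfg$gc_content)
          segs <- c(segs, paste(spac, collapse = ""))
          pos <- pos + 50L
          dgid <- paste0(gid, "_p2")
          segs <- c(segs, if (strand == "+") dup_cds else revcomp(dup_cds))
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = dgid, replicon_id = "chr", start = pos,
            end = pos + nchar(dup_cds), strand = strand, cds = dup_cds,
            protein = paste(dup_aa, collapse = ""),
            category = families$category[i], translatable = TRUE,
            stringsAsFactors = FALSE)
          truth_genes[[length(truth_genes) + 1L]] <- data.frame(
            gene_id = dgid, genome_id = g, family_id = fid,
            stringsAsFactors = FALSE)
          pos <- pos + nchar(dup_cds)
        }
      }
    }
    chrom <- paste(segs, collapse = "")
    stopifnot(nchar(chrom) == ly$L)
    genes <- do.call(rbind, c(rows, make.row.names = FALSE))
    lab_rows <- list()
    for (i in seq_len(nrow(genes))) {
      fid <- sub("_p2$", "", sub(paste0("^", g, "_"), "",
                                 genes$gene_id[i]))
      frow <- match(fid, families$family_id)
      for (lb in c(families$smbgc[frow], families$cazyme[frow]))
        if (!is.na(lb))
          lab_rows[[length(lab_rows) + 1L]] <-
            data.frame(gene_id = genes$gene_id[i], label = lb,
                       stringsAsFactors = FALSE)
    }
    labels <- if (length(lab_rows))
      do.call(rbind, c(lab_rows, make.row.names = FALSE)) else NULL
    genomes[[g]] <- genome(
      genome_id = g,
      species_label = paste0("Streptomyces simulans ", s),
      assembly_level = if (draft[[g]]) "draft" else "complete",
      replicons = data.frame(replicon_id = "chr", topology = "linear",
                             stringsAsFactors = FALSE),
      seqs = c(chr = chrom), genes = genes, labels = labels,
      isolation_source = iso[[g]])
  }

  # optional mislabelling
  if (cfg$mislabel_fraction > 0) {
    n_mis <- round(cfg$mislabel_fraction * length(genome_ids))
    for (g in sample(genome_ids, n_mis)) {
      other <- sample(setdiff(species_ids, species_of_genome[[g]]), 1)
      genomes[[g]]$species_label <-
        paste0("Streptomyces simulans ", other)
    }
  }

  metadata <- data.frame(
    genome_id = genome_ids,
    species_id = unname(species_of_genome),
    species_label = vapply(genomes, function(g) g$species_label,
                           character(1))[genome_ids],
    assembly_level = ifelse(draft[genome_ids], "draft", "complete"),
    isolation_source = unname(iso[genome_ids]),
    release_order = sample(length(genome_ids)),
    stringsAsFactors = FALSE)

  tta_df <- if (length(tta_rows)) do.call(rbind, lapply(tta_rows,
    function(i) data.frame(
      family_id = families$family_id[i], codon_index = tta_index[i],
      species = paste(tta_species[[i]], collapse = ","),
      stringsAsFactors = FALSE)))
    else data.frame(family_id = character(), codon_index = integer(),
                    species = character())

  zone_df <- do.call(rbind, lapply(species_ids, function(s) {
    df <- layouts[[s]]$df
    data.frame(species_id = s,
               family_id = families$family_id[df$fam_row],
               zone = df$zone, stringsAsFactors = FALSE)
  }))

  truth <- list(families = families,
                genes = do.call(rbind, c(truth_genes,
                                         make.row.names = FALSE)),
                partition = data.frame(genome_id = genome_ids,
                                       species_id =
                                         unname(species_of_genome),
                                       stringsAsFactors = FALSE),
                tta = tta_df,
                zones = zone_df)

  structure(list(genomes = genomes, truth = truth, metadata = metadata,
                 config = cfg,
                 internal = list(anc_aa = setNames(anc_aa,
                                                   families$family_id),
                                 rates = list(r1 = r1, r2 = r2, p1 = p1,
                                              p2 = p2, s1 = s1),
                                 codon_setup = cs)),
            class = "pangenome_sim")
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat(sprintf(
    "<pangenome_sim> %d genomes, %d species, %d families (seed %d)\n",
    length(x$genomes), x$config$n_species, nrow(x$truth$families),
    x$config$seed))
  invisible(x)
}

#' Plant a TTA codon into a family after generation
#'
#' Forces the codon at `codon_index` to TTA in all members of the family in
#' `species_ids` and to CTG (a non-TTA leucine codon) in all other members,
#' updating proteins, CDS and chromosome sequences consistently. The codon
#' at `codon_index` must encode leucine in the family ancestor.
#'
#' @param sim a [generate_pangenome()] result.
#' @param family_id family to modify.
#' @param codon_index 1-based codon position (stop codon excluded).
#' @param species_ids species receiving the TTA.
#' @return the modified `pangenome_sim`.
#' @export
plant_tta <- function(sim, family_id, codon_index, species_ids) {
  stopifnot(inherits(sim, "pangenome_sim"))
  anc <- sim$internal$anc_aa[[family_id]]
  if (is.null(anc)) stop("unknown family: ", family_id)
  if (codon_index < 1 || codon_index > length(anc))
    stop("codon_index out of range for family ", family_id)
  if (anc[codon_index] != "L")
    stop("codon ", codon_index, " of family ", family_id,
         " does not encode leucine in the ancestor")
  bad_sp <- setdiff(species_ids, sim$truth$partition$species_id)
  if (length(bad_sp)) stop("unknown species: ", paste(bad_sp,
                                                      collapse = ", "))
  gmap <- sim$truth$genes[sim$truth$genes$family_id == family_id, ]
  species_of <- setNames(sim$truth$partition$species_id,
                         sim$truth$partition$genome_id)
  for (ri in seq_len(nrow(gmap))) {
    g <- gmap$genome_id[ri]
    gid <- gmap$gene_id[ri]
    codon <- if (species_of[[g]] %in% species_ids) "TTA" else "CTG"
    sim$genomes[[g]] <- set_codon(sim$genomes[[g]], gid, codon_index,
                                  codon)
  }
  new_row <- data.frame(family_id = family_id, codon_index = codon_index,
                        species = paste(sort(species_ids), collapse = ","),
                        stringsAsFactors = FALSE)
  tta <- sim$truth$tta[sim$truth$tta$family_id != family_id |
                         sim$truth$tta$codon_index != codon_index, ,
                       drop = FALSE]
  sim$truth$tta <- rbind(tta, new_row)
  frow <- match(family_id, sim$truth$families$family_id)
  sim$truth$families$tta[frow] <- TRUE
  sim
}

# Overwrite one codon of a gene (cds, protein, chromosome) in place.
set_codon <- function(genome, gene_id, codon_index, codon) {
  gi <- match(gene_id, genome$genes$gene_id)
  stopifnot(!is.na(gi))
  g <- genome$genes[gi, ]
  n_codons <- nchar(g$cds) %/% 3
  stopifnot(codon_index <= n_codons - 1)  # stop codon untouchable
  cds <- g$cds
  substr(cds, 3 * (codon_index - 1) + 1, 3 * codon_index) <- codon
  aa <- unname(Biostrings::GENETIC_CODE[[codon]])
  prot <- g$protein
  substr(prot, codon_index, codon_index) <- aa
  genome$genes$cds[gi] <- cds
  genome$genes$protein[gi] <- prot
  chrom <- genome$seqs[[g$replicon_id]]
  if (g$strand == "+") {
    at <- g$start + 3 * (codon_index - 1) + 1    # 1-based
    substr(chrom, at, at + 2) <- codon
  } else {
    at <- g$end - 3 * codon_index + 1            # 1-based
    substr(chrom, at, at + 2) <- revcomp(codon)
  }
  genome$seqs[[g$replicon_id]] <- chrom
  genome
}

#' Machine-readable truth key for a synthetic pan-genome
#'
#' Flattens the planted ground truth into data.frames suitable for
#' [write_tables()]: per-family class (with species for species-bound
#' classes), TTA plants, the true species partition, and the gene-to-family
#' map.
#'
#' @param truth the `truth` element of a [generate_pangenome()] result.
#' @return named list of data.frames (`families`, `tta_plants`,
#'   `partition`, `genes`).
#' @export
truth_report <- function(truth) {
  fam <- truth$families[, c("family_id", "class", "species", "category",
                            "smbgc", "cazyme")]
  list(families = fam,
       tta_plants = truth$tta,
       partition = truth$partition,
       genes = truth$genes)
}

#' Write a whole synthetic pan-genome as FASTA/GFF3/TSV bundles
#'
#' One [write_genome_bundle()] per genome plus `metadata.tsv` and the truth
#' key tables.
#'
#' @param sim a [generate_pangenome()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_pangenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) write_genome_bundle(g, dir)
  write_tsv_det(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tables(truth_report(sim$truth), file.path(dir, "truth"))
  invisible(dir)
}
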