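#' Default six-member three-generation pedigree
#'
#' The family structure the simulator and fixtures assume: an affected
#' grandfather married to an unaffected grandmother, their affected son
#' (the father) and unaffected son (the uncle), an unaffected mother who
#' married in, and an affected daughter — three affected and three
#' unaffected members, consistent with a fully penetrant autosomal
#' dominant variant carried along the grandfather-father-daughter chain.
#'
#' @return A `pedigree` data frame.
#' @export
default_pedigree <- function() {
  validate_pedigree(data.frame(
    fam = "FAM1",
    id = c("GF", "GM", "FA", "UN", "MO", "DA"),
    father = c(NA, NA, "GF", "GF", NA, "FA"),
    mother = c(NA, NA, "GM", "GM", NA, "MO"),
    sex = c("male", "female", "male", "male", "female", "female"),
    phenotype = c("affected", "unaffected", "affected", "unaffected",
                  "unaffected", "affected"),
    stringsAsFactors = FALSE))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders draw two alleles under Hardy-Weinberg equilibrium at the
#' given alt-allele frequency; every non-founder inherits one uniformly
#' chosen allele from each parent, so the output is Mendelian-consistent
#' by construction. Vectorized over independent variants: `freq` may be a
#' vector, and each variant is dropped independently.
#'
#' @param ped a `pedigree` from [read_ped()] / [default_pedigree()].
#' @param freq alt-allele frequency, scalar or vector (one per variant).
#' @param n number of variants (defaults to `length(freq)`).
#' @return List with `dosage` (n x members integer matrix, columns named
#'   by member id) and `alleles` (n x members x 2 array of 0/1).
#' @export
gene_drop <- function(ped, freq, n = length(freq)) {
  stopifnot(all(freq >= 0 & freq <= 1))
  if (length(freq) == 1) freq <- rep(freq, n)
  stopifnot(length(freq) == n)
  ord <- attr(ped, "topo_order") %||% ped$id
  al <- array(NA_integer_, c(n, nrow(ped), 2),
              dimnames = list(NULL, ped$id, NULL))
  for (id in ord) {
    r <- ped[ped$id == id, ]
    for (k in 1:2) {
      parent <- if (k == 1) r$father else r$mother
      if (is.na(parent)) {
        al[, id, k] <- rbinom(n, 1, freq)
      } else {
        pick <- rbinom(n, 1, 0.5) + 1L
        pa <- al[, parent, , drop = FALSE]
        al[, id, k] <- pa[cbind(seq_len(n), 1L, pick)]
      }
    }
  }
  dosage <- matrix(al[, , 1], nrow = n) + matrix(al[, , 2], nrow = n)
  colnames(dosage) <- ped$id
  list(dosage = dosage, alleles = al)
}

#' Simulation configuration
#'
#' Study conditions for [simulate_cohort()]: the six-member pedigree, one
#' planted fully penetrant heterozygous dominant causal variant
#' (frameshift deletion, absent from every population source, CADD-high,
#' heterozygous in all affected and homozygous reference in all
#' unaffected members), and `n_background` background variants gene-
#' dropped through the pedigree with randomized annotation. Background
#' variants split into a common component (founder frequency
#' `common_maf_range`, so database MAFs fail the rarity stage) and a rare
#' component (`rare_maf_range`; database entries present with probability
#' `db_presence_rare`, absent otherwise). Functional classes cover
#' missense, synonymous, small nonframeshift deletions inside and
#' outside repeat-masked intervals, intronic and near/far splicing
#' variants; background effects deliberately exclude truncating classes,
#' since a chance-co-segregating background frameshift would be
#' indistinguishable from the planted variant. Per-tool damaging calls
#' fire with probability `predictor_damaging_rate`; a
#' `fraction_low_quality` of background sites is drawn below one site-
#' quality threshold.
#'
#' @param seed integer seed; identical configs give byte-identical
#'   output files.
#' @param n_background number of background variants.
#' @param pedigree pedigree template (default [default_pedigree()]).
#' @param fraction_common fraction of background in the common component.
#' @param fraction_synonymous,fraction_repeat_nonframeshift,fraction_nonframeshift_clear,fraction_intronic,fraction_splicing
#'   background class fractions; the remainder is missense.
#' @param predictor_damaging_rate per-tool probability of a damaging call
#'   on a background variant.
#' @param fraction_low_quality fraction of background sites failing one
#'   site-quality metric.
#' @param rare_maf_range,common_maf_range founder-frequency ranges of the
#'   two components.
#' @param db_presence_rare probability a rare background variant has an
#'   entry in a given frequency database.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 5000L,
                       pedigree = default_pedigree(),
                       fraction_common = 0.5,
                       fraction_synonymous = 0.25,
                       fraction_repeat_nonframeshift = 0.05,
                       fraction_nonframeshift_clear = 0.05,
                       fraction_intronic = 0.10,
                       fraction_splicing = 0.05,
                       predictor_damaging_rate = 0.1,
                       fraction_low_quality = 0.1,
                       rare_maf_range = c(1e-4, 0.005),
                       common_maf_range = c(0.02, 0.35),
                       db_presence_rare = 0.5) {
  cfg <- as.list(environment())
  fr <- c(fraction_common, fraction_synonymous, fraction_repeat_nonframeshift,
          fraction_nonframeshift_clear, fraction_intronic, fraction_splicing,
          predictor_damaging_rate, fraction_low_quality, db_presence_rare)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  cls <- fraction_synonymous + fraction_repeat_nonframeshift +
    fraction_nonframeshift_clear + fraction_intronic + fraction_splicing
  if (cls > 1) stop("background class fractions sum to more than 1")
  if (n_background < 0) stop("n_background must be >= 0")
  stopifnot(inherits(pedigree, "pedigree"))
  structure(cfg, class = "sim_config")
}

# Background class labels in draw order; remainder probability -> missense.
sim_class_probs <- function(cfg) {
  p <- c(synonymous = cfg$fraction_synonymous,
         repeat_nfs = cfg$fraction_repeat_nonframeshift,
         clear_nfs = cfg$fraction_nonframeshift_clear,
         intronic = cfg$fraction_intronic,
         splicing = cfg$fraction_splicing)
  c(p, missense = 1 - sum(p))
}

#' Simulate a pedigree-structured cohort with a planted causal variant
#'
#' Writes `cohort.vcf` (annotated, multi-sample), `family.ped`,
#' `repeats.bed` (intervals covering the designated repeat-resident
#' background indels) and `truth.tsv` into `out_dir`. The truth table
#' labels every variant `planted` or `background` and records the first
#' cascade stage expected to remove it (`pass` for the planted variant),
#' computed from the simulator's own generative quantities.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the four file paths and the `truth`
#'   data frame.
#' @export
simulate_cohort <- function(cfg = sim_config(), out_dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  ped <- cfg$pedigree
  affected <- ped$id[ped$phenotype == "affected"]
  unaffected <- ped$id[ped$phenotype == "unaffected"]
  n <- cfg$n_background
  nt <- n + 1L                                  # + planted

  pos <- sort(sample.int(2e8L, nt))             # globally unique positions
  chrom <- paste0("chr", sample(1:22, nt, replace = TRUE))
  planted_i <- sample.int(nt, 1)

  cls <- rep("planted", nt)
  if (n > 0) {
    pr <- sim_class_probs(cfg)
    cls[-planted_i] <- sample(names(pr), n, replace = TRUE, prob = pr)
  }

  ## founder frequencies and genotypes
  founder_freq <- numeric(nt)
  is_common <- rep(FALSE, nt)
  if (n > 0) {
    bg <- which(cls != "planted")
    is_common[bg] <- runif(n) < cfg$fraction_common
    founder_freq[bg] <- ifelse(is_common[bg],
                               runif(n, cfg$common_maf_range[1],
                                     cfg$common_maf_range[2]),
                               runif(n, cfg$rare_maf_range[1],
                                     cfg$rare_maf_range[2]))
  }
  geno <- gene_drop(ped, founder_freq, nt)$dosage
  geno[planted_i, ] <- ifelse(ped$id %in% affected, 1L, 0L)[
    match(colnames(geno), ped$id)]

  ## alleles
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nt, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  nfs <- cls %in% c("repeat_nfs", "clear_nfs")
  if (any(nfs)) {
    L <- sample(c(3L, 6L, 9L), sum(nfs), replace = TRUE)
    ref[nfs] <- vapply(seq_len(sum(nfs)), function(i)
      paste(c(alt[nfs][i],
              sample(bases, L[i], replace = TRUE)), collapse = ""), "")
    # alt keeps the shared leading base -> in-frame deletion of L bases
    alt[nfs] <- substr(ref[nfs], 1, 1)
  }
  ref[planted_i] <- paste0(alt[planted_i],
                           sample(bases, 1))   # 1-bp deletion, frameshift
  alt[planted_i] <- substr(ref[planted_i], 1, 1)

  ## annotation columns
  region <- rep("exonic", nt)
  region[cls == "intronic"] <- "intronic"
  region[cls == "splicing"] <- "splicing"
  effect <- rep(NA_character_, nt)
  effect[cls == "missense"] <- "nonsynonymous_SNV"
  effect[cls == "synonymous"] <- "synonymous_SNV"
  effect[nfs] <- "nonframeshift_deletion"
  effect[planted_i] <- "frameshift_deletion"
  splice_dist <- rep(NA_real_, nt)
  splice_dist[cls == "splicing"] <- sample(1:30, sum(cls == "splicing"),
                                           replace = TRUE)
  gene <- sprintf("BG%05d", seq_len(nt))
  gene[planted_i] <- "CAUSAL1"
  transcript <- sprintf("NM_%06d", sample.int(999999L, nt))
  exon <- sample(1:20, nt, replace = TRUE)
  cpos <- sample(1:9000, nt, replace = TRUE)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  codon <- codon_of_cdna_position(cpos)
  cdna <- sprintf("c.%d%s>%s", cpos, ref, alt)
  protein <- sprintf("p.%s%d%s", sample(aa, nt, replace = TRUE), codon,
                     sample(aa, nt, replace = TRUE))
  del <- nfs | seq_len(nt) == planted_i
  cdna[del] <- sprintf("c.%d_%ddel", cpos[del],
                       cpos[del] + nchar(ref[del]) - 2L)
  cdna[planted_i] <- sprintf("c.%ddel%s", cpos[planted_i],
                             substr(ref[planted_i], 2, 2))
  protein[del] <- sprintf("p.%s%dfs", sample(aa, sum(del), replace = TRUE),
                          codon[del])
  cdna[region != "exonic"] <- NA
  protein[region != "exonic"] <- NA

  ## population frequencies: value = founder freq x lognormal noise
  freq <- matrix(NA_real_, nt, length(MAF_SOURCES),
                 dimnames = list(NULL, MAF_SOURCES))
  for (j in seq_along(MAF_SOURCES)) {
    present <- ifelse(is_common, runif(nt) < 0.95,
                      runif(nt) < cfg$db_presence_rare)
    val <- pmin(founder_freq * exp(rnorm(nt, 0, 0.2)), 0.5)
    freq[, j] <- ifelse(present & cls != "planted", val, NA_real_)
  }

  ## predictors
  rate <- cfg$predictor_damaging_rate
  dmg <- matrix(runif(nt * 4) < rate, nt, 4,
                dimnames = list(NULL, c("sift", "polyphen", "mt", "cadd")))
  sift <- ifelse(dmg[, "sift"], "damaging", "tolerated")
  polyphen <- ifelse(dmg[, "polyphen"],
                     sample(c("probably_damaging", "possibly_damaging"), nt,
                            replace = TRUE), "benign")
  mt <- ifelse(dmg[, "mt"], "disease_causing", "polymorphism")
  cadd <- ifelse(dmg[, "cadd"], runif(nt, 20, 40), runif(nt, 0.1, 19.5))
  # availability by class: missense/synonymous variants carry all four
  # tools; indels and splicing carry MutationTaster + CADD; intronic none
  has_sp <- cls %in% c("missense", "synonymous")
  has_mc <- has_sp | nfs | cls == "splicing"
  sift[!has_sp] <- NA; polyphen[!has_sp] <- NA
  mt[!has_mc] <- NA; cadd[!has_mc] <- NA
  sift[planted_i] <- NA; polyphen[planted_i] <- NA; mt[planted_i] <- NA
  cadd[planted_i] <- 35

  ## site-quality metrics
  depth <- 5 + rpois(nt, 30)
  mq <- runif(nt, 40, 60)
  qual <- runif(nt, 50, 1000)
  lowq <- rep(FALSE, nt)
  if (n > 0) {
    bg <- which(cls != "planted")
    lowq[bg] <- runif(n) < cfg$fraction_low_quality
    which_metric <- sample(1:3, nt, replace = TRUE)
    depth[lowq & which_metric == 1] <- sample(0:4, sum(lowq & which_metric == 1),
                                              replace = TRUE)
    mq[lowq & which_metric == 2] <- runif(sum(lowq & which_metric == 2), 5, 30)
    qual[lowq & which_metric == 3] <- runif(sum(lowq & which_metric == 3),
                                            0.5, 20)
  }

  ## repeat intervals covering the designated repeat-resident indels
  rep_idx <- which(cls == "repeat_nfs")
  intervals <- if (length(rep_idx))
    GenomicRanges::GRanges(chrom[rep_idx],
                           IRanges::IRanges(pmax(pos[rep_idx] - 5L, 1L),
                                            pos[rep_idx] + nchar(ref[rep_idx]) + 5L))
  else GenomicRanges::GRanges()

  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         qual = qual, depth = as.numeric(depth), mq = mq,
                         gene = gene, transcript = transcript,
                         region = region, effect = effect, exon = exon,
                         cdna = cdna, protein = protein,
                         splice_dist = as.numeric(splice_dist),
                         stringsAsFactors = FALSE)
  variants <- cbind(variants, as.data.frame(freq))
  variants$sift <- sift; variants$polyphen <- polyphen
  variants$mutationtaster <- mt; variants$cadd <- cadd
  variants <- variants[, names(empty_variant_frame())]
  ord <- variant_order(variants)
  variants <- variants[ord, ]; rownames(variants) <- NULL
  geno <- geno[ord, , drop = FALSE]
  x <- variant_set(variants, geno)

  truth <- sim_truth_table(variants, geno, cls[ord], lowq[ord], affected,
                           unaffected, cfg)

  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                ped = file.path(out_dir, "family.ped"),
                bed = file.path(out_dir, "repeats.bed"),
                truth_path = file.path(out_dir, "truth.tsv"))
  write_vcf(x, paths$vcf)
  write_ped(ped, paths$ped)
  write_bed(intervals, paths$bed)
  write.table(truth, paths$truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, list(truth = truth, variant_set = x, config = cfg)))
}

# First cascade stage expected to remove each simulated variant, derived
# from the simulator's generative flags (not from the cascade code).
sim_truth_table <- function(v, geno, cls, lowq, affected, unaffected, cfg) {
  nt <- nrow(v)
  freq <- as.matrix(v[MAF_SOURCES])
  fail_quality <- lowq
  fail_rarity <- rowSums(freq >= 0.01, na.rm = TRUE) > 0
  small_nfs <- cls == "repeat_nfs"          # all simulated indels are < 10 bp
  fail_functional <- cls %in% c("synonymous", "intronic") | small_nfs |
    (cls == "splicing" & v$splice_dist > 10)
  calls <- cbind(v$sift == "damaging",
                 v$polyphen %in% c("probably_damaging", "possibly_damaging"),
                 v$mutationtaster == "disease_causing",
                 v$cadd >= 20)
  n_dmg <- rowSums(calls, na.rm = TRUE)
  n_avail <- rowSums(!is.na(calls))
  fail_vote <- cls != "planted" & (n_avail == 0 | n_dmg <= n_avail / 2)
  het_all_aff <- rowSums(geno[, affected, drop = FALSE] == 1) == length(affected)
  ref_all_unaff <- rowSums(geno[, unaffected, drop = FALSE] == 0) ==
    length(unaffected)
  fail_seg <- !(het_all_aff & ref_all_unaff)
  stage <- rep("pass", nt)
  for (i in rev(seq_along(CASCADE_STAGES))) {
    fail <- switch(CASCADE_STAGES[i],
                   site_quality = fail_quality, rarity = fail_rarity,
                   functional_class = fail_functional,
                   predictor_vote = fail_vote, segregation = fail_seg)
    stage[fail] <- CASCADE_STAGES[i]
  }
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             label = ifelse(cls == "planted", "planted", "background"),
             class = cls, expected_stage = stage, stringsAsFactors = FALSE)
}

#' Simulate a SNP panel for a known relationship
#'
#' Generates `n_snps` independent biallelic SNPs with alt-allele
#' frequencies drawn Uniform(0.1, 0.5) and gene-drops a minimal pedigree
#' realizing the requested relationship, returning the genotype vectors
#' of the focal pair. Used to validate the IBD estimator against known
#' truth (expected PI_HAT: 0.5 for parent-offspring and full sibs, 0 for
#' unrelated, 1 for duplicates).
#'
#' @param relationship one of `"parent_offspring"`, `"full_sibs"`,
#'   `"unrelated"`, `"duplicate"`.
#' @param n_snps number of SNPs.
#' @return List with `freq` and `geno` (n_snps x 2 dosage matrix, columns
#'   `A` and `B`).
#' @export
simulate_snp_panel <- function(relationship = c("parent_offspring",
                                                "full_sibs", "unrelated",
                                                "duplicate"),
                               n_snps = 20000L) {
  relationship <- match.arg(relationship)
  stopifnot(n_snps >= 1)
  freq <- runif(n_snps, 0.1, 0.5)
  ped <- validate_pedigree(data.frame(
    fam = "P", id = c("F1", "F2", "C1", "C2"),
    father = c(NA, NA, "F1", "F1"), mother = c(NA, NA, "F2", "F2"),
    sex = c("male", "female", "unknown", "unknown"),
    phenotype = "unknown", stringsAsFactors = FALSE))
  d <- gene_drop(ped, freq)$dosage
  pair <- switch(relationship,
                 parent_offspring = c("F1", "C1"),
                 full_sibs = c("C1", "C2"),
                 unrelated = c("F1", "F2"),
                 duplicate = c("F1", "F1"))
  geno <- d[, pair, drop = FALSE]
  colnames(geno) <- c("A", "B")
  list(freq = freq, geno = geno, relationship = relationship)
}
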