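#' Site-quality filter
#'
#' A variant passes when read depth, RMS mapping quality and the variant
#' quality score all exceed their thresholds (strict inequalities). A
#' missing metric fails the stage by default (fail-closed) with a
#' warning; set `missing_metric_fails_quality = FALSE` in the config to
#' ignore absent metrics instead.
#'
#' @param x a [variant_set()].
#' @param cfg a [filter_config()].
#' @return Logical vector, one element per variant.
#' @export
pass_site_quality <- function(x, cfg = filter_config()) {
  v <- x$variants
  if (!nrow(v)) return(logical())
  metric_ok <- function(val, thr) {
    ok <- val > thr
    if (any(is.na(ok))) {
      if (cfg$missing_metric_fails_quality) {
        warning(sum(is.na(ok)), " variant(s) with a missing site metric ",
                "failed the quality stage (fail-closed)", call. = FALSE)
        ok[is.na(ok)] <- FALSE
      } else ok[is.na(ok)] <- TRUE
    }
    ok
  }
  metric_ok(v$depth, cfg$min_depth) &
    metric_ok(v$mq, cfg$min_mq) &
    metric_ok(v$qual, cfg$min_qual)
}

#' Population-rarity filter
#'
#' A variant is rare when every *available* population-frequency source
#' reports a MAF strictly below the threshold. A variant absent from all
#' sources counts as rare by default (novel implies rare).
#'
#' @inheritParams pass_site_quality
#' @return Logical vector, one element per variant.
#' @export
is_rare <- function(x, cfg = filter_config()) {
  v <- x$variants
  if (!nrow(v)) return(logical())
  freq <- as.matrix(v[MAF_SOURCES])
  any_common <- rowSums(freq >= cfg$maf_threshold, na.rm = TRUE) > 0
  all_absent <- rowSums(!is.na(freq)) == 0
  ifelse(all_absent, cfg$missing_frequency_is_rare, !any_common)
}

#' Functional-class filter
#'
#' Retains nonsynonymous SNVs and indels in exons or within the splice
#' window of an exon boundary; discards synonymous SNVs, and discards
#' small (< 10 bp by default) nonframeshift indels lying in
#' repeat-masked intervals. Variants without annotation are filtered out
#' with a warning.
#'
#' @inheritParams pass_site_quality
#' @param repeats repeat intervals from [read_bed()] (may be `NULL` /
#'   empty).
#' @return Logical vector, one element per variant.
#' @export
pass_functional_class <- function(x, repeats = NULL, cfg = filter_config()) {
  v <- x$variants
  if (!nrow(v)) return(logical())
  no_ann <- is.na(v$region)
  if (any(no_ann))
    warning(sum(no_ann), " variant(s) without annotation were filtered out",
            call. = FALSE)
  in_scope <- v$region %in% "exonic" |
    (v$region %in% "splicing" &
       !is.na(v$splice_dist) & v$splice_dist <= cfg$splice_window)
  synonymous <- v$effect %in% "synonymous_SNV"
  nfs <- v$effect %in% c("nonframeshift_deletion", "nonframeshift_insertion")
  small <- mapply(indel_length, v$ref, v$alt) < cfg$nonframeshift_repeat_maxlen
  in_rep <- overlaps_repeat(x, repeats)
  repeat_nfs <- nfs & small & in_rep
  !no_ann & in_scope & !synonymous & !repeat_nfs
}

# Per-tool damaging / benign call tables. ANNOVAR single-letter codes are
# accepted alongside the full vocabulary.
SIFT_DAMAGING <- c("damaging", "D")
SIFT_BENIGN <- c("tolerated", "T")
POLYPHEN_DAMAGING <- c("probably_damaging", "possibly_damaging", "D", "P")
POLYPHEN_BENIGN <- c("benign", "B")
MT_DAMAGING <- c("disease_causing", "disease_causing_automatic", "D", "A")
MT_BENIGN <- c("polymorphism", "polymorphism_automatic", "N", "P")

predictor_call_matrix <- function(v, cfg, damaging = TRUE) {
  if (damaging) {
    cbind(sift = v$sift %in% SIFT_DAMAGING,
          polyphen = v$polyphen %in% POLYPHEN_DAMAGING,
          mutationtaster = v$mutationtaster %in% MT_DAMAGING,
          cadd = !is.na(v$cadd) & v$cadd >= cfg$cadd_damaging_min)
  } else {
    cbind(sift = v$sift %in% SIFT_BENIGN,
          polyphen = v$polyphen %in% POLYPHEN_BENIGN,
          mutationtaster = v$mutationtaster %in% MT_BENIGN,
          cadd = !is.na(v$cadd) & v$cadd < cfg$cadd_damaging_min)
  }
}

predictor_available_matrix <- function(v) {
  cbind(sift = !is.na(v$sift), polyphen = !is.na(v$polyphen),
        mutationtaster = !is.na(v$mutationtaster), cadd = !is.na(v$cadd))
}

#' Deleteriousness consensus vote
#'
#' Counts per-tool damaging calls — SIFT `damaging`; PolyPhen-2
#' `probably_damaging` or `possibly_damaging`; MutationTaster
#' `disease_causing(_automatic)`; CADD phred at or above the configured
#' cutoff (20 by default) — and retains a variant when damaging calls
#' exceed half of the *available* tools, so 3/4 passes, 2/4 fails, and
#' 2/2 passes. Truncating variants (frameshift, stopgain) bypass the vote
#' by default since SIFT/PolyPhen are undefined for them. A
#' non-truncating variant with no available predictor fails, with a
#' warning.
#'
#' @inheritParams pass_site_quality
#' @return Logical vector, one element per variant.
#' @export
predictor_vote <- function(x, cfg = filter_config()) {
  v <- x$variants
  if (!nrow(v)) return(logical())
  damaging <- rowSums(predictor_call_matrix(v, cfg, damaging = TRUE))
  available <- rowSums(predictor_available_matrix(v))
  truncating <- v$effect %in% TRUNCATING_EFFECTS
  none <- available == 0 & !truncating
  if (any(none))
    warning(sum(none), " non-truncating variant(s) with no available ",
            "predictor failed the consensus vote", call. = FALSE)
  out <- available > 0 & damaging > available / 2
  if (cfg$truncating_bypass_vote) out[truncating] <- TRUE
  out
}

#' Dominant co-segregation test
#'
#' Under the fully penetrant autosomal dominant model a candidate must be
#' heterozygous in every affected member and homozygous reference in
#' every unaffected member; unknown-phenotype members are ignored.
#' Homozygous-alternate affected members fail (the model requires
#' heterozygosity), and by default a missing genotype among phenotyped
#' members fails the test.
#'
#' @inheritParams pass_site_quality
#' @param ped a pedigree from [read_ped()]; every phenotyped member must
#'   be a sample of `x`.
#' @return Logical vector, one element per variant.
#' @export
segregates_dominant <- function(x, ped, cfg = filter_config()) {
  affected <- ped$id[ped$phenotype == "affected"]
  unaffected <- ped$id[ped$phenotype == "unaffected"]
  missing_ids <- setdiff(c(affected, unaffected), x$samples)
  if (length(missing_ids))
    stop("pedigree member(s) absent from the VCF samples: ",
         paste(missing_ids, collapse = ", "))
  if (!n_variants(x)) return(logical())
  ga <- x$geno[, affected, drop = FALSE]
  gu <- x$geno[, unaffected, drop = FALSE]
  ok_aff <- rowSums(ga == 1, na.rm = TRUE) +
    (if (cfg$missing_genotype_fails_segregation) 0 else rowSums(is.na(ga)))
  ok_unaff <- rowSums(gu == 0, na.rm = TRUE) +
    (if (cfg$missing_genotype_fails_segregation) 0 else rowSums(is.na(gu)))
  ok_aff == length(affected) & ok_unaff == length(unaffected)
}
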