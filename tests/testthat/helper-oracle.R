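# Independent brute-force oracle: re-reads the cohort files with its own
# minimal parsing and applies the published filtering rules per variant,
# sharing no code with the package implementation.

oracle_candidates <- function(vcf_path, ped_path, bed_path) {
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)[1]
  samples <- strsplit(lines[hdr], "\t")[[1]][-(1:9)]
  ped <- read.table(ped_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  affected <- ped[[2]][ped[[6]] == "2"]
  unaffected <- ped[[2]][ped[[6]] == "1"]
  bed <- tryCatch(read.table(bed_path, stringsAsFactors = FALSE),
                  error = function(e) NULL)

  keep <- character()
  for (ln in lines[-seq_len(hdr)]) {
    f <- strsplit(ln, "\t")[[1]]
    chrom <- f[1]; pos <- as.numeric(f[2]); ref <- f[4]; alt <- f[5]
    qual <- as.numeric(f[6])
    info <- strsplit(f[8], ";")[[1]]
    kv <- sub("^[^=]*=", "", info)
    names(kv) <- sub("=.*$", "", info)
    g <- function(k) if (k %in% names(kv)) kv[[k]] else NA
    num <- function(k) suppressWarnings(as.numeric(g(k)))

    # quality: depth > 4, RMS MQ > 30, variant quality > 20 (all strict)
    if (!isTRUE(num("DP") > 4 && num("MQ") > 30 && qual > 20)) next

    # rarity: every available source MAF < 0.01 (novel counts as rare)
    mafs <- c(num("1000g2015aug_all"), num("esp6500siv2_all"),
              num("gnomAD_ALL"), num("gnomAD_EAS"), num("inhouse_AF"))
    if (any(mafs >= 0.01, na.rm = TRUE)) next

    # functional class
    region <- g("Func.refGene"); effect <- g("ExonicFunc.refGene")
    sdist <- num("SpliceDist")
    in_scope <- identical(region, "exonic") ||
      (identical(region, "splicing") && isTRUE(sdist <= 10))
    if (!in_scope) next
    if (identical(effect, "synonymous_SNV")) next
    if (identical(effect, "nonframeshift_deletion") ||
        identical(effect, "nonframeshift_insertion")) {
      len <- abs(nchar(ref) - nchar(alt))
      span <- c(pos, pos + nchar(ref) - 1)
      in_rep <- !is.null(bed) && any(bed[[1]] == chrom &
                                       bed[[2]] + 1 <= span[2] &
                                       bed[[3]] >= span[1])
      if (len < 10 && in_rep) next
    }

    # consensus vote (truncating effects bypass)
    truncating <- effect %in% c("frameshift_deletion",
                                "frameshift_insertion", "stopgain")
    if (!truncating) {
      calls <- c(if (!is.na(g("SIFT_pred"))) g("SIFT_pred") == "damaging",
                 if (!is.na(g("Polyphen2_HDIV_pred")))
                   g("Polyphen2_HDIV_pred") %in% c("probably_damaging",
                                                   "possibly_damaging"),
                 if (!is.na(g("MutationTaster_pred")))
                   g("MutationTaster_pred") %in% c("disease_causing",
                                                   "disease_causing_automatic"),
                 if (!is.na(num("CADD_phred"))) num("CADD_phred") >= 20)
      if (length(calls) == 0 || sum(calls) <= length(calls) / 2) next
    }

    # dominant segregation: het in every affected, hom-ref in every
    # unaffected, no missing genotypes among phenotyped members
    gts <- f[-(1:9)]
    names(gts) <- samples
    if (!all(gts[affected] %in% c("0/1", "1/0"))) next
    if (!all(gts[unaffected] == "0/0")) next

    keep <- c(keep, paste(chrom, pos, ref, alt, sep = ":"))
  }
  keep
}

variant_keys <- function(x) {
  v <- if (inherits(x, "variant_set")) x$variants else x
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

# Independent hand application of the ACMG/AMP combining table for the
# criteria sets exercised in tests (frozen expected classes).
acmg_hand_table <- list(
  list(crit = c("PVS1", "PM2", "PP1"), class = "pathogenic"),
  list(crit = c("PVS1", "PP1", "PP3"), class = "pathogenic"),
  list(crit = c("PVS1", "PM2"), class = "likely_pathogenic"),
  list(crit = c("PVS1"), class = "uncertain_significance"),
  list(crit = c("PM2", "PP1", "PP3"), class = "uncertain_significance"),
  list(crit = character(), class = "uncertain_significance"),
  list(crit = c("BA1"), class = "benign"),
  list(crit = c("PVS1", "PM2", "PP1", "BA1"), class = "benign"),
  list(crit = c("BS1", "BP4"), class = "likely_benign"),
  list(crit = c("BP4"), class = "uncertain_significance"),
  list(crit = c("PVS1", "PM2", "BS1", "BP4"), class = "uncertain_significance"))
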