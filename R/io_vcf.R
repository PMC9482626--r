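#' Read an annotated multi-sample VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [variant_set()].
#' Multiallelic records are split into one row per ALT allele, with
#' genotypes recoded so that dosage counts the focal ALT only (other ALT
#' alleles at the same site count as non-focal). ANNOVAR-style annotation
#' is read from the INFO keys `Gene.refGene`, `Func.refGene`,
#' `ExonicFunc.refGene`, `AAChange.refGene`, the population-frequency keys
#' (`1000g2015aug_all`, `esp6500siv2_all`, `gnomAD_ALL`, `gnomAD_EAS`,
#' `inhouse_AF`), the predictor keys (`SIFT_pred`, `Polyphen2_HDIV_pred`,
#' `MutationTaster_pred`, `CADD_phred`) and the site metrics `MQ` and `DP`.
#' Missing keys or `.` values yield `NA` fields — never fabricated
#' defaults.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @return A [variant_set()] with one row per site x ALT.
#' @details Genotypes with any missing allele (`./.` or half-calls such as
#'   `./1`) are treated as missing. Multiallelic INFO values are applied
#'   unchanged to every split record; per-allele INFO splitting is an
#'   upstream (annotation) concern.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  validate_vcf_columns(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n <- nrow(fix)
  samples <- colnames(vcf@gt)[-1] %||% character()
  out <- empty_variant_frame()
  if (n == 0) return(variant_set(out, matrix(integer(), 0, length(samples),
                                             dimnames = list(NULL, samples))))

  gt_raw <- if (length(samples)) vcfR::extract.gt(vcf, element = "GT") else
    matrix(character(), n, 0)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) stop("non-numeric POS in VCF record ", which(is.na(pos))[1])

  # expand one row per site x ALT
  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alts <- lengths(alt_split)
  idx <- rep.int(seq_len(n), n_alts)      # source record of each output row
  alt_k <- sequence(n_alts)               # focal ALT index within its record

  ann <- info_columns(fix[, "INFO"], n)
  variants <- data.frame(chrom = fix[idx, "CHROM"], pos = pos[idx],
                         ref = fix[idx, "REF"], alt = unlist(alt_split),
                         qual = suppressWarnings(as.numeric(fix[idx, "QUAL"])),
                         stringsAsFactors = FALSE)
  variants <- cbind(variants, ann[idx, , drop = FALSE])
  rownames(variants) <- NULL

  # genotypes: decode the few distinct GT strings once, then recode the
  # dosage per output row as the count of the focal ALT allele
  if (length(samples)) {
    u <- unique(as.vector(gt_raw))
    dec <- vapply(u, function(g) {
      if (is.na(g)) return(c(NA_integer_, NA_integer_))
      a <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
      if (length(a) != 2) return(c(NA_integer_, NA_integer_))
      v <- suppressWarnings(as.integer(a))
      if (anyNA(v)) c(NA_integer_, NA_integer_) else v
    }, integer(2))
    m <- match(gt_raw, u)
    a1 <- matrix(dec[1, m], n, length(samples))
    a2 <- matrix(dec[2, m], n, length(samples))
    kmat <- matrix(alt_k, length(idx), length(samples))
    geno <- (a1[idx, , drop = FALSE] == kmat) +
      (a2[idx, , drop = FALSE] == kmat)
    mode(geno) <- "integer"
  } else {
    geno <- matrix(integer(), length(idx), 0)
  }
  colnames(geno) <- samples
  variant_set(variants[, names(out)], geno)
}

# Structural pre-scan: every data line must have a column count consistent
# with the header; errors name the offending 1-based line number.
validate_vcf_columns <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stop("VCF has no #CHROM header line: ", path)
  hdr <- hdr[1]
  ncols <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  for (ln in seq.int(hdr + 1L, length.out = length(lines) - hdr)) {
    if (!nzchar(lines[ln])) next
    got <- length(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (got != ncols)
      stop(sprintf("malformed VCF line %d: %d fields, header declares %d",
                   ln, got, ncols))
  }
  invisible(TRUE)
}

# Vectorized extraction of the annotation columns from raw INFO strings:
# one flat (record, key, value) table, then one pass per wanted key.
info_columns <- function(info, n) {
  info[is.na(info) | info == "."] <- ""
  parts <- strsplit(info, ";", fixed = TRUE)
  rec <- rep.int(seq_len(n), lengths(parts))
  kv <- unlist(parts)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  getcol <- function(key) {
    col <- rep(NA_character_, n)
    sel <- keys == key
    col[rec[sel]] <- vals[sel]
    col[!is.na(col) & col == "."] <- NA
    col
  }
  num <- function(key) suppressWarnings(as.numeric(getcol(key)))
  extract_re <- function(x, pattern) {
    x[is.na(x)] <- ""
    m <- regexpr(pattern, x)
    out <- rep(NA_character_, length(x))
    out[m > 0] <- regmatches(x, m)
    out
  }
  # ANNOVAR AAChange "GENE:NM_x:exonN:c.x:p.x[,...]" — first transcript kept
  aac <- sub(",.*$", "", getcol(INFO_KEYS[["aachange"]]))
  data.frame(depth = num(INFO_KEYS[["depth"]]),
             mq = num(INFO_KEYS[["mq"]]),
             gene = getcol(INFO_KEYS[["gene"]]),
             transcript = extract_re(aac, "(NM|NR|XM)_[0-9]+"),
             region = getcol(INFO_KEYS[["region"]]),
             effect = getcol(INFO_KEYS[["effect"]]),
             exon = as.integer(sub("exon", "",
                                   extract_re(aac, "exon[0-9]+"))),
             cdna = extract_re(aac, "c\\.[^:]+"),
             protein = extract_re(aac, "p\\.[^:]+"),
             splice_dist = num(INFO_KEYS[["splice_dist"]]),
             maf_1000g = num(INFO_KEYS[["maf_1000g"]]),
             maf_esp6500 = num(INFO_KEYS[["maf_esp6500"]]),
             maf_gnomad_all = num(INFO_KEYS[["maf_gnomad_all"]]),
             maf_gnomad_eas = num(INFO_KEYS[["maf_gnomad_eas"]]),
             maf_inhouse = num(INFO_KEYS[["maf_inhouse"]]),
             sift = getcol(INFO_KEYS[["sift"]]),
             polyphen = getcol(INFO_KEYS[["polyphen"]]),
             mutationtaster = getcol(INFO_KEYS[["mutationtaster"]]),
             cadd = num(INFO_KEYS[["cadd"]]),
             stringsAsFactors = FALSE)
}

#' Write a variant set as VCF 4.2
#'
#' Emits a minimal annotated VCF that [read_vcf()] parses back losslessly
#' (one biallelic record per row; annotation as ANNOVAR-style INFO keys;
#' genotypes as unphased GT).
#'
#' @param x a [variant_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_set"))
  v <- x$variants
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=pedprio-%s", as.character(packageVersion("pedprio"))),
           '##INFO=<ID=DP,Number=1,Type=Float,Description="Total read depth">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##INFO=<ID=Gene.refGene,Number=1,Type=String,Description="Gene symbol">',
           '##INFO=<ID=Func.refGene,Number=1,Type=String,Description="Genomic region">',
           '##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description="Exonic effect">',
           '##INFO=<ID=AAChange.refGene,Number=1,Type=String,Description="Transcript annotation">',
           '##INFO=<ID=SpliceDist,Number=1,Type=Integer,Description="Distance to exon boundary (bp)">',
           '##INFO=<ID=1000g2015aug_all,Number=1,Type=Float,Description="1000 Genomes MAF">',
           '##INFO=<ID=esp6500siv2_all,Number=1,Type=Float,Description="ESP6500 MAF">',
           '##INFO=<ID=gnomAD_ALL,Number=1,Type=Float,Description="gnomAD overall MAF">',
           '##INFO=<ID=gnomAD_EAS,Number=1,Type=Float,Description="gnomAD East Asian MAF">',
           '##INFO=<ID=inhouse_AF,Number=1,Type=Float,Description="In-house database MAF">',
           '##INFO=<ID=SIFT_pred,Number=1,Type=String,Description="SIFT call">',
           '##INFO=<ID=Polyphen2_HDIV_pred,Number=1,Type=String,Description="PolyPhen-2 HDIV call">',
           '##INFO=<ID=MutationTaster_pred,Number=1,Type=String,Description="MutationTaster call">',
           '##INFO=<ID=CADD_phred,Number=1,Type=Float,Description="CADD phred score">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  fmt_num <- function(val) ifelse(is.na(val), NA_character_,
                                  formatC(val, format = "fg", digits = 10))
  info_cols <- c(DP = "depth", MQ = "mq", Gene.refGene = "gene",
                 Func.refGene = "region", ExonicFunc.refGene = "effect",
                 SpliceDist = "splice_dist",
                 `1000g2015aug_all` = "maf_1000g",
                 esp6500siv2_all = "maf_esp6500",
                 gnomAD_ALL = "maf_gnomad_all", gnomAD_EAS = "maf_gnomad_eas",
                 inhouse_AF = "maf_inhouse", SIFT_pred = "sift",
                 Polyphen2_HDIV_pred = "polyphen",
                 MutationTaster_pred = "mutationtaster", CADD_phred = "cadd")
  lines <- vapply(seq_len(nrow(v)), function(i) {
    kv <- character()
    for (key in names(info_cols)) {
      val <- v[[info_cols[[key]]]][i]
      if (is.numeric(val)) val <- fmt_num(val)
      if (!is.na(val)) kv <- c(kv, paste0(key, "=", val))
    }
    if (!is.na(v$transcript[i])) {
      aac <- paste(c(v$gene[i],
                     v$transcript[i],
                     if (!is.na(v$exon[i])) paste0("exon", v$exon[i]),
                     if (!is.na(v$cdna[i])) v$cdna[i],
                     if (!is.na(v$protein[i])) v$protein[i]),
                   collapse = ":")
      kv <- c(kv, paste0("AAChange.refGene=", aac))
    }
    gt <- c("0/0", "0/1", "1/1")[x$geno[i, ] + 1L]
    gt[is.na(gt)] <- "./."
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i],
            fmt_num(v$qual[i]), "PASS",
            if (length(kv)) paste(kv, collapse = ";") else ".",
            "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}
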