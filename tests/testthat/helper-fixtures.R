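# Small in-code fixtures used across test files.

mini_vcf_lines <- function(records, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

write_mini_vcf <- function(records, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(mini_vcf_lines(records, samples), path)
  path
}

vcf_record <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                       qual = 50, info = "DP=20;MQ=45", gts = c("0/1", "0/0")) {
  paste(c(chrom, pos, ".", ref, alt, qual, ".", info, "GT", gts),
        collapse = "\t")
}

# A one-row variant_set with every annotation field settable; defaults
# describe a clean rare damaging exonic missense.
one_variant <- function(chrom = "chr1", pos = 1000, ref = "A", alt = "G",
                        qual = 100, depth = 30, mq = 50,
                        region = "exonic", effect = "nonsynonymous_SNV",
                        splice_dist = NA,
                        maf_1000g = NA, maf_esp6500 = NA,
                        maf_gnomad_all = NA, maf_gnomad_eas = NA,
                        maf_inhouse = NA,
                        sift = "damaging", polyphen = "probably_damaging",
                        mutationtaster = "disease_causing", cadd = 25,
                        geno = c(GF = 1, GM = 0, FA = 1, UN = 0, MO = 0,
                                 DA = 1)) {
  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  qual = qual, depth = depth, mq = mq,
                  gene = "GENE1", transcript = "NM_000001",
                  region = region, effect = effect, exon = 1L,
                  cdna = NA_character_, protein = NA_character_,
                  splice_dist = as.numeric(splice_dist),
                  maf_1000g = as.numeric(maf_1000g),
                  maf_esp6500 = as.numeric(maf_esp6500),
                  maf_gnomad_all = as.numeric(maf_gnomad_all),
                  maf_gnomad_eas = as.numeric(maf_gnomad_eas),
                  maf_inhouse = as.numeric(maf_inhouse),
                  sift = as.character(sift), polyphen = as.character(polyphen),
                  mutationtaster = as.character(mutationtaster),
                  cadd = as.numeric(cadd),
                  stringsAsFactors = FALSE)
  variant_set(v, matrix(as.integer(geno), 1,
                        dimnames = list(NULL, names(geno))))
}

stack_variants <- function(...) {
  sets <- list(...)
  variant_set(do.call(rbind, lapply(sets, function(s) s$variants)),
              do.call(rbind, lapply(sets, function(s) s$geno)))
}
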