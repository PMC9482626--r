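#' Variant-set container
#'
#' A `variant_set` holds one biallelic variant per row after multiallelic
#' splitting: a data frame of site-level fields and annotation, plus a
#' parallel genotype matrix of focal-ALT dosages (0, 1, 2, or `NA` for
#' missing) with one column per sample. Genotypes are unphased: dosage 1
#' covers both 0/1 and 1/0.
#'
#' @param variants data frame with the columns produced by [read_vcf()].
#' @param geno integer matrix, `nrow(variants)` x number of samples, with
#'   entries in `{0, 1, 2, NA}`; column names are sample ids.
#' @return An object of class `variant_set`.
#' @seealso [read_vcf()], [write_vcf()]
#' @export
variant_set <- function(variants, geno) {
  stopifnot(is.data.frame(variants), is.matrix(geno),
            nrow(variants) == nrow(geno))
  if (is.null(colnames(geno)) && ncol(geno) > 0)
    stop("genotype matrix must carry sample ids as column names")
  if (anyDuplicated(colnames(geno)))
    stop("duplicate sample ids in genotype matrix")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based VCF convention)")
  if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt)))
    stop("ref and alt alleles must be nonempty")
  if (any(variants$ref == variants$alt))
    stop("ref and alt must differ")
  structure(list(variants = variants, geno = geno,
                 samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants x %d samples\n",
              nrow(x$variants), length(x$samples)))
  if (length(x$samples))
    cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$variants[i, , drop = FALSE],
              x$geno[i, , drop = FALSE])
}

#' Number of variants in a variant set
#' @param x a `variant_set`.
#' @export
n_variants <- function(x) nrow(x$variants)

# Empty variants data.frame with the canonical column set.
empty_variant_frame <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), depth = numeric(),
             mq = numeric(), gene = character(), transcript = character(),
             region = character(), effect = character(), exon = integer(),
             cdna = character(), protein = character(),
             splice_dist = numeric(),
             maf_1000g = numeric(), maf_esp6500 = numeric(),
             maf_gnomad_all = numeric(), maf_gnomad_eas = numeric(),
             maf_inhouse = numeric(),
             sift = character(), polyphen = character(),
             mutationtaster = character(), cadd = numeric(),
             stringsAsFactors = FALSE)
}

# Chromosome-aware ordering used for every deterministic output.
variant_order <- function(variants) {
  chr <- sub("^chr", "", variants$chrom)
  num <- suppressWarnings(as.integer(chr))
  key <- ifelse(is.na(num), 100L + as.integer(factor(chr)), num)
  order(key, variants$pos, variants$ref, variants$alt)
}
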