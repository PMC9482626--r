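#' Classify a variant as SNV or INDEL from its alleles
#'
#' A variant is an SNV when both alleles are single bases; anything else
#' (length-changing, or an equal-length multi-base substitution) is
#' classified INDEL-side, matching the two-class vocabulary of pedigree
#' candidate tables. Equal-length multi-base substitutions (MNVs) are
#' deliberately not given SNV status so they can never slip through
#' SNV-specific predictor logic.
#'
#' @param ref,alt allele strings (nonempty, different).
#' @return `"SNV"` or `"INDEL"`.
#' @export
classify_variant_type <- function(ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("alleles must be nonempty")
  if (ref == alt) stop("ref and alt must differ")
  if (nchar(ref) == 1 && nchar(alt) == 1) "SNV" else "INDEL"
}

#' Is an indel frameshifting?
#'
#' True when the length difference between the alleles is not a multiple
#' of 3, so the reading frame shifts from the affected codon onward. A
#' 1-bp coding deletion (e.g. a single-base delC) is frameshifting; a 9-bp
#' in-frame deletion is not.
#'
#' @param ref,alt allele strings of an INDEL (per
#'   [classify_variant_type()]).
#' @return Logical.
#' @export
is_frameshift <- function(ref, alt) {
  if (classify_variant_type(ref, alt) != "INDEL")
    stop("is_frameshift() is defined for INDELs only")
  (abs(nchar(ref) - nchar(alt)) %% 3) != 0
}

#' Codon index of a coding-sequence position
#'
#' Maps a 1-based position on the coding sequence (HGVS c. numbering) to
#' the 1-based codon / protein residue index: `floor((pos - 1) / 3) + 1`.
#' This is the arithmetic that links, e.g., a deletion at c.8743 to a
#' frameshift starting at residue 2915, or a substitution at c.983 to
#' residue 328.
#'
#' @param cdna_pos 1-based coding position(s), integer.
#' @return Codon indices, same length as `cdna_pos`.
#' @export
codon_of_cdna_position <- function(cdna_pos) {
  if (any(is.na(cdna_pos)) || any(cdna_pos < 1))
    stop("coding position must be >= 1")
  if (any(cdna_pos != floor(cdna_pos)))
    stop("coding position must be an integer")
  floor((cdna_pos - 1) / 3) + 1
}

#' Indel length (absolute allele-length difference)
#' @param ref,alt allele strings.
#' @return Nonnegative integer.
#' @keywords internal
indel_length <- function(ref, alt) abs(nchar(ref) - nchar(alt))
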