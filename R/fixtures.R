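#' Load the packaged candidate-table worked example
#'
#' A 26-row transcription of a published pedigree-WGS candidate-variant
#' table (gene, mutation type, transcript, exon, coding change, protein
#' change, and whether the gene had prior literature links to the
#' disorder). Only fields printed in the source table are carried;
#' genomic coordinates were not printed, so conversion to a
#' [variant_set()] uses sentinel coordinates and the cascade is run on it
#' in fixture mode.
#'
#' @return Data frame with 26 rows and a `bd_linked` logical column.
#' @export
load_candidate_table <- function() {
  path <- system.file("extdata", "candidate_table.tsv", package = "pedprio")
  tbl <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
  tbl$bd_linked <- tbl$bd_linked == 1
  tbl
}

#' Summarize the candidate-table fixture
#' @param tbl output of [load_candidate_table()].
#' @return List with `records`, `snv`, `indel` and `bd_linked` counts.
#' @export
candidate_table_summary <- function(tbl = load_candidate_table()) {
  list(records = nrow(tbl),
       snv = sum(startsWith(tbl$mutation_type, "SNV")),
       indel = sum(startsWith(tbl$mutation_type, "INDEL")),
       bd_linked = sum(tbl$bd_linked))
}

#' Convert the candidate-table fixture to a variant set
#'
#' Alleles are reconstructed from the printed coding changes where
#' possible (substitutions give the two bases; deletions give a
#' left-anchored indel of the printed length with `N` placeholder
#' context, since the deleted sequence context is not printed) and
#' sentinel coordinates (`chrU`, row order) stand in for the unprinted
#' genomic positions. Quality metrics, population frequencies and
#' predictor scores are absent, which is why the cascade's fixture mode
#' bypasses the stages that need them.
#'
#' @param tbl output of [load_candidate_table()].
#' @return A [variant_set()] with 0 samples.
#' @export
candidate_table_variants <- function(tbl = load_candidate_table()) {
  n <- nrow(tbl)
  ref <- alt <- character(n)
  cdna <- protein <- rep(NA_character_, n)
  effect <- rep("unknown", n)
  for (i in seq_len(n)) {
    cod <- tbl$coding[i]
    m <- regmatches(cod, regexec("^([ACGT])([0-9]+)([ACGT])$", cod))[[1]]
    if (length(m) == 4) {               # substitution, e.g. C2821G
      ref[i] <- m[2]; alt[i] <- m[4]
      cdna[i] <- sprintf("c.%s%s>%s", m[3], m[2], m[4])
    } else if (grepl("del", cod)) {     # deletion, e.g. 8743delC, 2953_2961del
      span <- regmatches(cod, regexec("^([0-9]+)(_([0-9]+))?del", cod))[[1]]
      from <- as.integer(span[2])
      to <- if (nzchar(span[4])) as.integer(span[4]) else from
      len <- to - from + 1L
      ref[i] <- paste0("N", strrep("A", len))
      alt[i] <- "N"
      cdna[i] <- paste0("c.", cod)
    } else {                            # unprinted / unknown
      ref[i] <- "N"; alt[i] <- "A"
    }
    if (!is.na(tbl$protein[i]) && tbl$protein[i] != "unknown")
      protein[i] <- paste0("p.", tbl$protein[i])
    effect[i] <- switch(sub("^(SNV|INDEL)-", "", tbl$mutation_type[i]),
                        missense = "nonsynonymous_SNV",
                        `frameshift deletion` = "frameshift_deletion",
                        `nonframeshift deletion` = "nonframeshift_deletion",
                        "unknown")
  }
  v <- empty_variant_frame()
  v <- rbind(v, data.frame(
    chrom = "chrU", pos = seq_len(n), ref = ref, alt = alt,
    qual = NA_real_, depth = NA_real_, mq = NA_real_,
    gene = tbl$gene, transcript = tbl$transcript, region = "exonic",
    effect = effect, exon = tbl$exon, cdna = cdna, protein = protein,
    splice_dist = NA_real_,
    maf_1000g = NA_real_, maf_esp6500 = NA_real_,
    maf_gnomad_all = NA_real_, maf_gnomad_eas = NA_real_,
    maf_inhouse = NA_real_,
    sift = NA_character_, polyphen = NA_character_,
    mutationtaster = NA_character_, cadd = NA_real_,
    stringsAsFactors = FALSE))
  variant_set(v, matrix(integer(), n, 0))
}

#' Path to the packaged six-member family PED fixture
#' @return File path usable with [read_ped()].
#' @export
fixture_ped_path <- function() {
  system.file("extdata", "family.ped", package = "pedprio")
}
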