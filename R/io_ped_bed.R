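#' Read a PLINK 6-column pedigree file
#'
#' Whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, other = unknown), phenotype
#' (2 = affected, 1 = unaffected, 0 or -9 = unknown). A parent id of 0
#' means missing.
#'
#' @param path path to the PED file.
#' @return A `pedigree` data frame with columns `fam`, `id`, `father`,
#'   `mother` (NA when missing), `sex` and `phenotype` as labels.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 6) stop("PED file must have at least 6 columns")
  ped <- data.frame(fam = raw[[1]], id = raw[[2]],
                    father = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
                    mother = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
                    sex = c("1" = "male", "2" = "female")[raw[[5]]],
                    phenotype = c("2" = "affected", "1" = "unaffected")[raw[[6]]],
                    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$phenotype[is.na(ped$phenotype)] <- "unknown"
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id))
    stop("duplicate sample ids in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad))
      stop("unknown parent id(s) in pedigree: ",
           paste(unique(ref[bad]), collapse = ", "))
  }
  # acyclicity: peel founders repeatedly; leftovers imply a cycle
  placed <- character()
  remaining <- ped$id
  repeat {
    ready <- remaining[vapply(remaining, function(id) {
      r <- ped[ped$id == id, ]
      (is.na(r$father) || r$father %in% placed) &&
        (is.na(r$mother) || r$mother %in% placed)
    }, logical(1))]
    if (!length(ready)) break
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining))
    stop("pedigree contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  attr(ped, "topo_order") <- placed
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members (%d affected, %d unaffected)\n",
              nrow(x), sum(x$phenotype == "affected"),
              sum(x$phenotype == "unaffected")))
  print.data.frame(x)
  invisible(x)
}

#' Write a pedigree back to PLINK 6-column PED format
#' @param ped a `pedigree` from [read_ped()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$fam, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    c(male = "1", female = "2", unknown = "0")[ped$sex],
                    c(affected = "2", unaffected = "1", unknown = "0")[ped$phenotype])
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read repeat-masked intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based closed convention and stored as a `GRanges` for overlap queries.
#' An empty file yields an empty interval set (all overlap queries false).
#'
#' @param path path to a 3+-column BED file.
#' @return A `GRanges` holding the intervals (1-based closed).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
  } else {
    f <- strsplit(lines, "[ \t]+")
    nc <- vapply(f, length, 0L)
    if (any(nc < 3)) stop("BED line ", which(nc < 3)[1], " has fewer than 3 columns")
    start0 <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 2)))
    end0 <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 3)))
    bad <- is.na(start0) | is.na(end0) | start0 >= end0
    if (any(bad))
      stop("invalid BED interval (start >= end or non-numeric) at line ",
           which(bad)[1])
    gr <- GenomicRanges::GRanges(vapply(f, `[[`, "", 1),
                                 IRanges::IRanges(start0 + 1, end0))
  }
  gr
}

#' Write repeat intervals as BED (0-based half-open)
#' @param intervals a `GRanges`, 1-based closed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (!length(intervals)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- data.frame(as.character(GenomicRanges::seqnames(intervals)),
                    GenomicRanges::start(intervals) - 1L,
                    GenomicRanges::end(intervals))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test variants for repeat-region overlap
#'
#' A variant's 1-based reference span `[pos, pos + nchar(ref) - 1]` is
#' intersected with the repeat intervals.
#'
#' @param x a [variant_set()] or a data frame with `chrom`, `pos`, `ref`.
#' @param repeats intervals from [read_bed()] (or any `GRanges`, 1-based).
#' @return Logical vector, one element per variant.
#' @export
overlaps_repeat <- function(x, repeats) {
  v <- if (inherits(x, "variant_set")) x$variants else x
  if (!nrow(v)) return(logical())
  if (is.null(repeats) || !length(repeats)) return(rep(FALSE, nrow(v)))
  spans <- GenomicRanges::GRanges(v$chrom,
                                  IRanges::IRanges(v$pos,
                                                   v$pos + nchar(v$ref) - 1L))
  suppressWarnings(GenomicRanges::countOverlaps(spans, repeats) > 0)
}

#' Write the candidate-variant report
#'
#' One TSV row per candidate, ordered by (chromosome, position), with the
#' columns of a classical pedigree-WGS candidate table: gene, mutation
#' type, transcript, exon, coding change, protein change, plus
#' coordinates, per-source population frequencies and the ACMG class when
#' supplied.
#'
#' @param candidates a [variant_set()] of candidates (annotation required).
#' @param path output path.
#' @param acmg optional data frame from [acmg_classify()] aligned with
#'   `candidates` rows.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path, acmg = NULL) {
  v <- candidates$variants
  if (nrow(v) && any(is.na(v$gene)))
    stop("every candidate must carry annotation (gene symbol missing)")
  ord <- variant_order(v)
  mutation_type <- ifelse(
    vapply(seq_len(nrow(v)),
           function(i) classify_variant_type(v$ref[i], v$alt[i]), "") == "SNV",
    paste0("SNV-", ifelse(v$effect == "nonsynonymous_SNV", "missense",
                          ifelse(is.na(v$effect), "unknown", v$effect))),
    paste0("INDEL-", gsub("_", " ", ifelse(is.na(v$effect), "unknown",
                                           v$effect))))
  rep <- data.frame(gene = v$gene, mutation_type = mutation_type,
                    transcript = v$transcript, exon = v$exon,
                    coding = v$cdna, protein = v$protein,
                    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    v[MAF_SOURCES], stringsAsFactors = FALSE)
  if (!is.null(acmg)) {
    rep$acmg_criteria <- acmg$criteria
    rep$acmg_class <- acmg$class
  }
  rep <- rep[ord, , drop = FALSE]
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
  invisible(path)
}
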