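#' Run the variant-prioritization cascade
#'
#' Applies the five filtering stages in order — site quality, population
#' rarity, functional class, deleteriousness consensus, dominant
#' co-segregation — records a per-stage audit ledger, and annotates every
#' surviving candidate with computable ACMG evidence and class (ACMG
#' annotates, it never filters). Candidates are returned in deterministic
#' (chromosome, position) order.
#'
#' @param vcf a [variant_set()] or path to an annotated multi-sample VCF.
#' @param ped a pedigree from [read_ped()] or a PED path.
#' @param repeats repeat intervals from [read_bed()], a BED path, or
#'   `NULL` for none.
#' @param cfg a [filter_config()] or path to a YAML config.
#' @param fixture logical; when `TRUE`, only the annotation-complete
#'   stages (rarity, functional class) are applied and the stages that
#'   need site metrics, predictor scores or genotypes are passed through
#'   unchanged. Intended for worked-example records transcribed from a
#'   published candidate table, which carry no coordinates, site metrics
#'   or genotypes.
#' @return An object of class `pedprio_result` with elements
#'   `candidates` (a [variant_set()]), `ledger` (stage, n_in, n_out),
#'   `acmg` (criteria and class per candidate) and `config`.
#' @export
run_cascade <- function(vcf, ped = NULL, repeats = NULL,
                        cfg = filter_config(), fixture = FALSE) {
  if (is.character(vcf)) vcf <- read_vcf(vcf)
  if (is.character(ped)) ped <- read_ped(ped)
  if (is.character(repeats)) repeats <- read_bed(repeats)
  if (is.character(cfg)) cfg <- read_filter_config(cfg)
  stopifnot(inherits(vcf, "variant_set"), inherits(cfg, "filter_config"))
  if (!fixture && is.null(ped))
    stop("a pedigree is required unless fixture = TRUE")

  active <- if (fixture) c("rarity", "functional_class") else CASCADE_STAGES
  x <- vcf
  ledger <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), stringsAsFactors = FALSE)
  for (stage in CASCADE_STAGES) {
    n_in <- n_variants(x)
    keep <- if (!(stage %in% active)) rep(TRUE, n_in) else switch(
      stage,
      site_quality = pass_site_quality(x, cfg),
      rarity = is_rare(x, cfg),
      functional_class = pass_functional_class(x, repeats, cfg),
      predictor_vote = predictor_vote(x, cfg),
      segregation = segregates_dominant(x, ped, cfg))
    if (n_in) x <- x[keep]
    ledger <- rbind(ledger,
                    data.frame(stage = stage, n_in = n_in,
                               n_out = n_variants(x)))
  }
  x <- if (n_variants(x)) x[variant_order(x$variants)] else x
  acmg <- acmg_classify(x, segregating = !fixture, cfg)
  structure(list(candidates = x, ledger = ledger, acmg = acmg,
                 config = cfg, n_input = n_variants(vcf),
                 fixture = fixture),
            class = "pedprio_result")
}

#' @export
print.pedprio_result <- function(x, ...) {
  cat("Pedigree-based variant prioritization\n")
  cat(sprintf("  input variants: %d\n", x$n_input))
  for (i in seq_len(nrow(x$ledger)))
    cat(sprintf("  %-18s %6d -> %6d\n", x$ledger$stage[i],
                x$ledger$n_in[i], x$ledger$n_out[i]))
  cat(sprintf("  candidates: %d\n", n_variants(x$candidates)))
  invisible(x)
}

#' @export
summary.pedprio_result <- function(object, ...) {
  v <- object$candidates$variants
  type <- if (nrow(v))
    vapply(seq_len(nrow(v)),
           function(i) classify_variant_type(v$ref[i], v$alt[i]), "")
  else character()
  out <- list(n_input = object$n_input,
              n_candidates = nrow(v),
              n_snv = sum(type == "SNV"),
              n_indel = sum(type == "INDEL"),
              genes = unique(v$gene),
              acmg_classes = table(object$acmg$class),
              ledger = object$ledger)
  class(out) <- "summary.pedprio_result"
  out
}

#' @export
print.summary.pedprio_result <- function(x, ...) {
  cat(sprintf("%d candidate variant(s) from %d input variant(s): %d SNV, %d INDEL\n",
              x$n_candidates, x$n_input, x$n_snv, x$n_indel))
  if (length(x$genes)) cat("genes:", paste(x$genes, collapse = ", "), "\n")
  if (length(x$acmg_classes)) {
    cat("ACMG classes:\n")
    print(x$acmg_classes)
  }
  invisible(x)
}

#' Write the per-stage audit ledger as TSV
#' @param result a `pedprio_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(result, path) {
  write.table(result$ledger, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
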