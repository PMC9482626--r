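#' Filtering-cascade configuration
#'
#' Thresholds and switches for [run_cascade()]. The defaults reproduce the
#' published rule set literally, with strict inequalities as printed:
#' read depth > 4, RMS mapping quality > 30, variant quality > 20, every
#' population MAF < 0.01, splice window 10 bp, and discarding
#' nonframeshift indels shorter than 10 bp that lie in repeat-masked
#' intervals.
#'
#' @param min_depth minimum read depth (strict `>`), reads.
#' @param min_mq minimum RMS mapping quality (strict `>`), phred-like.
#' @param min_qual minimum variant quality score (strict `>`), phred-like.
#' @param maf_threshold population-frequency ceiling (strict `<`) applied
#'   to every available source.
#' @param splice_window bp from an exon boundary within which a splicing
#'   variant is retained.
#' @param nonframeshift_repeat_maxlen nonframeshift indels strictly
#'   shorter than this (bp) are discarded when inside a repeat interval.
#' @param cadd_damaging_min CADD phred score at or above which CADD counts
#'   as a damaging call in the consensus vote.
#' @param pm2_max_af MAF below which (or absent) the ACMG PM2
#'   absent-from-controls criterion fires.
#' @param bs1_min_af MAF above which BS1 (too frequent for the disorder)
#'   fires; BA1 uses `ba1_min_af`.
#' @param ba1_min_af MAF above which BA1 (stand-alone benign) fires.
#' @param missing_frequency_is_rare treat a variant absent from every
#'   frequency source as rare (novel variants pass the rarity stage).
#' @param missing_genotype_fails_segregation a missing genotype among
#'   phenotyped members fails the co-segregation test (conservative).
#' @param missing_metric_fails_quality a missing site metric fails the
#'   quality stage (fail-closed), with a warning.
#' @param truncating_bypass_vote frameshift/stopgain variants pass the
#'   predictor vote unconditionally (SIFT/PolyPhen are undefined for
#'   them).
#' @param inheritance_model only `"dominant"` is implemented.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 4,
                          min_mq = 30,
                          min_qual = 20,
                          maf_threshold = 0.01,
                          splice_window = 10,
                          nonframeshift_repeat_maxlen = 10,
                          cadd_damaging_min = 20,
                          pm2_max_af = 1e-4,
                          bs1_min_af = 0.01,
                          ba1_min_af = 0.05,
                          missing_frequency_is_rare = TRUE,
                          missing_genotype_fails_segregation = TRUE,
                          missing_metric_fails_quality = TRUE,
                          truncating_bypass_vote = TRUE,
                          inheritance_model = "dominant") {
  cfg <- list(min_depth = min_depth, min_mq = min_mq, min_qual = min_qual,
              maf_threshold = maf_threshold, splice_window = splice_window,
              nonframeshift_repeat_maxlen = nonframeshift_repeat_maxlen,
              cadd_damaging_min = cadd_damaging_min,
              pm2_max_af = pm2_max_af, bs1_min_af = bs1_min_af,
              ba1_min_af = ba1_min_af,
              missing_frequency_is_rare = isTRUE(missing_frequency_is_rare),
              missing_genotype_fails_segregation =
                isTRUE(missing_genotype_fails_segregation),
              missing_metric_fails_quality =
                isTRUE(missing_metric_fails_quality),
              truncating_bypass_vote = isTRUE(truncating_bypass_vote),
              inheritance_model = match.arg(inheritance_model, "dominant"))
  num <- c("min_depth", "min_mq", "min_qual", "maf_threshold",
           "splice_window", "nonframeshift_repeat_maxlen",
           "cadd_damaging_min", "pm2_max_af", "bs1_min_af", "ba1_min_af")
  for (f in num) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("config field '", f, "' must be a single nonnegative number")
  }
  if (cfg$maf_threshold <= 0 || cfg$maf_threshold >= 1)
    stop("maf_threshold must lie strictly inside (0, 1)")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (f in names(x)) cat(sprintf("  %-34s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read a filtering configuration from a YAML file
#'
#' Flat key-value YAML whose keys mirror the [filter_config()] argument
#' names exactly; unknown keys are an error, and omitted keys keep their
#' defaults.
#'
#' @param path path to the YAML file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(filter_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(filter_config, vals)
}
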