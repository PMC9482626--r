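#' Run the full prioritization pipeline and write its artifacts
#'
#' End-to-end orchestration: read inputs, run [run_cascade()], and write
#' the candidate report (TSV), the per-stage ledger (TSV) and a JSON run
#' manifest recording input paths, their MD5 digests (taken before
#' processing), the config snapshot, the package version, timestamps and
#' the ledger summary. The manifest is written even when a stage fails,
#' with the error message recorded.
#'
#' @param vcf,ped,repeats,cfg input paths (or in-memory objects; `repeats`
#'   may be `NULL`).
#' @param out_report,out_ledger,out_manifest output paths (`NULL` to
#'   skip an artifact; the manifest defaults next to the report).
#' @return The `pedprio_result`, invisibly.
#' @export
run_pipeline <- function(vcf, ped, repeats = NULL, cfg = filter_config(),
                         out_report = "report.tsv",
                         out_ledger = "ledger.tsv",
                         out_manifest = NULL) {
  if (is.null(out_manifest) && !is.null(out_report))
    out_manifest <- sub("\\.tsv$", "", out_report)
  if (!is.null(out_manifest) && !grepl("\\.json$", out_manifest))
    out_manifest <- paste0(out_manifest, ".manifest.json")
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  digest_of <- function(p) if (is.character(p) && file.exists(p))
    unname(tools::md5sum(p)) else NA_character_
  inputs <- list(vcf = list(path = if (is.character(vcf)) vcf else "<in-memory>",
                            md5 = digest_of(vcf)),
                 ped = list(path = if (is.character(ped)) ped else "<in-memory>",
                            md5 = digest_of(ped)),
                 repeats = list(path = if (is.character(repeats)) repeats else
                   if (is.null(repeats)) "<none>" else "<in-memory>",
                   md5 = digest_of(repeats)))
  if (is.character(cfg)) cfg <- read_filter_config(cfg)
  manifest <- list(tool = "pedprio",
                   version = as.character(packageVersion("pedprio")),
                   started = started, inputs = inputs,
                   config = unclass(cfg))
  write_manifest <- function(extra) {
    if (is.null(out_manifest)) return(invisible())
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(c(manifest, extra), out_manifest,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  res <- tryCatch(
    run_cascade(vcf, ped, repeats, cfg),
    error = function(e) {
      write_manifest(list(status = "failed", error = conditionMessage(e)))
      stop(e)
    })
  if (!is.null(out_report))
    write_report(res$candidates, out_report, acmg = res$acmg)
  if (!is.null(out_ledger)) write_ledger(res, out_ledger)
  write_manifest(list(status = "ok",
                      n_candidates = n_variants(res$candidates),
                      ledger = res$ledger))
  invisible(res)
}
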