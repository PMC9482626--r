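#' Combine ACMG/AMP evidence criteria into a five-tier class
#'
#' Applies the standard ACMG/AMP combining rules to a criteria set drawn
#' from the computable subset `{PVS1, PM2, PP1, PP3, BA1, BS1, BP4}`.
#' BA1 is stand-alone benign and short-circuits. When both a
#' pathogenic-side and a benign-side tier fire, the evidence is
#' contradictory and the class is `uncertain_significance`. The class is
#' a pure function of the criteria set.
#'
#' @param criteria character vector of criterion names (one variant), or
#'   a list of such vectors.
#' @return `"pathogenic"`, `"likely_pathogenic"`,
#'   `"uncertain_significance"`, `"likely_benign"` or `"benign"` (one per
#'   input set).
#' @export
acmg_combine <- function(criteria) {
  if (is.list(criteria))
    return(vapply(criteria, acmg_combine, ""))
  known <- c("PVS1", "PM2", "PP1", "PP3", "BA1", "BS1", "BP4")
  bad <- setdiff(criteria, known)
  if (length(bad)) stop("unsupported ACMG criteria: ",
                        paste(bad, collapse = ", "))
  n_pvs <- sum(criteria == "PVS1")
  n_ps <- 0L                       # no strong criteria in the subset
  n_pm <- sum(criteria == "PM2")
  n_pp <- sum(criteria %in% c("PP1", "PP3"))
  n_ba <- sum(criteria == "BA1")
  n_bs <- sum(criteria == "BS1")
  n_bp <- sum(criteria == "BP4")

  if (n_ba >= 1) return("benign")  # stand-alone

  pathogenic <-
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 || (n_pm == 1 && n_pp >= 1) ||
                      n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps == 1 && (n_pm >= 3 || (n_pm == 2 && n_pp >= 2) ||
                     (n_pm == 1 && n_pp >= 4)))
  likely_pathogenic <-
    (n_pvs == 1 && n_pm == 1) ||
    (n_ps == 1 && n_pm >= 1 && n_pm <= 2) ||
    (n_ps == 1 && n_pp >= 2) ||
    n_pm >= 3 ||
    (n_pm == 2 && n_pp >= 2) ||
    (n_pm == 1 && n_pp >= 4)
  benign <- n_bs >= 2
  likely_benign <- (n_bs == 1 && n_bp >= 1) || n_bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("uncertain_significance")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "uncertain_significance"
}

#' Assign computable ACMG criteria and classify variants
#'
#' Evaluates the criteria that are computable from annotation and
#' co-segregation alone:
#' \describe{
#'   \item{PVS1}{null variant: frameshift or stopgain effect.}
#'   \item{PM2}{absent from all population sources, or every available
#'     MAF below `pm2_max_af` (1e-4 by default).}
#'   \item{PP1}{co-segregates with the phenotype in the pedigree.}
#'   \item{PP3}{consensus deleteriousness vote passes on a missense.}
#'   \item{BA1}{any source MAF above `ba1_min_af` (0.05); stand-alone
#'     benign.}
#'   \item{BS1}{any source MAF above `bs1_min_af` (0.01).}
#'   \item{BP4}{at least one predictor available and all available
#'     predictors benign.}
#' }
#' Classification annotates candidates; it is never used as a filter
#' stage.
#'
#' @param x a [variant_set()] with annotation.
#' @param segregating logical vector (one per variant): does the variant
#'   co-segregate with affection under the dominant model?
#' @param cfg a [filter_config()].
#' @return Data frame with `criteria` (comma-joined string) and `class`.
#' @export
acmg_classify <- function(x, segregating, cfg = filter_config()) {
  v <- x$variants
  n <- nrow(v)
  if (length(segregating) == 1) segregating <- rep(segregating, n)
  stopifnot(length(segregating) == n)
  if (!n) return(data.frame(criteria = character(), class = character()))
  freq <- as.matrix(v[MAF_SOURCES])
  pvs1 <- v$effect %in% TRUNCATING_EFFECTS
  pm2 <- rowSums(freq >= cfg$pm2_max_af, na.rm = TRUE) == 0
  pp1 <- as.logical(segregating)
  missense <- v$effect %in% "nonsynonymous_SNV"
  vote <- suppressWarnings(predictor_vote(x, cfg))
  pp3 <- missense & vote
  ba1 <- rowSums(freq > cfg$ba1_min_af, na.rm = TRUE) > 0
  bs1 <- rowSums(freq > cfg$bs1_min_af, na.rm = TRUE) > 0
  avail <- rowSums(predictor_available_matrix(v))
  benign_calls <- rowSums(predictor_call_matrix(v, cfg, damaging = FALSE))
  bp4 <- avail > 0 & benign_calls == avail
  crit <- lapply(seq_len(n), function(i)
    c("PVS1", "PM2", "PP1", "PP3", "BA1", "BS1", "BP4")[
      c(pvs1[i], pm2[i], pp1[i], pp3[i], ba1[i], bs1[i], bp4[i])])
  data.frame(criteria = vapply(crit, paste, "", collapse = ","),
             class = acmg_combine(crit),
             stringsAsFactors = FALSE)
}
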