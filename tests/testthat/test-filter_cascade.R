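cfg <- filter_config()

test_that("site-quality thresholds are strict as published", {
  q <- function(depth, mq, qual)
    pass_site_quality(one_variant(depth = depth, mq = mq, qual = qual), cfg)
  expect_true(q(5, 31, 21))     # just above every threshold
  expect_false(q(4, 60, 99))    # depth must exceed 4
  expect_false(q(100, 30, 50))  # MQ must exceed 30
  expect_false(q(100, 60, 20))  # qual must exceed 20
})

test_that("missing site metrics fail closed by default, configurably open", {
  x <- one_variant(depth = NA)
  expect_warning(res <- pass_site_quality(x, cfg), "missing site metric")
  expect_false(res)
  open <- filter_config(missing_metric_fails_quality = FALSE)
  expect_true(pass_site_quality(x, open))
})

test_that("rarity requires every available source below the threshold", {
  expect_true(is_rare(one_variant(maf_1000g = 0.001, maf_esp6500 = 5e-4,
                                  maf_gnomad_all = 0.002,
                                  maf_gnomad_eas = 0.003), cfg))
  expect_false(is_rare(one_variant(maf_1000g = 0.001,
                                   maf_gnomad_all = 0.02), cfg))
  expect_true(is_rare(one_variant(), cfg))          # novel -> rare
  expect_false(is_rare(one_variant(),
                       filter_config(missing_frequency_is_rare = FALSE)))
  expect_false(is_rare(one_variant(maf_inhouse = 0.01), cfg))  # strict <
})

test_that("functional-class filter implements the published rules", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t900\t1100", bed)
  rep_iv <- read_bed(bed)
  f <- function(x, r = NULL) pass_functional_class(x, r, cfg)
  expect_true(f(one_variant()))
  expect_false(f(one_variant(effect = "synonymous_SNV")))
  expect_false(f(one_variant(region = "intronic", effect = NA)))
  expect_true(f(one_variant(region = "splicing", effect = NA, splice_dist = 10)))
  expect_false(f(one_variant(region = "splicing", effect = NA, splice_dist = 11)))
  # 9-bp nonframeshift deletion: discarded inside a repeat, kept outside
  nfs <- function(pos) one_variant(pos = pos, ref = paste0("T", strrep("A", 9)),
                                   alt = "T", effect = "nonframeshift_deletion")
  expect_false(f(nfs(1000), rep_iv))
  expect_true(f(nfs(5000), rep_iv))
  # a frameshift deletion in a repeat region is NOT discarded
  expect_true(f(one_variant(pos = 1000, ref = "TA", alt = "T",
                            effect = "frameshift_deletion"), rep_iv))
  # 10-bp+ nonframeshift deletions survive even in repeats (strict < 10)
  big <- one_variant(pos = 1000, ref = paste0("T", strrep("A", 12)), alt = "T",
                     effect = "nonframeshift_deletion")
  expect_true(f(big, rep_iv))
  expect_warning(res <- f(one_variant(region = NA, effect = NA)),
                 "without annotation")
  expect_false(res)
})

test_that("consensus vote needs damaging calls from more than half the available tools", {
  v <- function(...) predictor_vote(one_variant(...), cfg)
  expect_true(v())                                   # 4/4 damaging
  expect_true(v(cadd = 5))                           # 3/4
  expect_false(v(cadd = 5, sift = "tolerated"))      # 2/4
  expect_true(v(sift = NA, polyphen = NA))           # 2/2
  expect_false(v(sift = NA, polyphen = NA, cadd = 5))  # 1/2
  expect_true(v(polyphen = "possibly_damaging"))     # possibly counts damaging
  expect_true(v(cadd = 20, polyphen = "benign"))     # cadd = 20 counts (>=), 3/4
  expect_false(v(cadd = 19.9, sift = "tolerated", polyphen = "benign",
                 mutationtaster = "disease_causing_automatic"))  # 1/4
})

test_that("truncating variants bypass the vote; unscored non-truncating fail", {
  fs <- one_variant(ref = "TA", alt = "T", effect = "frameshift_deletion",
                    sift = NA, polyphen = NA, mutationtaster = NA, cadd = NA)
  expect_true(predictor_vote(fs, cfg))
  expect_false(predictor_vote(fs, filter_config(truncating_bypass_vote = FALSE,
                                                missing_metric_fails_quality = TRUE)))
  ns <- one_variant(sift = NA, polyphen = NA, mutationtaster = NA, cadd = NA)
  expect_warning(res <- predictor_vote(ns, cfg), "no available")
  expect_false(res)
})

test_that("dominant segregation demands het affected and hom-ref unaffected", {
  ped <- read_ped(fixture_ped_path())
  seg <- function(geno) segregates_dominant(
    one_variant(geno = geno), ped, cfg)
  good <- c(GF = 1, GM = 0, FA = 1, UN = 0, MO = 0, DA = 1)
  expect_true(seg(good))
  expect_false(seg(replace(good, "GF", 0)))   # an affected without the allele
  expect_false(seg(replace(good, "GF", 2)))   # hom-alt is not heterozygous
  expect_false(seg(replace(good, "UN", 1)))   # carrier unaffected
  expect_false(seg(replace(good, "MO", NA)))  # missing fails by default
  tol <- filter_config(missing_genotype_fails_segregation = FALSE)
  expect_true(segregates_dominant(one_variant(geno = replace(good, "MO", NA)),
                                  ped, tol))
  expect_error(segregates_dominant(
    variant_set(one_variant()$variants,
                matrix(1L, 1, 1, dimnames = list(NULL, "GF"))), ped, cfg),
    "absent from the VCF")
})

test_that("ACMG classes match hand application of the combining table", {
  for (case in acmg_hand_table)
    expect_equal(acmg_combine(case$crit), case$class, label = paste(
      "criteria:", paste(case$crit, collapse = "+")))
})

test_that("ACMG class is a pure function over every criteria subset", {
  crit <- c("PVS1", "PM2", "PP1", "PP3", "BA1", "BS1", "BP4")
  tiers <- c("pathogenic", "likely_pathogenic", "uncertain_significance",
             "likely_benign", "benign")
  for (mask in 0:(2^7 - 1)) {
    set <- crit[bitwAnd(mask, 2^(0:6)) > 0]
    cls1 <- acmg_combine(set)
    cls2 <- acmg_combine(sample(set))        # order-invariant
    expect_identical(cls1, cls2)
    expect_true(cls1 %in% tiers)
    if ("BA1" %in% set) expect_identical(cls1, "benign")
  }
})

test_that("criteria assignment reflects annotation and segregation", {
  fs <- one_variant(ref = "TA", alt = "T", effect = "frameshift_deletion",
                    sift = NA, polyphen = NA, mutationtaster = NA, cadd = NA)
  out <- acmg_classify(fs, segregating = TRUE, cfg)
  expect_equal(out$criteria, "PVS1,PM2,PP1")
  expect_equal(out$class, "pathogenic")
  common <- one_variant(maf_gnomad_all = 0.06)
  expect_equal(acmg_classify(common, FALSE, cfg)$class, "benign")
  bland <- one_variant(maf_gnomad_all = 0.005, sift = "tolerated",
                       polyphen = "benign", mutationtaster = "polymorphism",
                       cadd = 3)
  out2 <- acmg_classify(bland, FALSE, cfg)
  expect_equal(out2$criteria, "BP4")
  expect_equal(out2$class, "uncertain_significance")
  damaging_missense <- one_variant()
  out3 <- acmg_classify(damaging_missense, TRUE, cfg)
  expect_equal(out3$criteria, "PM2,PP1,PP3")
  expect_equal(out3$class, "uncertain_significance")
})

test_that("unknown config keys and invalid thresholds are rejected", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("min_depth: 10", "maf_threshold: 0.005"), path)
  cfg2 <- read_filter_config(path)
  expect_equal(cfg2$min_depth, 10)
  expect_equal(cfg2$maf_threshold, 0.005)
  writeLines("not_a_key: 1", path)
  expect_error(read_filter_config(path), "unknown config key")
  expect_error(filter_config(maf_threshold = 1.2), "inside")
  expect_error(filter_config(min_depth = -1), "nonnegative")
})

test_that("empty input yields empty candidates and an all-zero ledger", {
  path <- write_mini_vcf(character(), samples = c("GF", "GM", "FA", "UN",
                                                  "MO", "DA"))
  res <- run_cascade(path, fixture_ped_path())
  expect_equal(n_variants(res$candidates), 0)
  expect_true(all(res$ledger$n_in == 0))
  expect_true(all(res$ledger$n_out == 0))
})

test_that("cascade equals the naive conjunction of predicates (oracle)", {
  sim <- simulate_cohort(sim_config(seed = 202, n_background = 1500),
                         tempfile())
  res <- run_cascade(sim$vcf, sim$ped, sim$bed)
  expect_setequal(variant_keys(res$candidates),
                  oracle_candidates(sim$vcf, sim$ped, sim$bed))
  # ledger chain: monotone and internally consistent
  expect_true(all(res$ledger$n_out <= res$ledger$n_in))
  expect_equal(res$ledger$n_in[-1], res$ledger$n_out[-nrow(res$ledger)])
  expect_equal(res$ledger$n_in[1], n_variants(sim$variant_set))
})

test_that("independent stages commute: any order of rarity/functional/vote", {
  sim <- simulate_cohort(sim_config(seed = 77, n_background = 400), tempfile())
  x <- sim$variant_set
  ped <- read_ped(sim$ped)
  rep_iv <- read_bed(sim$bed)
  preds <- list(
    rarity = function(s) is_rare(s, cfg),
    functional = function(s) suppressWarnings(
      pass_functional_class(s, rep_iv, cfg)),
    vote = function(s) suppressWarnings(predictor_vote(s, cfg)))
  base <- x[pass_site_quality(x, cfg)]
  results <- lapply(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), function(ord) {
    s <- base
    for (p in preds[ord]) s <- s[p(s)]
    s <- s[segregates_dominant(s, ped, cfg)]
    sort(variant_keys(s))
  })
  expect_identical(results[[1]], results[[2]])
  expect_identical(results[[1]], results[[3]])
  full <- run_cascade(x, ped, rep_iv, cfg)
  expect_setequal(results[[1]], variant_keys(full$candidates))
})

test_that("every removed variant fails at its truth-labelled stage", {
  sim <- simulate_cohort(sim_config(seed = 31, n_background = 800), tempfile())
  res <- run_cascade(sim$vcf, sim$ped, sim$bed)
  stages <- pedprio:::CASCADE_STAGES
  surviving <- sapply(seq_along(stages), function(i)
    sum(!sim$truth$expected_stage %in% stages[seq_len(i)]))
  expect_equal(res$ledger$n_out, surviving)
  expect_setequal(variant_keys(res$candidates),
                  variant_keys(sim$truth[sim$truth$expected_stage == "pass", ]))
})
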