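test_that("gene drop honours fixed founder frequencies", {
  ped <- default_pedigree()
  set.seed(1)
  expect_true(all(gene_drop(ped, 0, n = 50)$dosage == 0))
  expect_true(all(gene_drop(ped, 1, n = 50)$dosage == 2))
})

test_that("gene drop is Mendelian: no child allele absent from its parents", {
  ped <- default_pedigree()
  for (seed in 1:5) {
    set.seed(seed)
    al <- gene_drop(ped, runif(200, 0.05, 0.5))$alleles
    for (id in ped$id[!is.na(ped$father)]) {
      fa <- ped$father[ped$id == id]
      mo <- ped$mother[ped$id == id]
      expect_true(all(al[, id, 1] == al[, fa, 1] | al[, id, 1] == al[, fa, 2]))
      expect_true(all(al[, id, 2] == al[, mo, 1] | al[, id, 2] == al[, mo, 2]))
    }
  }
})

test_that("identical configs produce byte-identical cohorts", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(sim_config(seed = 99, n_background = 150), d1)
  simulate_cohort(sim_config(seed = 99, n_background = 150), d2)
  for (f in c("cohort.vcf", "family.ped", "repeats.bed", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  d3 <- tempfile()
  simulate_cohort(sim_config(seed = 100, n_background = 150), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("a zero-background cohort contains exactly the planted variant", {
  sim <- simulate_cohort(sim_config(seed = 12, n_background = 0), tempfile())
  x <- read_vcf(sim$vcf)
  expect_equal(n_variants(x), 1)
  expect_equal(x$variants$gene, "CAUSAL1")
  expect_equal(x$variants$effect, "frameshift_deletion")
  expect_true(is_frameshift(x$variants$ref, x$variants$alt))
  expect_equal(sim$truth$expected_stage, "pass")
})

test_that("the planted variant satisfies every cascade predicate", {
  sim <- simulate_cohort(sim_config(seed = 13, n_background = 250), tempfile())
  x <- sim$variant_set
  i <- which(sim$truth$label == "planted")
  planted <- x[i]
  ped <- read_ped(sim$ped)
  rep_iv <- read_bed(sim$bed)
  cfg <- filter_config()
  expect_true(pass_site_quality(planted, cfg))
  expect_true(is_rare(planted, cfg))
  expect_true(pass_functional_class(planted, rep_iv, cfg))
  expect_true(predictor_vote(planted, cfg))
  expect_true(segregates_dominant(planted, ped, cfg))
  # heterozygous in every affected, hom-ref in every unaffected
  aff <- ped$id[ped$phenotype == "affected"]
  expect_true(all(planted$geno[, aff] == 1))
  expect_true(all(planted$geno[, setdiff(ped$id, aff)] == 0))
})

test_that("every VCF record appears in the truth table exactly once", {
  sim <- simulate_cohort(sim_config(seed = 14, n_background = 300), tempfile())
  x <- read_vcf(sim$vcf)
  expect_equal(sort(variant_keys(x)), sort(variant_keys(sim$truth)))
  expect_equal(anyDuplicated(variant_keys(sim$truth)), 0)
})

test_that("background variants cover the designed failure modes", {
  sim <- simulate_cohort(sim_config(seed = 15, n_background = 2000),
                         tempfile())
  tallies <- table(sim$truth$expected_stage)
  for (stage in pedprio:::CASCADE_STAGES[1:4])
    expect_gt(tallies[[stage]], 0)
  # repeat-resident nonframeshift indels are all labelled functional-stage
  nfs <- sim$truth$class == "repeat_nfs"
  expect_true(all(sim$truth$expected_stage[nfs] %in%
                    c("site_quality", "rarity", "functional_class")))
})

test_that("simulator configs are validated before any file is written", {
  expect_error(sim_config(n_background = -5), "n_background")
  expect_error(sim_config(fraction_common = 1.5), "fractions")
  expect_error(sim_config(fraction_synonymous = 0.6, fraction_intronic = 0.5),
               "sum")
})

test_that("snp panels realize the requested relationship", {
  set.seed(20)
  dup <- simulate_snp_panel("duplicate", 100)
  expect_identical(dup$geno[, 1], dup$geno[, 2])
  po <- simulate_snp_panel("parent_offspring", 100)
  expect_true(all(po$freq >= 0.1 & po$freq <= 0.5))
  # a parent and offspring can never be opposite homozygotes
  expect_true(all(abs(po$geno[, 1] - po$geno[, 2]) < 2))
})
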