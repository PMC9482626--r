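---
title: "Pedigree-based rare-variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based rare-variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedprio)
```

## The problem

In a small family where a disorder apparently follows autosomal dominant
inheritance, whole-genome sequencing of affected and unaffected members
yields millions of variants, of which at most a handful can plausibly be
causal. `pedprio` implements the classical prioritization cascade for
this design: successive filters on site quality, population rarity,
functional consequence, in-silico deleteriousness consensus, and finally
co-segregation with affection status under a fully penetrant dominant
model. Every stage logs its input and output counts in an audit ledger,
so the provenance of the final candidate list is explicit.

The package deliberately starts *after* alignment, variant calling and
functional annotation: its input is a multi-sample VCF whose INFO field
carries ANNOVAR-style annotation (gene, region, exonic effect,
per-database population frequencies, predictor calls), a PLINK 6-column
pedigree file, and a BED file of repeat-masked intervals.

## The filtering cascade

Stages run in a fixed order; each is a per-variant predicate and the
candidate set is their conjunction, so the ordering affects only the
ledger attribution, not the final set (a property the test suite
verifies by permuting the independent middle stages).

1. **Site quality.** Read depth > 4, root-mean-square mapping quality
   > 30, variant quality score > 20. All three bounds are strict
   inequalities, reproducing the published rule set literally. A
   missing metric fails the stage by default (fail-closed), with a
   warning; this is configurable because upstream pipelines differ in
   which INFO keys they emit.
2. **Population rarity.** The variant must have MAF < 0.01 in *every*
   available source among the 1000 Genomes, ESP6500, gnomAD (overall
   and East Asian) and an in-house database. A variant absent from all
   sources counts as rare: in a rare-disease design, novelty is
   evidence of rarity, not of error. This is switchable for users who
   prefer to fail closed.
3. **Functional class.** Only exonic variants and splicing variants
   within 10 bp of an exon boundary remain in scope; synonymous SNVs
   are discarded; nonframeshift indels shorter than 10 bp lying inside
   repeat-masked intervals are discarded (short in-frame indels in
   low-complexity sequence are a well-known alignment-artifact class;
   the same indel outside a repeat is kept).
4. **Deleteriousness consensus.** Per-tool damaging calls are: SIFT
   `damaging`; PolyPhen-2 `probably_damaging` or `possibly_damaging`;
   MutationTaster `disease_causing(_automatic)`; CADD phred at or
   above 20, the conventional "top 1%" cutoff (configurable — the rule
   set we reproduce names CADD without printing a threshold). A
   variant is retained when damaging calls exceed half of the tools
   *available* for it, so 3/4 passes, 2/4 fails and 2/2 passes. Using
   available tools as the denominator generalizes the "more than half
   of these four" rule without penalizing variant classes some tools
   refuse to score. Truncating variants (frameshift, stopgain) bypass
   the vote by default: SIFT and PolyPhen are undefined for them, and
   a frameshift should not be discarded because tools abstained.
5. **Dominant co-segregation.** A candidate must be heterozygous in
   every affected member and homozygous reference in every unaffected
   member; unknown-phenotype members are ignored. Homozygous-alternate
   affected genotypes fail — the model is a fully penetrant
   heterozygous dominant allele, and in a small pedigree a hom-alt
   carrier of a rare allele is more plausibly a genotyping error.
   Missing genotypes among phenotyped members fail by default
   (conservative), with a config switch for pedigrees with incomplete
   calls.

ACMG/AMP evidence is then attached to every candidate — it never
filters. The computable subset is PVS1 (null variant), PM2 (absent or
below 1e-4 in every population source), PP1 (co-segregation), PP3
(consensus vote on a missense), BA1 (> 0.05 anywhere, stand-alone
benign), BS1 (> 0.01 anywhere) and BP4 (all available predictors
benign). The published combining table maps the criteria set to the
five-tier class; we apply it as printed, so for example one very-strong
plus one moderate plus one supporting criterion (a co-segregating,
population-absent frameshift) meets the *pathogenic* combination
`PVS1 + 1 PM + 1 PP`, not merely likely-pathogenic. PM2's 1e-4 bound
and BS1's 0.01 bound are conventional choices the guideline leaves
quantitative, and both are exposed in `filter_config()`. Contradictory
evidence (a pathogenic-side and a benign-side combination firing
together) yields `uncertain_significance`; BA1 short-circuits to
benign.

### Coordinate conventions and small arithmetic

VCF positions are 1-based closed; BED intervals are 0-based half-open
and converted at the boundary, so BED `(s, e)` overlaps 1-based
position `p` iff `s < p ≤ e`. Indel reference spans
`[pos, pos + nchar(ref) − 1]` are used for repeat overlap, so a long
deletion can reach into a repeat from outside. Multiallelic records are
split per ALT at read time and genotypes recoded against the focal
allele, because every downstream rule is per-allele. Equal-length
multi-base substitutions are classified on the INDEL side: the
two-class SNV/INDEL vocabulary has no MNV slot and they must not slip
through SNV-specific predictor logic. Coding position `c` maps to codon
`floor((c − 1)/3) + 1`; an indel is frameshifting iff its
allele-length difference is not a multiple of 3.

## Pairwise IBD for pedigree QC

Sample swaps and misstated relationships are the classic failure mode
of family studies, so the package ships the standard method-of-moments
identity-by-descent estimator used for this QC. For a pair of samples
genotyped at independent biallelic SNPs with known alt frequency $p$,
the probabilities of observing 0, 1 or 2 alleles identical by state
conditional on sharing 0 or 1 allele identical by descent under
Hardy–Weinberg equilibrium are (with $q = 1 - p$):

$$P(\mathrm{IBS}0 \mid \mathrm{IBD}0) = 2p^2q^2, \quad
  P(\mathrm{IBS}1 \mid \mathrm{IBD}0) = 4p^3q + 4pq^3,$$
$$P(\mathrm{IBS}1 \mid \mathrm{IBD}1) = 2p^2q + 2pq^2, \quad
  P(\mathrm{IBS}2 \mid \mathrm{IBD}2) = 1 .$$

Because IBS0 is impossible given any IBD sharing at a locus, the moment
equations solve sequentially: $\hat Z_0$ from the observed IBS0 count,
$\hat Z_1$ from IBS1 after removing the $\hat Z_0$ contribution,
$\hat Z_2$ as the remainder. Estimates are clamped to $[0,1]$ and
renormalized (the sequential estimator can step slightly outside the
simplex by sampling noise), and
$\hat\pi = \hat Z_1/2 + \hat Z_2$. SNPs with panel MAF below 0.05 are
pruned first — moment estimators are unstable at rare alleles. No LD
pruning is implemented: the simulated panels are independent by
construction, and LD modelling on real data is out of scope. For a true
parent–offspring pair $Z_0 = 0$ identically, which is why the estimated
lower edge of the parent–offspring $\hat\pi$ band sits at exactly 0.5
after clamping, and the band over simulated pairs reproduces the
45–55% acceptance window used for trio QC.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the study conditions the cascade assumes:
the six-member, three-generation pedigree (affected grandfather, father
and daughter; unaffected grandmother, uncle and married-in mother), one
planted fully penetrant heterozygous dominant causal variant — a
frameshift deletion absent from every population database, CADD-high,
heterozygous in exactly the affected members — and `n_background`
background variants gene-dropped through the pedigree (founders drawn
under HWE, children inheriting one uniformly chosen allele per parent),
so Mendelian consistency holds cohort-wide and the segregation filter
is tested against realistic transmission, not independent genotypes.

Defaults, chosen once as the package's study conditions:

* `n_background = 5000`; half the background sits in a *common*
  component (founder frequency U(0.02, 0.35)) whose database MAFs —
  founder frequency times lognormal noise (σ = 0.2), present with
  probability 0.95 per source — fail the rarity stage; the other half
  is a *rare* component (founder frequency U(1e-4, 0.005), database
  entries present with probability 0.5, absent otherwise).
* Background functional classes: 25% synonymous, 5% repeat-resident
  nonframeshift deletions (the BED file is generated to cover them),
  5% nonframeshift deletions in the clear, 10% intronic, 5% splicing
  at 1–30 bp from the boundary, remainder missense. Background effects
  deliberately exclude truncating classes: a background frameshift
  that co-segregated by chance would be indistinguishable from the
  planted variant by design, and the benchmark is meant to have an
  unambiguous answer.
* Per-tool damaging-call probability 0.1 on background variants;
  missense and synonymous variants carry all four predictors, indels
  and splicing variants carry MutationTaster and CADD only, intronic
  variants none.
* 10% of background sites are drawn below one (uniformly chosen)
  site-quality threshold; all other metrics sit clearly above
  (depth 5 + Poisson(30), MQ U(40, 60), QUAL U(50, 1000)).

Under these conditions the expected number of background variants that
both co-segregate by chance and survive every other stage is about
0.004 per cohort (chance co-segregation for a rare founder allele at
frequency $f$ is $\approx f(1-f)^5/4$ in this pedigree, ~1.7 expected
events per 5000 background variants, times a ~0.25% chance of then
passing the functional and consensus stages), so planted-variant
recovery is expected to be exact, and the truth table written alongside
the cohort records the first stage each background variant should fail.

What the simulator does *not* emulate: linkage disequilibrium and
haplotype structure, sequencing-read-level error processes, genotyping
error and de novo mutation, annotation disagreement between
transcripts, incomplete penetrance and phenocopies, and population
stratification. Passing tests therefore demonstrate the correctness of
the filtering logic under clean, independent, Mendelian data — not
robustness of the overall strategy on real WGS callsets, where the
upstream caller and annotator dominate error behaviour.

A note on scale: the original analyses this cascade family is known for
start from millions of called variants. Those genome-scale inputs are
not redistributable, and the cohorts here (hundreds to a few thousand
variants in unit tests, 5000 background variants over 20 seeds in the
deepest recovery test, 10 parent–offspring pairs at 20,000 SNPs for
the IBD band) were chosen as the smallest sizes at which every stage
and the estimator's sampling behaviour are meaningfully exercised.

## Degenerate inputs and tie-breaks

Empty VCFs yield an empty candidate set and an all-zero ledger.
Half-missing genotypes (`./1`) are treated as fully missing — the
genotype model is all-or-nothing. Candidate output order is
deterministic: numeric-aware chromosome order, then position, ref, alt.
A consensus vote with zero available tools fails (for non-truncating
variants) rather than abstaining, so an unannotatable variant cannot
drift through the cascade. The pedigree reader rejects cycles and
unknown parent ids outright rather than repairing them.

## Known limitations

* The dominant fully-penetrant model is the only segregation model;
  recessive, X-linked and compound-heterozygous designs are out of
  scope.
* ACMG coverage is the computable criteria subset only; criteria that
  need external evidence (functional assays, de novo confirmation,
  allelic data) are not represented, so classes are conservative.
* The IBD estimator assumes independent SNPs and known frequencies;
  with frequencies estimated from the small pedigree itself
  (`estimate_ibd_pairs()` on a family VCF) the estimates are biased and
  should be treated as a gross swap check only.
* Desk-scale, in-memory processing: the VCF reader is vectorized but
  not streaming; genome-scale callsets should be pre-filtered upstream.
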