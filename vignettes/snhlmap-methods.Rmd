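---
title: "snhlmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{snhlmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snhlmap)
```

# Scope

`snhlmap` implements a two-arm analysis for the genetics of sensorineural
hearing loss (SNHL), a phenotype with extreme locus heterogeneity: well
over a hundred mapped non-syndromic loci, dominant and recessive, with the
DFNB1 locus (*GJB2*/*GJB6*) the only major recurrent contributor.  Under
that heterogeneity no single study design suffices, so the package pairs

* an **exome arm** — prioritization of SNVs/indels in small pedigrees and
  isolated probands, followed by inheritance-model filtering; and
* a **CNV arm** — genome-wide case–control association of deletions and
  duplications called from array-CGH, at region, gene and pathway level,
  with an overall CNV-load comparison;

plus an **overlay** that flags samples carrying a deletion *and* a point
mutation at one configured locus (the classic DFNB1 compound-lesion
pattern), and a **synthetic-data module** that generates desk-scale inputs
with the statistical structure each stage assumes.

Alignment and variant calling are upstream of this package: it consumes
multi-sample VCFs from two independent callers, per-sample CNV call BEDs
from two calling algorithms, and treats functional-impact categories,
clinical flags and population frequencies as input annotations (it never
computes SIFT/CADD-style scores itself).

# Coordinates

Internally all coordinates are 0-based half-open (BED convention), so
`end - start` is always the length and interval arithmetic needs no ±1
bookkeeping.  Printed human-genetics coordinates are 1-based inclusive and
converted only at I/O: a printed pair $(s, e)$ becomes $[s-1, e)$, of
length $e - s + 1$.  Chromosome names are normalized to the `chr` prefix
so mixed-dialect inputs merge cleanly.

# The prioritization cascade

`run_cascade()` applies four pure predicates in a fixed order (quality,
rarity, deleteriousness, gene blacklist).  Membership of the final set is
order-independent — each stage is a filter on variant annotations — but
the fixed order makes the per-stage accounting in the `CascadeReport`
comparable between runs.

**Quality** (`min_quality`, default 20, genotype-quality units): a variant
is kept when every *non-missing* genotype among the samples in scope has
quality ≥ 20.  The boundary is inclusive — a call at exactly 20.0
survives.  Scope is the pedigree or cohort manifest, not every VCF column,
so extraneous samples in a merged file cannot reject a variant.

**Rarity** (`max_pop_freq`; 0.15 in proband mode, 0.03 in family mode):
a variant is excluded when its allele frequency is ≥ the threshold in
*any* configured source (three population panels by default).  The
boundary is exclusive for keeping — a variant at exactly 3% fails family
mode.  Variants absent from every source are **kept**: absence from
reference panels is evidence of rarity, and truly private mutations (such
as a paternal allele seen in only one family) never appear in them.  The
"any source" reading is the conservative interpretation when sources
disagree.  Family mode is tighter because a fully penetrant allele
segregating with a severe familial phenotype must be very rare; proband
mode at 15% keeps reduced-penetrance candidates.

**Deleteriousness**: keep a variant if its impact category is damaging
(missense, frameshift, in-frame indel, stop change, splice, microRNA
binding-site or microRNA-deleterious, structural) *or* any clinical flag
attests to phenotype association (pathogenic, possibly pathogenic,
unknown significance, gain-of-function literature, gene fusion, inferred
activating, BSIFT gain-of-function).  Splice-category variants qualify
only when the recorded intronic offset is ≤ 2 bases (`max_splice_offset`);
deeper intronic splice-region variants have little evidence of effect.

**Gene blacklist** (default empty): hypervariable genes that recur as
artifacts across exome studies can be removed; the list is a user input,
not package data, because published studies do not enumerate it.

**Missing genotypes** are handled conservatively throughout: the cascade
ignores the quality of a missing call, but every segregation model
rejects a variant with a missing genotype in any pedigree member.  A
variant that cannot be confirmed in all samples cannot be claimed to
segregate.

# Dual-caller consensus

Caller outputs differ by hundreds of thousands of raw calls for technical
reasons, so requiring a variant to appear in both callers' outputs is a
strong error filter.  `intersect_callsets()` matches on position + alleles
by default; position-only matching is exposed because representation
differences (indel left-alignment) can defeat allele matching.  The
default is the stricter rule; annotations are taken from the first set
and the consensus is flagged in the caller field.

# Segregation models

All models operate on alternate-allele copy counts over a validated
pedigree (acyclic parentage, parental references resolved):

* **recessive** — homozygous-alt in every affected member, *not*
  homozygous in every unaffected member (carrier parents are expected).
* **compound heterozygous** — per gene, an unordered variant pair with
  one allele heterozygous in exactly one parent and absent in the other
  (one per parent), every affected child heterozygous for both, and no
  unaffected member carrying both.  Phase is inferred from parental
  origin only — never from read data — so the model is unavailable for
  parentless probands rather than approximated.
* **dominant** — carried by every affected member and genotype-ref in
  every unaffected member.  `allow_homozygous_affected` (default `TRUE`)
  admits homozygous affected carriers, which arise when an affected
  parent is homozygous.
* **de novo** — ref in both (unaffected, genotyped) parents and
  heterozygous in every member of a required set, e.g. both affected
  twins of a discordant family.

"Absent in unaffected" means genotype ref, the strictest reading.  A
mildly affected carrier (e.g. a mother with a milder phenotype under
incomplete penetrance) should be coded *affected* in the pedigree; the
engine does not soften the predicate instead.  Similarly, an affected
sibling whose phenotype has a known independent cause is excluded at
pedigree construction, not special-cased in the engine.

For isolated probands, `homozygous_rare_hits()` returns homozygous-alt
survivors partitioned by membership in a user-supplied list of known
disease genes, and `network_proximity_filter()` keeps hits whose gene is
within a configurable shortest-path distance of an anchor gene in a
user-supplied interaction network (distance 0 = is an anchor; genes
absent from the network are unreachable, never silently kept).
`recurrence_tally()` counts genes hit in at least a minimum number of
probands after removing variants also seen in unaffected family members.

# Array-CGH quality control

Two per-sample noise scores gate the CNV cohort:

* `qc_mad1dr()` — the unscaled median absolute deviation of consecutive-
  probe LRR differences, pooled across chromosomes (differences are never
  taken across a chromosome boundary).  For i.i.d. Gaussian probe noise
  of standard deviation $\sigma$ the expected score is
  $0.6745\,\sigma\sqrt{2}$, since consecutive differences have variance
  $2\sigma^2$.  Hybridizations above 0.23 are conventionally too noisy.
* `qc_robust_variance()` — the mean of squared consecutive-probe
  differences after trimming `trim_fraction` (default 3%) from each end
  of the ordered values.  The trim absorbs the variance spikes expected
  at true CNV breakpoints, so the score measures noise rather than
  signal.  The conventional acceptance range is 0.15–0.2; the package
  default cutoff is 0.2, the permissive end, because the convention
  states a range rather than a value — it is configurable.

# CNV association

**Carrier definition.** A sample is a carrier for a tested unit when any
of its calls overlaps the unit by at least 1 bp (`min_overlap`); genes
are extended by a 10 kb flank on each side (`flank`) so that deletions of
proximal regulatory sequence count.  A sample with several overlapping
calls counts once — contingency cells are sample counts.

**Smallest region of overlap.** `smallest_region_of_overlap()` returns
$[\max(\text{starts}), \min(\text{ends}))$, the maximal interval contained
in every call; it localizes a shared lesion more sharply than any single
call.  Disjoint inputs are an error that names an offending pair.

**Constant-frequency regions.** `region_association()` pools all call
breakpoints per chromosome into atomic intervals, computes each atom's
case and control carrier *sets*, merges contiguous atoms with identical
sets, and tests each merged region.  Defining regions by identical
carrier sets (not merely equal counts) makes boundaries reproducible and
guarantees that every base of a reported region has exactly the reported
frequency; a segment whose frequency changes is split.  Reported regions
therefore tile without overlap.

**Testing.** Each unit gets a two-sided Fisher exact test,
`fisher_exact_two_sided()`: conditional on the margins, the p-value sums
the probabilities of all tables whose hypergeometric probability does not
exceed the observed table's (relative tolerance 1e-9 on the comparison,
so probability ties land in the tail).  Two-sided is the appropriate
default when testing frequency *differences*.  Multiplicity is handled
with Benjamini–Hochberg FDR across the tested units (the `q` column);
BH is the standard choice where only "an FDR correction" is specified.
Genes and pathways with no carrier in either group are not tested (they
carry no information and would only dilute the FDR).

**Effect sizes.** `odds_ratio()` computes $OR = ad/bc$ with the Woolf
logit 95% interval $\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.  A
single zero cell triggers the Haldane–Anscombe correction (+0.5 to all
cells, flagged in the result); two zero cells on a diagonal leave the OR
undefined and raise an error rather than returning a fabricated number.

**Evidence tiers.** `cnv_evidence_filter()` reproduces the two-tier
carrier counting used with dual calling algorithms: `"both"` keeps calls
confirmed by a same-state call of the other algorithm with ≥ 1 bp overlap
in the same sample (high confidence), `"any"` accepts single-algorithm
calls (high sensitivity).  On the shipped chr16 fixture these tiers give
the 23/7 and 40/15 carrier counts.

**CNV load.** `cnv_load_test()` compares per-sample burden (call count,
total affected bp, optionally the number of genes of a supplied set that
are affected) between groups with a two-sided Wilcoxon rank-sum test.
When every sample has identical burden the statistic is degenerate and p
is reported as 1 by convention.

**Denominators.** Contingency denominators are the analyzed cohort (the
samples passing QC), passed explicitly, not inferred from the call files
— samples with zero calls still belong in the denominator.  The shipped
fixture uses 149 cases and 157 controls: the published carrier counts and
odds ratios for the chr16 deletion (23/7 → OR 3.91; 40/15 → OR 3.47) are
jointly consistent only with 149 analyzed cases although 150 were
enrolled, so one case is taken to have failed QC.  This reconciliation is
surfaced here rather than silently hard-coded: both ORs reproduce to two
decimals under these denominators and under no neighbouring pair.

# The compound-lesion overlay

`overlay_cnv_snv()` emits a lesion when a sample has ≥ 1 *loss* call
overlapping a configured locus and ≥ 1 heterozygous point variant in a
locus member gene.  Loci are configuration (name, interval, member
genes), not hard-coded coordinates, because locus definitions are
build-specific; the inputs must carry matching build tags or the overlay
refuses to run.  Phase is always `"unresolved"`: whether the deletion and
the point mutation are in cis or trans cannot be determined from call
data, and no regulatory-element inference is attempted — a small deletion
matches a locus only by interval overlap.  Which variant list to overlay
(cascade survivors vs externally curated pathogenic calls) is the
caller's choice; the pipeline uses cascade survivors.

# Synthetic data: what it emulates and what it does not

The generators' defaults are the study conditions of the cohort the
package reanalyzes:

* `simulate_pedigree_vcf()` — 4–5-member pedigrees; a planted causal
  variant (or pair) satisfying the chosen model exactly; background
  variants with allele frequencies from a Beta(0.4, 2) spectrum (mostly
  rare, some common), founder genotypes binomial at those frequencies,
  children by Mendelian allele sampling; genotype qualities N(35, 8)
  truncated at zero so a tail fails the quality cut; impact categories
  from a mixture in which every cascade stage rejects a non-trivial
  fraction (otherwise stage tests would be vacuous); per-source panel
  frequencies observed with probability 0.85 each, so some variants are
  absent from some panels.
* `simulate_cnv_cohort()` — 149 cases / 157 controls; planted deletion
  carriers Bernoulli at 23/149 and 7/157 (the observed chr16 rates);
  carrier intervals jittered outwards with exponential (mean 5 kb)
  margins re-anchored so the carriers' SRO equals the planted region
  exactly, making recovery scoring unambiguous; background calls
  Poisson(1) per sample, uniform over length-weighted autosomes, sizes
  log-normal with median 10 kb (typical array-resolution CNV scale);
  planted calls emitted under both algorithm labels, background calls
  under one or both.
* `simulate_lrr_track()` — i.i.d. Gaussian probe noise with optional
  embedded mean-shift segments, evenly spaced probes.

Each generator writes a manifest (planted ids, carrier lists, rates,
seed) that is the oracle for recovery tests, and is a pure function of
its parameters and seed — identical seeds give byte-identical files.

Deliberately **not** emulated: linkage disequilibrium and site spectra of
real exomes, caller-specific error modes (the two "algorithms" differ
only in label), segmentation boundary noise (carrier intervals are exact
supersets of the planted region), population structure, batch effects and
QC-failing samples.  Passing recovery tests therefore demonstrates the
correctness of the filtering and testing machinery under the assumed
statistical structure, not robustness to real-data artifacts.

# Numerical and degenerate-input conventions

* Fisher probability ties: relative tolerance 1e-9 when comparing table
  probabilities, so floating-point-equal tables enter the tail sum.
* BH q-values follow the step-up definition exactly
  ($q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1).
* Robust-variance trim count is $\lfloor \text{trim} \cdot n \rfloor$ per
  tail; trimming everything is an error, as is a track without two
  consecutive probes on any chromosome.
* Rank-sum on fully tied burdens reports p = 1 (the test statistic's
  null variance is zero).
* Variant ids are preserved from the VCF ID column when present,
  otherwise derived as `chrom:pos:ref:alt`; duplicates are disambiguated
  deterministically.
* Multi-allelic records are split per alternate allele before any
  filtering, with per-allele INFO values taken in allele order.
* Records with a missing REF or ALT, malformed positions, or CNV rows
  with `end <= start` are rejected with line-numbered diagnostics, not
  silently dropped.

# Problem sizes used by the test suite

The shipped tests run entirely on generated or printed-data inputs: 300
background variants per pedigree for sensitivity runs (50 seeds per
inheritance model), cohorts of 149/157 samples at 1 background call per
sample for association recovery (40 seeds), 200-seed calibration checks
for the carrier-rate and odds-ratio distributions, 100k probes for the
closed-form QC check, and 500 random tables for the Fisher enumeration
comparison.  These sizes were chosen as the smallest at which the
statistical claims are sharp; all are parameters, and nothing in the
package limits larger runs.

A note on statistical head-room: at the planted rates 0.15 vs 0.045 with
149/157 samples, the exact power of a two-sided Fisher test at p ≤ 0.05
is 87%, so region-level recovery across seed sets is expected near that
rate; gene-level recovery (planted gene ranked first) is essentially
certain because background genes rarely accumulate carriers.

# Known limitations

* X-linked and mitochondrial segregation models are not implemented (no
  analyzed family required them); neither is statistical linkage (LOD).
* Compound-het detection requires both parents; trios with one parent
  are not approximated.
* The region test treats samples as exchangeable — no covariates,
  ethnicity strata or relatedness adjustment; stratified analyses must
  be run per stratum.
* The overlay does not attempt phasing or clinical classification.
* Probe-level association (testing each probe rather than
  constant-frequency regions) is out of scope; published probe-level
  p-values are therefore not comparable to this package's region
  p-values.
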