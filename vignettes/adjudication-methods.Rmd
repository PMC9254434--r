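---
title: "Variant adjudication by graph genotyping: models and methods"
author: "adjukit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant adjudication by graph genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

adjukit takes candidate variant calls from several sources and decides, by
re-genotyping against the sequencing reads, which of them are real. This
vignette documents the models and the engineering decisions behind each
stage, what the synthetic-data generator does and does not emulate, and the
package's known limitations.

## 1. Normalisation and merging

VCF allows many encodings of one event, and different callers use
different ones; before anything can be compared, every candidate is
reduced to a canonical form. Records are split per ALT allele; when a
genotype (GT) is present only the called alleles are kept (records without
GT contribute all their alleles by default — `require_gt = TRUE` drops
them instead, for inputs where uncalled records are noise). Complex
alleles are decomposed into primitive SNPs and indels by global alignment
of REF against ALT, and every primitive is left-normalised: identical
trailing bases are trimmed (extending left from the reference when an
allele would empty) and identical leading bases removed. The result is
parsimonious, left-aligned, and idempotent, so equivalent encodings from
different callers collapse to identical keys and can be merged with their
origins unioned.

Two numerical choices here are deliberate:

* **Decomposition alignment.** Scoring is match +1, mismatch/gap −1 per
  base, with a *tiny* additional gap-opening cost (1/64, exactly
  representable in binary so ties stay exact). Under strictly linear gap
  costs the optimum is badly non-unique: a 4bp insertion whose interior
  happens to match the next reference base can split into two shorter
  insertions at the same total score, and two callers' encodings of one
  event then decompose to *different* primitive sets and never merge.
  The infinitesimal opening cost selects the contiguous-run optimum
  without changing which alignments are optimal in the unit-cost sense.
  Remaining ties resolve deterministically (substitution preferred over
  gap).
* **Coordinates.** Internally everything is 1-based and closed-interval,
  the native convention of R, IRanges, and VCF itself. An insertion
  occupies its single anchor base.

Variants whose left-anchored representation would have to cross the contig
start (a deletion of a repeat that runs to position 1) are rejected with
an error rather than silently re-anchored to the right.

## 2. Site clustering

Merged variants whose reference intervals overlap (transitive closure)
become one multi-allelic site; the site's alleles are every sequence
reachable by applying a conflict-free subset of its variants (conflict =
interval overlap; insertions at one anchor are mutually exclusive
alternatives). Three guards keep the graph practical:

* **Deletion cap** (`max_del_len = 50`): deletions longer than 50bp are
  excluded and counted, because SNPs beneath a long deletion make the
  combination count explode (n biallelic SNPs → 2^n alleles). Insertions
  are not capped.
* **Allele cap** (`max_alleles = 500`): when the conflict-free combination
  count would exceed the cap, only allele combinations actually observed
  in some sample's input genotypes are used (plus the reference). A
  sample whose own calls conflict within the cluster is skipped with a
  warning. If the observed combinations still exceed the cap, alleles are
  kept by descending observed frequency, ties broken lexicographically —
  a deterministic rule for a case the underlying method leaves open.
* **Duplicate-path merging** (`window = 7`): in low-complexity sequence,
  two alternate deletions of a repeat unit at *different* sites can
  realise the identical genome sequence through different graph paths,
  which would make exact read mapping ambiguous. As each site is
  appended, blocks of consecutive sites ending at it (up to 7
  predecessors) are checked by realising every path over the block's
  span; a block with duplicate spellings is merged into one site whose
  alleles are the distinct realised sequences. Blocks spelling more than
  4096 paths are not checked — duplicate spelling is a phenomenon of
  small repeat sites, and enumerating paths over large clusters would
  cost more than the mapping ambiguity it prevents.

For cohort-scale runs the sites can be partitioned into genome slices of
approximately equal total allele count (never splitting a site), each
padded by one read length so adjacent slices overlap and mapping has no
end effects; reads per slice can then be pulled from an indexed BAM.

## 3. Exact-match read mapping

A read maps to an allele when the *entire* read, with no clipping and no
mismatches, equals a substring of some graph path overlapping that
allele. Per site, γ(X) counts the reads whose matched allele set is
exactly X (each read counted once per site, however many paths it
matches), and a per-base counter of every matched allele is incremented
at the matched positions — multi-mapping is allowed, so a read lying in
the shared interior of two long alleles counts toward both. Both strands
are searched; reads containing ambiguous bases are skipped and counted.

The mapper spells, for each site, every combination of focal allele and
nearby neighbour alleles within a flank of `read length − 1` bases (so any
read overlapping an allele by a single base is findable), and looks up
each window substring in a hash of the read sequences and their reverse
complements. Neighbour combinations per side are capped at 128, dropping
the farthest neighbours to reference-only first; within one read length
this cap is generous for bacterial variant densities, and the property
suite checks the mapper against a brute-force haplotype-enumeration
oracle on dense random graphs. Read-order independence is tested
explicitly.

## 4. The genotype likelihood

Per-site total coverage c is modelled as negative binomial. The
parameter pair NB(n, r) with n = d²/(σ²−d) and r = (σ²−d)/σ² is pinned
to the pmf
P(k) ∝ (1−r)ⁿ rᵏ — the unique parameterisation with mean d and variance
σ² (asserted numerically to 1e-6 in the tests). Overdispersion is
required; if the observed variance does not exceed the mean — seen only
with unrealistically even simulated depth — σ² is set to 2d.

Each allele's log-likelihood sums three natural-log terms: the NB
probability of its coverage c_a; an error term ε^(c−c_a) for the reads
supporting other alleles (ε defaults to 0.002, a typical short-read
per-base error rate); and a gap penalty p^(b/ℓ)(1−p)^((ℓ−b)/ℓ), where ℓ
is the allele length and b its number of covered positions. We take
p = 1 − NB(n,r,0), the probability that a position has *non-zero* depth.
This expression is sometimes described, confusingly, as a zero-depth
probability; only the non-zero reading makes the two exponents pair
consistently (covered fraction with p, uncovered with 1−p), so that is
what is implemented, and the naming pitfall is flagged here.

The best allele is called (haploid only); ties break toward the lowest
allele index, reference first, so output is deterministic under allele
permutation. `GT_CONF` is the margin over the second-best allele. A site
with zero coverage yields a null call (`.`) with confidence 0 — a forced
reference call would claim evidence that does not exist.

## 5. Filters and the confidence null

Four FILTER criteria, all user-settable via `filter_config()`:

| filter   | fails when                         | default   |
|----------|------------------------------------|-----------|
| MIN_DP   | c < min_dp                         | 2         |
| MAX_DP   | c > d + k·σ                        | k = 3     |
| MIN_FRS  | c_called / c < min_frs             | 0.9       |
| MIN_GCP  | GT_CONF below null percentile      | 0.5%      |

GT_CONF depends on depth, so raw values are not comparable between runs.
`MIN_GCP` therefore simulates 10,000 biallelic SNPs from the *fitted*
model — correct-allele depth from the NB, wrong-allele depth binomial
with size equal to the drawn depth and probability ε — genotypes them
through the same likelihood (SNP semantics: ℓ = 1, covered iff depth
> 0), and takes the empirical order statistic at the configured
percentile (index ⌊p/100·n⌋, no interpolation) as the threshold. A call
fails on strict inequality. Because the simulated confidences are
discrete, the mass sitting exactly at the threshold makes the realised
failure rate of true calls land slightly *below* the nominal percentile
(≈0.40% against 0.5% at d=30, σ²=45); this is a property of empirical
quantiles of discrete distributions, not an implementation artefact, and
the acceptance check measures it within binomial error. Null calls fail
all four filters. The null simulation is seeded and reproducible.

## 6. Joint genotyping

For a cohort, the per-sample input VCFs are merged exactly as above (the
per-sample genotypes feeding the allele-cap fallback), one graph is built
for everyone, and each sample is genotyped independently — its own depth
model and its own confidence null, since confidence normalisation is
per-run by construction. Every sample's output contains the identical
site list; a multi-sample VCF combines them column-wise, and the distance
between two samples is the number of sites where their called alleles
differ. Sites where either call is null are skipped by default
(`count_null_as_diff = TRUE` counts them), since a null call is absence
of evidence, not evidence of difference. A sample whose reads cannot be
read is recorded as failed and the rest of the cohort proceeds.
Orchestration is plain in-process iteration — no workflow engine.

## 7. Truth-based evaluation

Each evaluated call becomes an **alt probe** (called allele plus, by
default, 100 flanking reference bases each side, truncated at contig
edges) and a **ref probe** (reference allele, same flanks). Probes are
aligned to the truth genome: exact full-probe matches first (both
strands), otherwise seeded local alignment around exact 18-mer candidate
loci. An alignment that does not contain the whole allele is discarded,
and equally good alignments at two distinct loci discard the probe as
ambiguous — the analog of ignoring mapping-quality-zero placements.

Scoring: no alt alignment → false positive, score 0. Alt aligns but the
ref probe has no alignment starting at the same truth position → clean
true positive, score 1. Otherwise the truth allele *t* is read off the
alt probe's best alignment (for the usual exact match, simply the truth
substring under the allele interval; subject insertions contiguous with
the allele's right edge belong to it, per left-anchored VCF convention),
and the score is 1 − d(t,a)/d(t,r) with both distances computed against
that same *t* — 0 when d(t,r) = 0. The edit distance counts an indel run
of *any* length as one edit (three-state alignment: unit mismatch, unit
gap-open, free extension), so a long indel weighs the same as a SNP.
Scores can be negative for very wrong calls. Precision is Σ numerators /
Σ denominators with false positives contributing 0/1, alt-only true
positives 1/1, and d(t,r)=0 calls 0/1. Calls touching a mask of either
genome are excluded entirely.

Recall applies the evaluated callset to the reference, producing a
mutated genome, and probe-evaluates the *truth* variants against it;
recall is the mean score. The truth set is user-supplied, or built from
the two assemblies with minimap2 (`-c --cs`, difference strings parsed
internally), keeping only candidates whose own probe evaluation scores
exactly 1 and dropping same-position conflicts.

Two calls within one flank length of each other interact: each probe
contains the *reference* version of its neighbour, so a correct pair of
adjacent calls can each score below 1. This is inherent to independent
per-call probes and is documented rather than patched; the end-to-end
suite keeps implanted variants separated except for the deliberate dense
cluster.

## 8. The synthetic-data generator

`simulate_bundle()` emulates the evaluation setting end to end: a seeded
uniform-composition genome (GC fraction configurable); implanted SNPs and
indels (non-conflicting by rejection sampling, left-normalised, with the
truth genome defined as their application — so generator and evaluator
cannot drift apart); an optional dense cluster packing several variants
into a 10bp window; reads at negative-binomially distributed depth; and
two pseudo-callers with configurable recall, false-call rate and
complementary misses, one of which re-encodes indels right-shifted to
exercise normalisation.

Depth is realised by drawing per-window read-start counts from
NB(mean d, variance σ²) with windows of one read length, then placing
starts uniformly within the window — the per-position depth *marginals*
are approximately, not exactly, negative binomial, which suffices for the
model-recovery properties the tests assert. Defaults mirror the study
conditions used throughout the tests: d = 30, σ² = 45, read length 100,
error rate 0 for the end-to-end checks (the genotype model's ε then only
prices wrong-allele reads), pseudo-caller recall 0.8 with FP rate 0.05.
Indel sizes default to uniform 1–10bp; the >50bp deletion-exclusion path
is exercised by its own unit test. What the generator does *not* emulate:
platform error profiles and quality scores, paired reads, contamination,
copy-number variation, and real genome repeat structure beyond what
uniform random sequence provides — so a passing suite demonstrates
correctness of the machinery, not performance on hard repetitive regions
of real genomes.

Problem sizes in the test suite were chosen to exercise every code path
at desk scale: the end-to-end check runs a 100kb genome with 350 truth
variants at 30×; the mapper/normaliser oracle equivalences use hundreds
of small randomized cases; the joint-genotyping invariants use five
samples on a 15kb genome.

## 9. Known limitations

* Haploid genotyping only; no heterozygous likelihoods, no phasing, no
  ploidy > 1 (`MIN_FRS` is the only contamination guard).
* Non-nested sites only: no SNPs represented underneath long deletions
  (hence the 50bp deletion cap); VCF cannot express nesting cleanly.
* Exact matching uses no base qualities and no pair information; highly
  repetitive regions lose reads to multi-mapping ambiguity (mitigated,
  not solved, by duplicate-path merging).
* Probe evaluation treats calls independently; adjacent interacting
  calls can each receive partial credit even when jointly perfect.
* The truth-set builder requires minimap2 on the PATH and uses a single
  aligner rather than a union of two.
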