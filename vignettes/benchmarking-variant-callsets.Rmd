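---
title: "Benchmarking small-variant callsets: harmonization, read re-check and threshold optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking small-variant callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Benchmarking a variant caller against a truth set looks like set
intersection, but a naive positional diff misreports all three error rates:

* the same edit has many legal VCF spellings — anchored at different
  positions inside a repeat tract, padded with shared bases, or bundled into
  a multi-allelic record — so spelling differences masquerade as
  false-negative/false-positive pairs;
* specificity needs a count of true negatives, which for a genome is
  naturally measured in reference base pairs, not variants;
* a recall deficit conflates two very different failure modes: variants that
  were never sequenced (no read support, unrecoverable without a new
  library) and variants that are visible in the reads but were discarded by
  caller filters (recoverable by re-tuning).

`varbench` addresses the three in order: a harmonizer maps every record to
one canonical spelling; the comparator counts true negatives in base pairs
inside the high-confidence regions; and a read re-check splits false
negatives into *bioinformatic* (b-FN, supporting reads exist) and
*sequencing* (seq-FN, none) classes, which yields the maximum theoretical
recall

$$\mathrm{RecallMax} = \frac{TP + bFN}{TP + FN},$$

the recall ceiling attainable by relaxing caller parameters given the
sequencing data that actually exists.

## Canonical representation and harmonization

The canonical form is the 5-column convention `chrom, start, end, ref, alt`
(1-based inclusive), with `-` for the absent allele:

| class | start/end                  | ref           | alt            |
|-------|----------------------------|---------------|----------------|
| SNV   | start = end                | base          | base           |
| DEL   | deleted interval           | deleted bases | `-`            |
| INS   | start = end = anchor base  | `-`           | inserted bases |
| MNV   | substituted interval       | bases         | bases          |

Block substitutions of unequal length (rare, and never produced by the
generator) are carried under the MNV label with `end = start + |ref| - 1`.

`harmonize_callset()` applies, per record:

1. **Multi-allelic decomposition** (`split_multiallelic()`): one record per
   ALT; INFO/FORMAT fields declared `Number=A`/`Number=R` in the header are
   sliced to the matching allele (well-known keys such as `AF`, `AD`, `SAF`
   are recognised when the header is silent), scalar fields are duplicated.
   Alleles with zero frequency — resolved VAF of 0, or allelic depth 0 when
   no VAF is resolvable — are dropped; alleles with no frequency evidence at
   all are retained. A mis-sized `Number=A` array marks the field missing
   with a warning, never an abort.
2. **Left alignment and parsimony** (`left_align()`): while `ref` and `alt`
   end with the same base, drop it; whenever one allele empties, prepend the
   reference base before the current position and decrement it; finally trim
   shared leading bases while both alleles are longer than one base. The
   result is the unique leftmost parsimonious spelling. At the start of a
   contig, when a further shift would be required, the current spelling is
   returned with a warning — a degenerate but legal input should not abort a
   benchmark run. A `ref` allele disagreeing with the reference is a
   per-record error that drops the record with a warning.
3. **Canonicalisation** (`to_canonical()`): the table above. `ref == alt`
   after trimming (a null variant) drops the record with a warning.

Duplicate canonical variants collapse to one, keeping the copy with the
highest QUAL — the copy most likely to survive downstream thresholds.
`N` bases are matched literally; exact matching is the conservative choice
for benchmarking. Haplotype-aware (diplotype) matching is out of scope: the
comparison is presence-only, genotype- and zygosity-blind.

The correctness property the test suite enforces is *haplotype equivalence*:
for randomly generated (reference window, spelling) pairs — including
homopolymer- and dinucleotide-shifted anchors, padded alleles, and
multi-allelic records with zero-frequency decoys — applying the canonical
edit to the reference reproduces exactly the sequence produced by the raw
edit, and all equivalent spellings collapse to one key (10,000 pairs per
run).

## Caller dialects

Callers disagree about where VAF, DP and strand bias live. A
`caller_dialect()` is an ordered lookup plan per parameter; the named
dialects (`gatk-hc`, `tvc`, `lofreq`, `deepvariant`) put the caller's own
fields first and fall through to a generic chain (VAF: `FORMAT/AF` →
`INFO/AF` → `FORMAT/AD` as alt over total allelic depth → `INFO/AO,RO`; DP:
`FORMAT/DP` → `INFO/DP` → `sum(AD)`; STB: `INFO/STB` → `INFO/SAF,SAR` →
`FORMAT/ADF,ADR` → `INFO/DP4`). An unresolvable parameter is `NA`, never a
silent zero. Records with FILTER other than PASS are kept and flagged by
default (`pass_only = TRUE` excludes them): the benchmark should see the
caller's output as-is, and filter policy is the user's sensitivity/precision
trade-off. Multi-sample VCFs use the first sample, with a warning.

## Metrics and true negatives in base pairs

Matching is exact on the canonical key inside the merged high-confidence
regions. A variant is in-region only if its full `[start, end]` interval is
contained in one region (an insertion is located at its anchor base);
any-overlap would count half-covered deletions at panel edges whose truth
status is ambiguous. True negatives are

`tn_bases = total region bases − distinct positions claimed by TP or FP calls`,

where a deletion claims every deleted base and an insertion one anchor
position. FN positions are *not* subtracted: specificity concerns the
query's positive claims, and an uncalled position is still a negative claim.
Every ratio with a zero denominator is reported as null, never NaN.

## Read re-check and the FN taxonomy

Every FN is re-evaluated in the read evidence (`classify_fns()`), from
either an indexed BAM/SAM or a readcount table (documented in the README;
both paths are proven identical on generated fixtures). Counting rules
(`readcount_site()`):

* duplicate, secondary, supplementary and unmapped alignments are excluded;
  reads below the mapping-quality floor and bases below the base-quality
  floor are excluded (`recheck_policy()`, defaults 0/0 — the criterion is
  existence of support, and quality floors are exposed for diagnostic users
  who want stricter evidence);
* an SNV/MNV is supported by a read whose aligned bases across the interval
  equal the alt allele; a deletion by a read whose alignment deletes exactly
  the canonical interval; an insertion by a read inserting exactly the
  canonical sequence after the anchor. Exact matching mirrors the exact-key
  comparator — no fuzzy windows;
* depth is the number of retained reads spanning the anchor position.

An FN with at least `min_alt_reads` (default 1) supporting reads is a b-FN
and receives caller-independent parameters derived from the pileup:
`DP = depth`, `VAF = alt/depth`, `STB = max(alt_fwd, alt_rev)/(alt_fwd +
alt_rev)` — the larger strand's share of alt reads, 0.5 balanced, 1 fully
one-sided. Without read evidence all FNs stay `unchecked` and `recall_max`
is not reported rather than silently equated to recall.

## Parameter analysis

**SeqPos** is the set of variants actually present in the sequencing output:
TP + b-FN (labelled 1, positively callable) + FP (labelled 0, should be
called negative); seq-FNs are excluded. TPs and FPs carry caller parameters,
b-FNs pileup parameters — the only ones available for each.

**Distribution tests.** `compare_distributions()` runs two-sided
Mann–Whitney tests (TP vs FP, TP vs b-FN) per parameter at α = 0.05: exact
(full rank enumeration) when both groups have ≤ 8 observations and the data
are tie-free, normal approximation with tie and continuity correction
otherwise. The switch keeps small-sample p-values exact; the suite checks
them against a brute-force enumeration oracle for all group sizes up to 6.
P-values are reported raw — the analysis is descriptive, per-parameter, and
a multiplicity correction across a handful of parameters would be a policy
choice left to the reader.

**ROC and cutpoints.** `roc_curve()` places thresholds at midpoints between
consecutive distinct observed values plus infinite sentinels. Directions are
fixed per parameter: VAF, DP, QUAL, QD greater-is-positive; STB
smaller-is-positive (heavy strand bias suggests an artifact); both are
overridable. The AUROC is the trapezoidal area, which equals the pairwise
concordance statistic U/(n₁n₀) with ties credited ½ — both are computed on
every call and their identity is asserted in the tests (1,000 random sets
including ties). The optimal cutpoint maximises Youden's J = sensitivity +
specificity − 1, the symmetric default of the cutpoint literature; ties are
broken toward the threshold retaining more positives. Records with a
missing parameter are excluded and counted; a single-class input is an
explicit "ROC undefined" error.

**QD.** Some callers report no quality-by-depth. For those, `compute_qd()`
supplies `QD = 4 · QUAL / DP` (null at zero depth), kept as a single small
function precisely so the scaling can be swapped if a different convention
is wanted.

**Threshold simulation.** `simulate_thresholds()` re-evaluates each call
against a `threshold_set()` (`min_vaf`, `min_dp`, `max_stb`, `min_qual`,
`min_qd`) using its own parameters: failing TPs demote to FN (still flagged
b-FN — they remain sequenced and callable), failing FPs are removed and
their positions return to the true-negative bases, passing b-FNs are
recovered as TPs, seq-FNs always stay FN. A missing parameter never fails a
call: a threshold on a metric a caller does not report must not annihilate
its callset. Two consequences worth stating explicitly: with an *empty*
threshold set every b-FN is recovered, so simulated recall equals the
input's `recall_max` with the FP count unchanged; and `TP + FN` is conserved
by every simulation.

## The synthetic generator

`sim_config()` → `generate_reference()` → `generate_truth_and_query()` →
`generate_reads()` (wrapped by `simulate_benchmark()`) produce a complete
fixture plus a *ledger*: one row per emitted variant recording its canonical
coordinates, intended class (TP, b-FN, seq-FN, FP), query spelling
(canonical, re-spelled, multi-allelic) and exact per-strand read counts. The
ledger is the oracle for every end-to-end test: the pipeline must reproduce
its confusion matrix exactly, for every seed.

What it emulates, and the defaults chosen where a value had to be fixed:

* **Layout.** One variant per 110 bp slot with a 50 bp contig margin, so
  read windows (2 × 30 bp flank) never interfere across sites and per-site
  counts stay exact. Default 15 kb region, 100 truth variants (60 SNV, 20
  INS, 20 DEL) — the scale of a targeted panel region set.
* **Repeat context.** Half of the indels (configurable) sit inside generated
  homopolymer (5–15 bp) or dinucleotide tracts with guarded boundaries, the
  context that produces divergent indel spellings in real callsets.
* **Depth.** Negative binomial, mean 300 and dispersion 8 — typical of a
  clinical targeted panel and overdispersed as capture data are; truncated
  at 2 except at seq-FN dropout sites, which may be forced to depth 0.
* **VAF.** Default Beta(mean 0.35, concentration 25) for real variants —
  heterozygous-germline/high-purity-somatic territory; FP VAFs sit
  `separation` (default 2) SDs lower. The alternative `split` rule draws the
  two classes uniformly on either side of a stated cutoff with a small guard
  gap — a clean generative separation used to test cutpoint recovery.
* **Strand.** Real-variant alt reads are balanced (0.5); FP alt reads are
  biased (0.8), as sequencing artifacts typically are. QUAL is normal (mean
  80, sd 15) for real calls, shifted down by `separation` SDs for FPs.
* **Error classes.** Per-truth-variant withholding probabilities: b-FN 0.15,
  seq-FN 0.05 (b-FN sites always get ≥ 1 alt read, seq-FN sites none); FP
  injection binomial at 0.15 per truth variant; 30% of query TPs re-spelled
  as shifted/padded/multi-allelic equivalents.
* **Reads.** Perfect, locally placed reads (full-M CIGARs, or I/D for
  indels) rendered to SAM and to the readcount table from the same ledger
  counts. Caller-reported DP/QUAL are drawn separately from the pileup
  depth, as a real caller's annotations never coincide exactly with a
  pileup.

What it deliberately does **not** emulate: sequencing errors and base
quality distributions, alignment ambiguity and mapping errors,
contamination, somatic subclonality, genotype errors. Passing the suite
therefore certifies the bookkeeping — harmonization, matching, counting,
classification, ROC arithmetic — on structurally realistic inputs; it does
not certify robustness to noisy alignments, which is the province of real
validation datasets.

## Validation problem sizes

The acceptance suite runs: 10,000 (window, spelling) harmonization pairs;
100 generator seeds at ~113 sites each for ledger/confusion-matrix
agreement (through the readcount path, with the SAM path proven identical on
full fixtures separately); 1,000 random label/score sets for the
AUROC–concordance identity; exhaustive Mann–Whitney enumeration for all
group sizes ≤ 6; 100 seeds at ~530 SeqPos records for recovery of a VAF
separation placed at 0.07 (recovered within the local observed-value
spacing); and 5-seed sweeps for the threshold-simulation invariants. The
`scripts/acceptance.R` entry point recomputes the headline quantities from
scratch for any seed.

## Known limitations

* Exact-key matching cannot credit a caller that represents one truth indel
  as a nearby complex variant with a different canonical key (the price of
  not doing haplotype comparison).
* Cutpoints are optimised marginally, one parameter at a time; joint
  threshold optimisation is out of scope.
* The re-check trusts the alignments it is given; no realignment or local
  assembly is attempted around indels.
* gVCF blocks, structural variants, breakends and phasing fields are out of
  scope; symbolic ALTs are skipped with a warning and counted.
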