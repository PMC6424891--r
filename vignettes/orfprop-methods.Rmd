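---
title: "Methods: ORF-level counting and proportion-based differential transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ORF-level counting and proportion-based differential transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The quantification model

`orfprop` implements a deliberately simple, proportion-based view of a
bacterial RNA-seq experiment. After alignment (which is out of scope —
the package consumes SAM or a documented TSV dialect), a sample is
reduced to a vector of ORF counts by three rules:

1. **Read filtering.** Reads that do not map to a unique position are
   removed first; then any remaining read that overlaps an annotated
   rRNA or tRNA feature by at least one nucleotide is removed. The
   order matters only for the accounting: applying uniqueness first
   makes the `FilterStats` decomposition deterministic (a non-unique
   rRNA read counts as non-unique). Every input read lands in exactly
   one of three bins, and `nInput = nNonUnique + nRrnaTrna + nRetained`
   is a class invariant, not a convention.
2. **Overlap counting.** A retained read counts towards every ORF whose
   interval it overlaps by at least one nucleotide — fully contained or
   partially covering, one or several ORFs. A read overlapping *k* ORFs
   adds 1 to each of the *k* counts, but only 1 to the mRNA total *N*,
   defined as the number of distinct retained reads overlapping at
   least one protein-coding feature. This keeps each ORF's count
   self-contained while *N* remains "reads mapping within any
   protein-coding region". A strict mode (`multiOrf = "discard"`) drops
   junction-spanning reads entirely for sensitivity analysis.
3. **Two normalizations.** Within a sample, transcript levels of
   different genes are compared as hits per kilobase,
   `h_i = c_i × 1000 / L_i` (read count per ORF length in kb). Across
   samples, the same gene is compared via its relative transcript
   abundance `r_i = c_i / N`, because the gene length is constant but
   *N* varies with sequencing depth.

Overlap is computed on the reference-consuming span of the alignment
(CIGAR `M/D/N/=/X`); soft clips do not extend the interval. Filtering
and counting are unstranded by default (`stranded = TRUE` restricts
overlap tests to same-strand features); bacterial RNA-seq protocols
differ in strand retention and the default assumes none.

## Uniqueness

"Uniquely mapped" is not a property a SAM file states directly, so the
package defines it operationally: a read is unique iff its record is
primary, not supplementary, the aligner-reported `NH` tag is absent or
1, and `MAPQ > 0`. The policy is configurable (`uniquePolicy` in
`readAlignments()`: `"nh-mapq"`, `"nh"`, `"mapq"`) because aligners
encode multi-mapping differently; the default is the intersection of
the two common signals, which is the most conservative definite rule.

# Differential transcription

For a contrast of two conditions, replicate counts are summed within
each group before abundances are formed (pooling; an experiment that
pools culture aliquots before sequencing is the design this mirrors).
The per-ORF condition ratio is `r2 / r1` — comparison over baseline. A
zero baseline abundance makes the ratio undefined; it is reported as
`NA` and classified `undefined`, never as infinity. Users who need
finite ratios can request a Haldane-style +0.5 count shift
(`pseudocount = "haldane"`); it is off by default because it changes
every ratio, not only the degenerate ones.

Equal transcription of an ORF is a hypothesis about proportions: is
`c/N` the same in both conditions? Two tests are dispatched on the
replication of the **baseline** group:

* **Replicated baseline:** the pooled two-proportion z-test on
  replicate-summed counts,
  `z = (c1/N1 − c2/N2) / sqrt(p̂(1−p̂)(1/N1 + 1/N2))` with
  `p̂ = (c1+c2)/(N1+N2)` and a two-sided normal p-value.
* **Single versus single library:** the Pearson chi-square test
  (1 df) on the 2×2 table `[[c1, N1−c1], [c2, N2−c2]]`.

No continuity correction is applied to the chi-square: that choice
preserves the algebraic identity `χ² = z²` between the two branches,
which the test suite verifies to 1e-9 relative tolerance on random
tables, and it keeps the two dispatch branches mutually consistent
rather than introducing a discontinuity at the replication boundary.
Both tests are two-sided. Degenerate tables (pooled proportion 0 or 1)
return statistic 0 and p = 1 rather than `NaN`.

Raw p-values are primary; Benjamini–Hochberg q-values are computed over
all tested ORFs and reported alongside, so thresholding on either is
possible. An alternative replicate-dispersion z-mode (z from the mean
and standard error of per-replicate abundances) was considered and
deliberately not made the default: with 2–3 replicates the standard
error estimate is so unstable that the pooled test is both simpler and
better calibrated.

## Change classes

Scatter-plot classification uses fold thresholds: by default 2-fold and
10-fold increases and 50%/90% reductions (remaining fractions 0.5 and
0.1). The strongest matching class wins, and boundaries are inclusive —
a ratio of exactly 2.0 is a 2-fold increase. Inclusivity is a
documented fixed choice ("a twofold increase" does not resolve the
boundary); it matters only for ratios landing exactly on a threshold,
which has measure zero for continuous data but can occur with small
counts. The classes partition `[0, ∞) ∪ {undefined}` and are a monotone
step function of the ratio, which the suite checks property-style.

# The simulator

The synthetic-data generator exists so that every pipeline stage can be
validated against known truth without any external download. It
emulates the statistical structure of a far-red-light (FRL)
photoacclimation profiling study:

* a genome of non-overlapping ORFs plus rRNA/tRNA features on one
  reference;
* baseline abundances drawn log-normally (sdlog 1 — a typical spread
  for bulk bacterial transcriptomes, where expression spans a few
  orders of magnitude);
* regulons as gene sets with per-condition multiplicative factors:
  a 20-gene FaRLiP-like cluster that is nearly silent in white light
  (fixed baseline relative abundance 6e-5 per gene, so that at the
  design depth of 2×10⁶ reads its baseline expected count is ~120)
  and induced 10³–4.35×10⁴-fold in FRL; a 15-gene
  phycobiliprotein/PSI-like set, highly expressed at baseline (10×
  weight) and repressed to 5–50% in FRL; a 4-gene antibiotic-response
  set induced 50–670-fold under erythromycin;
* knockout conditions in which the induction factor is 1 (`rfpB`,
  `rfpC`) or weak, 2–5-fold (`rfpA`);
* 5% rRNA-derived reads and 2% non-uniquely-mapping reads;
* multinomial count sampling (optionally Dirichlet-multinomial when an
  overdispersion concentration is set).

Counts are multinomial because that is the minimal sampling model
consistent with proportion-based testing; real libraries carry
biological and technical overdispersion whose magnitude cannot be
known desk-side, so the Dirichlet option is a sensitivity knob, not an
estimate. Reads are fixed-length and ungapped, placed uniformly within
their source feature; the optional boundary-jitter mode produces
partial (≥1-nt) overlaps solely to exercise the counting rule. What
passing tests therefore demonstrate is the correctness of the
*computations* under the stated sampling model — not robustness to GC
bias, positional coverage artifacts, operon structure, or dispersion
beyond the multinomial.

**Renormalization is a feature, not a bug.** Because condition
profiles are renormalized to sum to 1, a strong induction compresses
every other gene's relative abundance: with the default scenario the
FRL composition is dominated by the induced cluster and unregulated
genes show observed ratios well below 1. The `TruthTable` stores the
post-renormalization expected ratios, and all recovery tests compare
against those — the raw fold factor of a gene is not the quantity the
pipeline estimates. This mirrors the real compositional behaviour of
relative-abundance data under extreme induction.

Determinism: each sample's random stream is derived from
`(seed, condition, replicate)` via a string hash, so adding a condition
or replicate never changes the draws of the others, and every output of
`runPipeline()` is byte-identical across reruns of the same
configuration (numeric columns are formatted with a fixed 12
significant digits; the run log contains no timestamps for this
reason).

# Verification design

The suite is property-based, at sizes chosen to keep the default run
fast while leaving the statistics well-resolved:

* counting is compared with an exhaustive read×ORF scan on 100
  randomized instances (≤50 ORFs, ≤5,000 reads), including 1-nt
  boundary reads and ORF-spanning reads;
* `Σ r_i = 1` is asserted to 1e-12 on samples without multi-ORF reads
  (simulated reads are fully contained in non-overlapping ORFs, which
  guarantees that precondition by construction);
* the `χ² = z²` identity is checked to 1e-9 relative tolerance, and z
  antisymmetry under condition swap exactly;
* null calibration uses 10,000 ORFs with two samples drawn from one
  truth profile at an expected count of ~500 per ORF. At this coverage
  the discrete p-value distribution is smooth enough for a meaningful
  uniformity check (false-positive rate at 0.05, Kolmogorov–Smirnov
  distance); at the low end of usable coverage (expected count ~20)
  the 2×2 tables are so discrete that the KS distance to the uniform
  is dominated by ties near p = 1 regardless of implementation
  correctness, so calibration is assessed in the well-covered regime;
* parameter recovery runs the full default scenario (9 samples at
  2×10⁶ reads each) and requires every induced gene to be recovered as
  ≥10-fold up with q < 0.05, abolition in the knockouts to be
  recovered as `unchanged`, and the induced genes' estimated ratios to
  fall in an exact-binomial interval around the truth. The interval is
  built from per-margin exact binomial quantile intervals at level
  `1 − (1 − level)/2` on the two counts (Bonferroni), so its joint
  coverage is at least the nominal level; with 20 genes at 99% joint
  coverage an occasional single-gene excursion is expected over
  repeated seeds, which is the coverage the acceptance report makes
  visible.

# Limitations

* Proportion tests treat *N* as fixed; with very strong induction the
  effective power for unregulated genes reflects the compositional
  shift, as discussed above. The method is by design not a
  negative-binomial GLM and does not model biological replicate
  dispersion beyond pooling.
* The uniqueness policy is an operational reconstruction; aligners
  that emit neither `NH` nor meaningful `MAPQ` will need the TSV
  dialect or a policy override.
* Gapped/spliced alignments are handled only through their
  reference-consuming span — appropriate for bacterial data, wrong for
  spliced transcripts.
* rRNA/tRNA removal is by ≥1-nt coordinate overlap with annotated
  features, mirroring the ORF counting rule; removal by containment or
  by sequence similarity would give slightly different filter counts.
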