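# orfprop

ORF-level read counting and proportion-based differential transcription
for bacterial RNA-seq.

## The problem

Bacterial transcriptome studies — the motivating case is far-red-light
photoacclimation (FaRLiP) profiling in cyanobacteria, where a ~20-gene
cluster is induced by several orders of magnitude while
phycobiliprotein and photosystem genes are repressed — are often
quantified with a deliberately transparent scheme rather than a GLM
framework:

1. remove reads mapping to rRNA/tRNA regions and reads without a
   unique mapping position;
2. count, for every open reading frame (ORF), the reads overlapping it
   by **at least one nucleotide**;
3. normalize within a sample as **hits per kilobase**
   (h<sub>i</sub> = c<sub>i</sub> · 1000 / L<sub>i</sub>) and across
   samples as **relative transcript abundance**
   (r<sub>i</sub> = c<sub>i</sub> / N, with N the total of reads
   mapping in any protein-coding region);
4. test equal transcription per ORF on the condition ratio
   r₂/r₁ — with a **pooled two-proportion z-test** when the baseline
   condition is replicated,

   z = (c₁/N₁ − c₂/N₂) / √( p̂(1−p̂)(1/N₁ + 1/N₂) ),  p̂ = (c₁+c₂)/(N₁+N₂),

   and a **2×2 Pearson chi-square test** (1 df, no continuity
   correction, so χ² = z²) between single libraries;
5. classify genes against fold thresholds: 2-fold / 10-fold increases,
   50% / 90% reductions.

`orfprop` implements this pipeline as a tested, reusable Bioconductor-
style package (S4 classes over `GRanges`), together with a seeded
simulator that generates genomes, regulon truth profiles, count tables
and SAM alignments with the structure of such a study — a strongly
inducible cluster, knockouts in which the induction is abolished, a
repressed light-harvesting gene set, an antibiotic-response gene set,
rRNA contamination and multi-mapping reads — so that every stage is
verifiable against ground truth without any data download.

## Worked example

Simulate the default study scenario (7 conditions, triplicate white
light baseline, 2×10⁶ reads per sample) and contrast far-red light
against white light:

```r
library(orfprop)

cfg <- defaultStudyScenario(seed = 1)
sc  <- simulateScenario(cfg)             # annotation + truth + counts
res <- compareConditions(sc$groups$WT_WL, sc$groups$WT_FRL)

far <- regulons(sc$truth)$farlip_cluster
head(res[match(far, res$feature_id), ], 4)
```

```
    feature_id c_baseline c_other  ratio statistic test_used p_value q_value change_class
101   ORF_0101        377  166295 1323.3    -712.4    z_test       0       0       up_10x
102   ORF_0102        364   15809  130.3    -213.9    z_test       0       0       up_10x
103   ORF_0103        344  219195 1911.6    -821.2    z_test       0       0       up_10x
104   ORF_0104        374   33024  264.9    -312.5    z_test       0       0       up_10x
```

Each row is one ORF: pooled baseline and comparison counts, the ratio
of relative abundances (comparison over baseline — ORF_0101 is ~1,300×
more abundant, relatively, in far-red light), the pooled z statistic
(negative because the baseline proportion is smaller), the BH-adjusted
q-value, and the fold-threshold class. Summaries per gene set:

```r
regulonSummary(res, regulons(sc$truth))
```

```
         regulon n_members median_ratio n_up_10x n_down_90pct verdict
1 farlip_cluster        20    3.265e+02       20            0      up
2     pbp_psi_wl        15    7.154e-03        0           15    down
3    em_response         4    5.862e-02        0            4    down
```

All 20 induced-cluster genes are recovered as ≥10-fold up; the
light-harvesting set is repressed. Note the compositional effect: the
unrelated `em_response` genes show ratios ≪ 1 here purely because the
induced cluster dominates the far-red composition — the simulator's
truth table stores exactly these post-renormalization expected ratios.

An end-to-end run (alignment simulation → filtering → counting →
normalization → comparisons → TSV/JSON reports) is one call:

```r
runPipeline(list(scenario = "default", seed = 1), "out/")
```

and a thin CLI wrapper with `simulate` / `count` / `compare` / `run`
subcommands is provided in `inst/scripts/orfprop-cli.R`.

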