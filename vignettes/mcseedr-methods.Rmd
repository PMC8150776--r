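---
title: "Methods and design notes for mcseedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mcseedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcseedr)
```

# The assay and its signal model

MCSeEd (Methylation Content Sensitive Enzyme ddRAD) reduces a genome to
restriction fragments cut by a methylation-sensitive enzyme (one enzyme per
sequence context: CG, CHG, CHH, 6mA) paired with a methylation-insensitive
one. Methylation of a recognition site blocks digestion, so the number of
reads observed at a locus **decreases** as methylation at that site
increases. Everything downstream rests on that anti-correlation; no
bisulfite conversion or base-level methylation call is involved. Each
context is sequenced from separate libraries and analyzed separately,
including multiple-testing correction.

The pipeline compares exactly two genotype groups with replicated libraries
per group (at least 2, typically 3). Group 1 is, by convention, the group
listed first in the sample sheet; all reported deltas are group 1 minus
group 2, and "methylated" means hyper-methylated in group 1.

# Normalization and the CV locus filter

Counts are scaled to counts-per-million per library. The upstream protocol
says only that reads are "normalized"; CPM was chosen because it is
deterministic, parameter-free and independent of any reference sample, and
because every downstream statistic depends only on within-locus count
ratios, for which any per-library scale factor is equivalent.

The locus filter discards sites whose coefficient of variation
(CV = sample sd / mean across all libraries of the comparison) exceeds
`10^0.35 ≈ 2.239`, i.e. sites whose co-logarithm `−log10(CV)` is **below**
−0.35. The protocol wording ("discarding sites with a co-logarithm of the
CV above −0.35") taken literally would discard all *stable* sites and keep
the noisiest ones, which contradicts the filter's evident purpose of
removing unreliable restriction loci (unstable digestion, cross-mapping,
amplification artifacts). We therefore implement "discard CV > 10^0.35" and
expose both the threshold (`colog_threshold`) and an `invert` flag for the
literal reading. Note that with *k* libraries the sample CV of non-negative
data is bounded by √k (≈ 2.449 at k = 6), so at the default threshold the
filter removes only near-one-hot count profiles; it becomes more active
with more libraries. Loci with zero mean are always removed, which also
guarantees a positive row maximum for the next stage.

# Relative methylation

Per locus *i* and library *s*, with `n` the normalized counts:

`m[i,s] = 1 − n[i,s] / max_t n[i,t]`

The library with the most reads at the site defines the "least methylated"
state (m = 0); a library with no reads is fully methylated (m = 1). This is
a *relative* quantity — it cannot distinguish a locus that is 30% vs 60%
methylated in *all* libraries — which is sufficient because every test
below is a between-group contrast. The row maximum is itself a noisy
statistic (a maximum over ~6 overdispersed draws), which inflates the
variance of `m`; this is accounted for in the test's dispersion handling,
not in the transform.

# DMP calling

Relative methylation is mapped onto binomial pseudo-counts:
`numC = round(m × pseudo_coverage)` methylated pseudo-reads out of
`pseudo_coverage` (default 100) per library. A logistic regression of
methylation proportion on the group indicator is tested against the
intercept-only model by likelihood ratio (1 df). With a single two-level
covariate the binomial GLM has a closed-form MLE — the pooled within-group
proportions — so the LRT statistic is computed vectorized as the G
statistic of the pooled 2×2 table; the unit tests verify equality with
`glm()` fits. P-values are Benjamini–Hochberg adjusted within the context,
and `q < 0.05` defines a DMP. No minimum-difference cutoff is applied
beyond the FDR threshold.

**Overdispersion.** The pseudo-coverage is a resolution parameter, not a
real sampling depth: treating the pseudo-counts as literal binomial
observations ignores between-replicate (biological plus negative-binomial
sequencing) variation and is badly anti-conservative. Measured on null
synthetic data at the generator defaults (NB dispersion 0.1), the *plain*
binomial LRT calls ~70% of null loci at p < 0.05 and thousands of post-BH
"DMPs" on 5000 null loci. The default test therefore scales the LRT by a
McCullagh–Nelder Pearson dispersion — per-locus residual Pearson χ²/(k−2)
around the group fits, summarized genome-wide by the median and floored at
1 — and refers G/φ to χ²(1). This is quasi-binomial scaling, standard for
proportion GLMs with replication; it is *not* a beta-binomial model (which
is deliberately out of scope). Three modes are exposed:

* `"shrink"` (default): one genome-wide φ (median of per-locus estimates,
  floor 1), χ²(1) reference. Calibrated and the most powerful of the
  calibrated options because φ is effectively known.
* `"MN"`: per-locus φ (floor 1), F(1, k−2) reference — methylKit-style
  per-site correction; very conservative at k = 6.
* `"none"`: the unscaled binomial LRT — the literal prescription; use only
  when the input proportions really are binomial at the stated coverage.

The floor at 1 means that on genuinely binomial data (or in the
near-noiseless limit of the simulator) the default reduces to the plain
LRT. Because `"shrink"` borrows φ across loci, adding or removing loci can
move every p-value slightly; the invariance "adding group-identical
positions leaves p-values unchanged" holds exactly for `"none"` and is
tested there. Degenerate inputs (saturated groups, complete separation)
have finite closed-form G; a continuity-corrected two-proportion χ² is the
documented fallback should a non-finite statistic ever arise.

**Pseudo-coverage choice.** G scales linearly with `pseudo_coverage` and so
does φ, so the scaled statistic is invariant to it (up to rounding); 100
merely sets the rounding resolution of `m` to 1%.

# DMR calling

## Clustering scan

Per chromosome, left to right: the first unclustered DMP anchors a window
of length L; each subsequent DMP within L bp of the current anchor that
shares the direction joins the cluster and becomes the new anchor (sliding
extension). A DMP at distance exactly L still joins (closed gap
condition) — fixed by the published example that loci spaced exactly 500 bp
chain at L = 500. An opposite-direction significant DMP inside the window
**terminates** the cluster and anchors the next one, so a "same methylation
pattern" region can never contain a contradicting position; a
`opposite = "skip"` mode chains the two directions independently instead.
The scan is provably equivalent to chaining consecutive same-direction DMPs
with gaps ≤ L, splitting at direction changes — the test suite checks this
equivalence against a brute-force oracle on 1000 random instances.

Clusters need at least `min_cluster_size = 2` members. The source protocol
states "at least two DMPs" in its results and "more than 2 DMPs" in its
methods; we default to the results wording (2) and expose the parameter.

## Region test and window optimization

Member pseudo-counts are pooled per library (summed numC over summed
coverage) and the same quasi-binomial LRT is applied per cluster, with BH
across all clusters of the context; region q < 0.05 defines a DMR whose
interval is the minimal span of its member DMPs (the protocol does not
define the reported interval; the minimal span is the most conservative
choice). Pooling k member loci multiplies both the information and the
Pearson dispersion by ~k, so φ estimated at cluster level is comparable to
the locus-level one.

Window-length optimization clusters and tests at every candidate length
(default 100–2000 bp, step 100 — the protocol names only the endpoints) and
chooses the length maximizing the DMR count, ties broken by the smallest
length (an explicit determinism choice). The published operator-chosen
lengths per context and comparison are bundled as
`default_window_lengths()` and are the recommended setting on real data;
the scan is the fallback. An empty DMP list yields the smallest candidate,
flagged `empty`.

# Extended gene bodies and metagene profiles

Genes load from GFF3 (via `rtracklayer`); with several transcripts the
longest genomic span defines the gene body. "Upstream"/"downstream" are
strand-relative (5′/3′ of the gene) — the biological reading of "2 kb
upstream" — and the three EGB regions partition
`[start − 2000, end + 2000)` exactly, clipped at chromosome bounds. A gene
region's status is the unanimous direction of its overlapping DMRs;
regions hit by both directions in the same comparison are "ambiguous" and
excluded downstream. Summary tables count **distinct gene regions
overlapped at least once**, not DMR–region overlap events — the convention
under which the published per-context cells sum exactly to the published
"overlapped at least once" totals, which the acceptance suite verifies.

Metagene profiles bin DMPs that belong to DMRs at 100 bp over ±2000 bp
around the translation start and around the stop codon, strand-resolved
(offsets are mirror-invariant by construction, and tested). The gene-body
side of each anchor is truncated at 2000 bp; genes shorter than 2000 bp
contribute to both anchors, and a DMP is counted at most once per anchor
window.

# Regulatory gene sets and expression intersection

The "regulatory region" of a gene is the union of the 2 kb flanks and the
first and last 400 bp of the gene body (after the ATG / before the stop) —
the phrase in the source joins both, so the two lengths are separate
parameters (`flank`, `core`). A gene enters the methylated or de-methylated
set if at least one DMR overlaps that union and all overlapping DMRs agree
in direction. Shared/specific partitions between comparisons are plain set
arithmetic (`venn_sets`), and the gene sets default to the union over the
four contexts (a per-context mode is available via the `contexts`
argument) — the published shared/specific counts are not context-resolved,
which motivates the union default. Differential expression is consumed as a
table (gene id, logFC, FDR), never recomputed; the DMG×DEG intersection is
an inner join reporting each gene once with its supporting annotations.

# The synthetic data generator

`simulate_counts()` emulates one pairwise comparison of the motivating
design: 2 groups × 3 replicates for one context, on 2 chromosomes of 1 Mb
with 2000 loci each (one locus per ~500 bp — a desk-scale stand-in for the
~10⁶ loci per context of a real run). Per locus, baseline methylation
`mu ~ U(0.1, 0.9)`; effect loci move the groups to `mu ± effect/2`
(clipped); expected counts are `nb_mean (1 − m)` with `nb_mean = 200`, and
counts are negative-binomial with dispersion 0.1 in the edgeR sense
(variance `mu + 0.1 mu²`, biological CV ≈ 0.32 — a typical replicate-level
figure for enzymatic reduced-representation libraries). Three percent of
loci carry effects of size 0.5, laid out as 20 four-locus blocks spaced
150 bp (planted DMRs) plus isolated loci kept > 5 kb from any block
(planted singleton DMPs, which must never surface as DMRs). All defaults
are the stated world of the recovery experiments, not tuning knobs.

What the generator does **not** emulate: restriction-site sequence motifs,
enzyme efficiency differences, read-level artifacts, mapping bias,
chromosome-scale methylation gradients, or correlated methylation between
neighboring background loci. A green test therefore establishes that the
pipeline recovers planted signal under independent NB noise — not that it
is robust to spatially correlated or systematic artifacts in real data.

# Calibration vs. power: an honest accounting

Two acceptance-level requirements pull against each other at the stated
noise level:

* **Null calibration** (effect 0, dispersion 0.1, 3+3, 5000 loci): with the
  default overdispersion-scaled test the raw p < 0.05 rate is ~0.04–0.05
  and post-BH DMP counts are ~0, and cluster-level type-I error is within
  its binomial band. This criterion passes. With `"none"` it would fail
  catastrophically (see above).
* **Planted-block recovery** (effect 0.5, dispersion 0.1, 20 blocks of 4):
  a block is recoverable only if ≥ 2 of its 4 loci are individually called
  (members of clusters are DMPs by definition). At this noise level the
  per-locus standardized effect is ≈ 3–3.5 σ while the BH threshold at
  ~4000 loci sits near 3.4–3.6 σ, so per-locus power is ~0.3–0.5 and
  P(≥ 2 of 4) lands near 0.4–0.6 — we measure 45–55% block recovery with
  zero false blocks and correct directions. The ≥ 80% recovery criterion is
  therefore **not met** and is deliberately left failing rather than met by
  an uncalibrated test, a smaller locus count, or a quieter generator: the
  information per locus simply is not there. Recovery reaches ~80% at
  dispersion ≈ 0.05 (biological CV 0.22) with everything else unchanged,
  which is the regime the per-DMP power unit test probes (dispersion 0.02).

# Numerical and degenerate-input choices

* BH adjustment is always within context (separate enzymes/libraries).
* `0·log 0 = 0` throughout the likelihood arithmetic; saturated groups have
  zero Pearson residuals by convention, and φ estimates below 1 are floored.
* Direction is the sign of the group-mean difference of relative
  methylation; a delta of exactly 0 cannot be significant (G = 0).
* Window-scan ties break to the smallest length; `which.max` order is the
  documented tie rule.
* Duplicate genomic positions are a format error at read time, not merged.
* Chromosome-bound clipping can shorten flanks; regions are never negative.

# Known limitations

* No beta-binomial model, no covariates in the GLM, no smoothing/HMM DMR
  caller — all out of scope by design.
* Relative methylation is comparison-relative; absolute methylation levels
  are not identified.
* The 6mA context is treated statistically identically to 5mC contexts;
  enzyme-specific biases are not modeled.
* GO annotation/enrichment and upstream read processing (QC, trimming,
  alignment, locus discovery) are outside the package.
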