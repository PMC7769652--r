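---
title: "Methods and design notes for the aaalnc pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the aaalnc pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaalnc)
```

# The analysis model

`aaalnc` implements the downstream analysis of a small two-group tissue
microarray study of long noncoding RNAs: a screening cohort of a few case
tissues (abdominal aortic aneurysm in the motivating design, 5 samples)
against a few controls (3 samples), qPCR validation in a larger cohort
(11 vs 12), and network-level interpretation of the validated transcripts.
This document records the statistical model of each stage, the parameters
that matter, what the synthetic generator does and does not emulate, and the
design decisions taken where the conventional description of this analysis
leaves the rules open.

## Differential expression

Intensities are held on the **linear scale** throughout; log2 is always an
explicit transform. The reason is the fold-change convention used in this
type of study: FC is the *absolute ratio of group mean linear intensities*,
always reported ≥ 1 with the direction as a separate Up/Down label (so a
19.9-fold *down*-regulated probe still prints FC = 19.9). Testing, however,
is done in log2 space, where single-channel array intensities are
approximately Gaussian.

The per-probe test is the **pooled-variance unpaired t-test**
(df = n1 + n2 − 2), not Welch. This choice is checkable: the published
cohort-table blood-pressure P values (0.017, 0.005 at 5 vs 3; 0.003 at
11 vs 12) are reproduced at 3-decimal rounding by the pooled kernel from the
printed mean/SD/n, and not by Welch. The same kernel backs the probe tests,
the qPCR group comparison and the summary-statistics cohort tests, and the
suite checks raw-vector and summary-form agreement to 12 digits. Two
degenerate cases are fixed by convention: zero pooled variance with equal
means gives P = 1; with unequal means it gives P = 0 and a `degenerate`
flag.

The screening gate is **FC > 2 and raw P < 0.05, both strict**. The gate
deliberately uses raw P, not FDR: published top tables of this design print
raw P only, and the headline DE counts are raw-P based. BH-FDR is still
computed and carried on every record. A probe whose fold change is exactly
2.0 is excluded. Equal group means tie-break to "Up" (arbitrary but fixed).

Quantile normalization is provided (`normalize_quantile`) because the
upstream normalization of "normalized intensities" is typically unstated:
each column is mapped onto the across-sample mean sorted vector, with tied
values receiving the mean of their assigned quantiles. Note that limma's
`normalizeQuantiles` interpolates ranks for ties, which differs on runs of
tied values; the tie rule here is pinned by hand-computed tests, and the
limma comparison is made on tie-free data.

Note the headline outputs of the motivating study (2046 DE lncRNAs, 1363 DE
mRNAs, specific GO/KEGG term counts, 229 coexpression edges, the Figure-5
class counts) are data-dependent quantities of an undeposited dataset. They
are **not** reproduction targets; the schema, gates and statistical kernels
are, and are covered by oracle and property tests.

## Over-representation analysis

The Fisher test is **one-sided** (over-representation): published results of
this kind report only enriched terms. P = Pr(X ≥ c) for the hypergeometric
overlap c of the DE list (size n) with a set (size K inside the universe of
N genes). The **universe is the assayed gene complement** (the array
annotation), not the genome — standard microarray ORA practice. The
enrichment score is −log10 P, the conventional definition behind
"enrichment score" axes in array-service figures. BH-FDR is applied within
each GO category (BP/CC/MF) and separately for pathway sets, since the
correction family is otherwise unstated. The chi-square variant uses the
Pearson statistic with 1 df and no continuity correction and flags results
with any expected cell < 5 as unreliable. Sidedness matters when comparing
the two: the one-sided Fisher P converges to *half* the two-sided chi-square
P for large balanced tables; the convergence test therefore compares
chi-square against the two-sided Fisher P.

## Positional classification of lncRNAs

The six category names are standard in array annotation, but no formal rule
set accompanies them; the rules here are a documented **reconstruction**,
applied in fixed precedence (first match over any gene wins):

1. *exon sense-overlapping* — same strand, ≥ 1 bp exon–exon overlap;
2. *intron sense-overlapping* — same strand, span overlap, no exon–exon
   overlap;
3. *intronic antisense* — opposite strand, lncRNA span wholly inside one
   intron;
4. *natural antisense* — opposite strand, ≥ 1 bp span overlap, not rule 3;
5. *bidirectional* — no overlap, opposite strands, TSS-to-TSS distance ≤ 1 kb
   with divergent (head-to-head) orientation;
6. *intergenic* — none of the above.

The 1 kb window is the conventional bidirectional-promoter definition and is
configurable. Precedence puts exonic above intronic within sense, and
intronic above general within antisense; a lncRNA overlapping several genes
takes the highest-precedence class, ties broken by nearest TSS. Same-strand
non-overlapping neighbors within 1 kb (tandem) are *not* bidirectional —
divergence is required — and fall to intergenic.

Every lncRNA receives exactly one class, so category counts always sum to
the input size (the partition property mirrored by the published counts
summing to their total). One stated invariant required qualification: strand
flip of all loci preserves rules 1–4 and 6 but not rule 5, because flipping
strands moves the TSSs that define divergence; the property suite therefore
checks flip invariance with the bidirectional window disabled.

Loci are held as `GRanges` (1-based closed, the Bioconductor convention)
with exon blocks; the BED12 reader/writer convert explicitly from/to 0-based
half-open file coordinates, and round-trip plus `rtracklayer` cross-checks
pin the conversion.

## Coexpression (CNC) network

Every lncRNA × mRNA pair is scored by the Pearson correlation of log2
profiles across **all samples pooled** (case + control; m = 8 in the
motivating design — the correlation-P values printed in such studies are
consistent with the m = 8 t-transform). P is two-sided from
t = r√(m−2)/√(1−r²) with m − 2 df. The retention gate is
**|r| ≥ 0.97 (non-strict), P ≤ 0.05, BH-FDR ≤ 1** over the tested grid. The
magnitude reading of "not less than 0.97" is deliberate: published networks
of this design contain negative edges. The FDR ≤ 1 gate is vacuous and kept
only for interface fidelity. Where a published table note instead cites
|r| ≥ 0.8, the threshold conflict is unresolved at the source; 0.97 is the
default and `r_cut` is exposed. Zero-variance profiles are skipped with a
warning rather than propagating NaN.

## ceRNA network

For genes a and b sharing c targeting miRNAs out of N total (K targeting a,
n targeting b), the pair score is the hypergeometric upper tail

$$P = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

inclusive of i = c, computed from log-space binomial coefficients (overflow
safe at array-scale N) and returned exactly 1 at c = 0. The suite checks the
full N ≤ 25 grid against exact integer-arithmetic tails and small-N draws
enumeration, plus symmetry in K ↔ n and monotonicity in c.

The three qualitative ceRNA filtering conditions (relative concentration,
sponge capacity, MRE inequality) are formalized as: candidate pairs
restricted to differentially expressed transcripts (concentration);
`min_shared = 3` shared miRNAs (sponge capacity); and an optional
MRE-weighted shared count for the gate (`weight_mre`, MRE inequality) — the
hypergeometric test itself always uses plain counts. Both gates (c and P)
are applied because the source description ("passed this filtering") does
not say which was used.

N defaults to the number of distinct miRNAs in the supplied target table
("total miRNAs used to predict targets" when the table is the full
prediction run). For sparse tables — e.g. a synthetic excerpt where only a
quarter of the simulated 200-miRNA universe hits any of 16 genes — that
default deflates N and the tail P, so `n_mirna` can be supplied explicitly;
the pipeline passes the generator's universe size.

## qPCR quantification

Replicate Ct values are arithmetic means per sample × gene; ΔCt = target −
reference; ΔΔCt subtracts the **mean ΔCt of the calibrator group** (not a
single calibrator sample — the comparison of interest is group-level);
rq = 2^−ΔΔCt. This makes the calibrator group's geometric mean rq exactly 1.
The group comparison is the shared pooled t-test on per-sample rq by default
(published bar charts plot relative expression on the linear scale); a
`log_scale` option tests on −ΔΔCt instead, since the statistical scale is
conventionally unstated. Whether published bars are means of per-sample rq
or 2^−(mean ΔΔCt) is ambiguous; per-sample rq means are used. Amplification
efficiency is assumed 100% (no Pfaffl correction; out of scope).

## Synthetic data: the stated world

The generators exist so that every stage has recoverable planted truth
offline. Their defaults are fixed once, from the motivating design where
stated and from field-standard choices where not, and are **not** tuned
against test outcomes:

* **Design**: 5 case vs 3 control (screening); 11 vs 12 (qPCR validation).
* **Intensity model**: log-normal — per-probe baseline log2 mean ~ N(8,
  1.5²), Gaussian log2 noise σ = 0.25, exponentiated. Arrays' true
  distributional form is unstated upstream; log-normal is the standard
  single-channel stand-in, and this is the main idealization: no
  probe-level outliers, batch/dye effects or intensity-dependent variance.
  A green recovery test shows the gates work under this model, not that the
  original arrays would reproduce.
* **Effects**: planted |log2FC| uniform on [1, 5.46] (up to ~44-fold, the
  largest effect contemplated by the design) on a fraction `frac_de = 0.05`
  of probes per biotype; direction ± with equal probability. `frac_de = 0`
  is allowed for null calibration (raw P ~ Uniform(0,1), KS-checked).
* **Scale**: 2000 lncRNA + 1200 mRNA probes by default, 400 + 240 in the
  `tiny` profile (tests run at reduced probe counts to stay inside CI
  budgets — stated here once; the full ~35k/20k array scale is reachable by
  argument).
* **Coexpression**: the planted mRNA log2 profile is ρ·z + √(1−ρ²)·ε with z
  the standardized lncRNA profile; expected sample r ≈ ρ (0.99 default).
  At m = 8 this passes the |r| ≥ 0.97 gate in ≳99% of replicates.
* **miRNA targets**: Bernoulli(0.02) background over a 200-miRNA × gene
  grid, planted pairs forced to share exactly 5 miRNAs.
* **Loci**: six-cassette geometry per class along one synthetic chromosome,
  40 kb spacing so cassettes cannot interact within the 1 kb window.
* **Ct tables**: triplicates, technical SD 0.2 cycles, a sample-level RNA
  loading effect shared by target and reference (cancels in ΔCt), planted
  ΔΔCt = −(true log2 ratio).

All generators draw from a locally seeded RNG and restore the caller's
state; identical seed + parameters give bit-identical outputs.

## Numerical and interface choices

* BH-FDR wraps `stats::p.adjust(method = "BH")` behind input validation;
  tests compare it against a brute-force step-up implementation (1000
  random vectors) so the dual-route check is preserved.
* Fisher tails use `stats::phyper` / `stats::fisher.test`; the ceRNA tail
  is implemented directly from the formula (it is the method's core) with
  `phyper` and enumeration as oracles.
* Tabular I/O is TSV, UTF-8; networks export as Cytoscape-ready node/edge
  attribute tables plus SIF (`pp` positive, `nn` negative, or the explicit
  edge `type` for tripartite ceRNA exports).
* Pipeline config is an R list or YAML; the manifest is JSON with seeds,
  thresholds, row counts and file names, and carries no timestamps so
  identical runs produce identical manifests.

## Known limitations

No moderated-variance (limma-style) testing, paired designs or multi-group
contrasts; no GO graph propagation or pathway topology; no sequence-based
MRE prediction (target tables are inputs); no amplification-efficiency
correction; no batch-effect simulation. The classification rules are a
reconstruction and other annotators may bin edge cases differently,
particularly same-strand tandem neighbors and multi-gene overlaps.
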