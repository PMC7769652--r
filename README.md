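# aaalnc

Differential expression and regulatory-network analysis for two-group
lncRNA/mRNA tissue microarray studies, built around the design of an
abdominal aortic aneurysm (AAA) versus normal aorta comparison: a handful of
case tissues against a handful of controls, followed by qPCR validation in a
larger cohort and network-level interpretation of the validated lncRNAs.

The package is aimed at analysts who have probe-level normalized intensities
(plus probe annotation, gene sets, genomic loci and miRNA target tables) and
want the complete downstream chain as tested, scriptable R functions — and at
method developers who need a seeded synthetic benchmark with planted ground
truth for exactly this pipeline shape.

## What it computes

* **Differential expression** (`screen_de`): per-probe pooled-variance
  unpaired t-test on log2 intensities (df = n1 + n2 − 2), fold change as the
  *absolute ratio* of group mean linear intensities (always ≥ 1, direction
  carried by an Up/Down label), Benjamini–Hochberg FDR, and the screening
  gate FC > 2 and raw P < 0.05 (strict inequalities).
* **Gene-set over-representation** (`fisher_enrichment`,
  `chi_square_enrichment`): one-sided Fisher's exact test
  P = Pr(X ≥ c) for the hypergeometric overlap of a DE list with each set,
  or Pearson chi-square (1 df, no continuity correction) on the same 2×2
  table; BH-FDR within category; enrichment score = −log10 P.
* **Positional lncRNA classification** (`classify_all`): each lncRNA locus
  is assigned exactly one of intergenic, natural antisense, intronic
  antisense, exon sense-overlapping, bidirectional, intron
  sense-overlapping, by strand and overlap geometry with a fixed precedence
  (see the methods vignette).
* **Coding–noncoding coexpression network** (`build_cnc`): all lncRNA × mRNA
  Pearson correlations across pooled samples, two-sided P from
  t = r√(m−2)/√(1−r²), gate |r| ≥ 0.97, P ≤ 0.05, FDR ≤ 1, signed edges,
  Cytoscape export (SIF + attribute tables).
* **ceRNA network** (`cerna_p`, `build_cerna`): for each candidate
  lncRNA–mRNA pair sharing c of N miRNAs (K targeting one gene, n the
  other), the hypergeometric tail
  P = Σ_{i=c}^{min(K,n)} C(K,i)·C(N−K,n−i)/C(N,n),
  gated at ≥ 3 shared miRNAs and P < 0.05; tripartite
  lncRNA–miRNA–mRNA export.
* **qPCR quantification** (`ddct`, `compare_groups`): triplicate Ct means,
  ΔCt against a reference gene, ΔΔCt against the calibrator-group mean,
  rq = 2^−ΔΔCt, and a pooled t-test between groups.
* **Cohort tables** (`t_test_from_summary`, `fisher_2x2`): two-sample
  pooled-variance t-tests straight from printed mean ± SD and n, and
  Fisher's exact test for categorical rows.
* **Synthetic data** (`simulate_expression`, `simulate_coexpression`,
  `simulate_mirna_targets`, `simulate_loci`, `simulate_ct_table`,
  `simulate_gene_sets`): seeded, deterministic generators that emulate the
  5-vs-3 design with planted effects, so every stage has recoverable ground
  truth.
* **Pipeline** (`run_pipeline`): the whole chain end to end with a JSON
  provenance manifest; a CLI front-end lives at
  `system.file("cli", "aaalnc.R", package = "aaalnc")` with subcommands
  `simulate`, `diffexpr`, `enrich`, `classify`, `cnc`, `cerna`, `qpcr`,
  `cohort`, `pipeline`.

## Worked example

```r
library(aaalnc)

sim <- simulate_expression(seed = 1, n_case = 5, n_ctrl = 3,
                           n_lnc = 400, n_mrna = 240, frac_de = 0.05,
                           fc_log2_range = c(2, 2), sigma_log2 = 0.25)
de <- screen_de(normalize_quantile(sim$matrix), sim$annotation,
                fc_cut = 2, p_cut = 0.05)
nrow(de$up); nrow(de$down)
#> [1] 10
#> [1] 22
top_table(de$down, k = 3)[, c("seqname", "probe_name", "p_value", "fc")]
#>         seqname probe_name      p_value       fc
#> 324 SYNLNC00324 ASHGV00324 1.181806e-04 4.490734
#> 526   SYNM00526 ASHGV00526 5.237879e-05 4.377941
#> 37  SYNLNC00037 ASHGV00037 2.253912e-05 4.305157
```

32 probes pass the gate — exactly the 32 the generator planted (20 lncRNA +
12 mRNA at log2FC = 2, i.e. fold change 4, close to the FC column above)
with zero false positives at this noise level. The cohort kernel reproduces
printed clinical P values from summary statistics alone:

```r
t_test_from_summary(90.20, 8.67, 5, 63.67, 8.39, 3)$p_value
#> [1] 0.005469005   # prints as 0.005
```

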