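# cafpaths

Classification and developmental-path inference for cancer-associated
fibroblast (CAF) subpopulations in single-cell RNA-seq.

## The problem

Tumour stroma contains fibroblast subpopulations of disputed origin:
bone-marrow-derived mesenchymal stem cells (BM-MSCs) and local
tissue-resident fibroblasts are both candidate CAF sources. Given gene ×
cell count matrices from tumour tissue and matched normal tissue, this
package runs the full multi-stage analysis that addresses the question:

1. **Fibroblast identification** — a strict two-step screen: coarse
   k-means clusters with high pan-fibroblast marker scores (step 1), then
   per-cell exclusion of anything expressing epithelial / immune /
   endothelial lineage markers (step 2).
2. **Per-sample clustering** — k-means with the number of clusters *k*
   chosen from the sum-of-squared-error curve: the smallest *k* after
   which every relative drop (SSE(k) − SSE(k+1)) / SSE(k) stays below a
   threshold (default 0.10).
3. **Taxonomy** — tumour clusters with *PRRX1* activation and CAF-related
   gene scores ≥ 0.5 SD above the cluster mean are "perpetually activated"
   **paCAF** (others non-paCAF); paCAFs are subtyped **myCAF**
   (*ACTA2*/*TAGLN*-high) vs **iCAF** (*PDGFRA*/*CFD*/*CXCL12*-high) with a
   Wilcoxon rank-sum test on per-cell signature-score differences; normal
   clusters with high BM-MSC markers (*ENG*, *NT5E*, *THY1*, *PDGFRB*,
   *CD44*) and no hematopoietic markers are **tr-MSCF** (MSC-like), the
   rest **tr-RF** (resting).
4. **Origin tracing** — all-pairwise Spearman correlation (ρ = Pearson on
   midranks) between tumour- and normal-cluster centroid profiles over
   highly variable genes; each tumour cluster's putative origin is its
   best-correlated normal cluster, "exclusive" when the margin over the
   runner-up is ≥ δ.
5. **Trajectory** — a principal curve (alternating projection, per-coordinate
   lowess smoothing and arclength reparameterization) fitted to the
   tr-MSCF/iCAF/myCAF cells' PCA embedding; pseudotime is normalized
   arclength rooted at tr-MSCF, and population ordering is tested by
   rank-sum on pseudotime.

Because the real public accessions are not required, a first-class
**synthetic generator** (`simulate_dataset()`) plants the assumed structure
— mixed-tissue composition with a fibroblast minority, marker programs, and
a latent tr-MSCF → iCAF → myCAF differentiation continuum with
logistic program dynamics on negative-binomial counts — together with
ground-truth labels, so every stage is verifiable at desk scale. See the
methods vignette (`vignettes/cafpaths-methods.Rmd`) for the models,
parameter defaults and their rationale.

## Worked example

```r
library(cafpaths)
report <- run_all(default_config(seed = 1))
print(report)
```

```
caf_run_report
  fibroblast fraction: 0.0816
  chosen k: T1=3, N1=2
  paCAF fraction of CAFs: 0.6844
  taxonomy:
 cluster tissue     label
    T1.1 tumour non-paCAF
    T1.2 tumour      iCAF
    T1.3 tumour     myCAF
    N1.1 normal     tr-RF
    N1.2 normal   tr-MSCF
  ordering iCAF_vs_myCAF: myCAF later (p = 9.68e-27)
  ordering tr-MSCF_vs_iCAF: iCAF later (p = 1.2e-24)
  ordering tr-MSCF_vs_myCAF: myCAF later (p = 7.73e-24)
```

Reading the output: 8.2 % of the ~5,000 simulated cells pass the strict
fibroblast screen (the generator planted 8 %); the elbow rule picks 3
tumour and 2 normal fibroblast clusters; the taxonomy recovers all five
planted populations; 68 % of tumour fibroblasts fall in paCAF clusters
(planted share 65 %); and the pseudotime ordering tr-MSCF < iCAF < myCAF is
recovered with overwhelming rank-sum significance — the in-simulation
analogue of the serial gene-expression transition from MSC-like normal
fibroblasts through inflammatory to myofibroblastic CAFs. The origin map in
`report$origin` shows each paCAF cluster correlating best with the tr-MSCF
cluster and the non-paCAF cluster with tr-RF.

The same analysis, stage by stage with intermediate tables written under
`results/`, is in `analysis/01_simulate.R` … `analysis/07_robustness.R`
(each is a thin `Rscript` driver over the package functions).

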