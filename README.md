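# PanNENmethyl

Methylation-based tumor classification and cell-of-origin analysis for
pancreatic neuroendocrine neoplasms (PanNENs), as an R package.

PanNENs comprise well-differentiated tumors (PanNETs, G1–G3) and poorly
differentiated carcinomas (PanNECs), which are hard to tell apart
histologically but differ sharply in prognosis and treatment. DNA
methylation is inherited through development, so a tumor's CpG methylation
profile retains the signature of its cell of origin. `PanNENmethyl`
implements the analysis chain that exploits this: given beta-value
matrices (probes × samples), probe annotation, sample sheets and
methylated/unmethylated intensity tables, it

- discovers sample groups by **consensus clustering** of the 10K most
  variable probes (Monti-style resampling; consensus index
  `m(i,j) = #co-clustered / #co-sampled`; delta-area CDF rule for k);
- calls **differentially methylated probes** with moderated t-tests on
  M-values (`M = log2(β/(1−β))`), reporting Δβ and log2FC on beta means
  and classifying probes by the dual cut-off (adjusted p < 1e-5,
  |log2FC| > 0.25);
- estimates per-tumor **cell-type signature proportions** by non-negative
  least squares against a reference atlas `A` of sorted alpha/beta/
  acinar/ductal profiles: `x = argmin ‖Ax − b‖₂, x ≥ 0`, proportions
  `p = x/Σx`;
- builds **phylo-epigenetic neighbor-joining trees** on `1 − r` Pearson
  distances over reference-discriminating CpGs and tests clade
  hypotheses (e.g. "NEC-like tumors form a clade with the exocrine
  references");
- infers **copy number** from array intensities: per-probe
  `log2(tumor/normal-panel)` ratios, 5 Mb binning, circular binary
  segmentation with a permutation test, whole-chromosome
  amplification-rich / deletion-rich / low-CNA signatures, focal
  recurrence tables, and regression of FISH counts on chromosome dosage;
- ships a seeded **synthetic-cohort generator** that plants all of the
  above structure (mixtures with known proportions, group DMP blocks,
  island/stem-cell shifts, copy-number segments, FISH counts) with
  machine-readable ground truth, so every stage has a recovery test.

## Worked example

```r
library(PanNENmethyl)
report <- runPipeline(pipelineConfig(seed = 1, outDir = "pannen-run"))
report$clustering$chosen_k
#> [1] 3
report$clustering$ari
#> [1] 1
report$deconvolution$proportion_mae
#> [1] 0.0009087315
report$tree$exocrine_clade
#> [1] TRUE
round(report$cna$fish$r_squared, 3)
#> [1] 0.74
```

On the default synthetic cohort (57 tumors in three groups of 39/14/4
with alpha, acinar and beta origins; 11 sorted-cell references), the
pipeline rediscovers exactly the three planted groups (`chosen_k = 3`,
adjusted Rand index 1 against truth), recovers the planted mixing
proportions to a mean absolute error below 0.001, places the acinar-origin
group in a clade with the acinar and ductal references, and the synthetic
FISH counts track the estimated chromosome dosage at R² ≈ 0.74. The run
also writes `report.json`, cluster labels, the Newick tree, an IGV SEG
file and the ground-truth JSON into `outDir`.

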