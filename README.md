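# sh2profiler

Analysis toolkit for **SH2-domain binding profiles** of cancer cell-line
panels. SH2 (and PTB) domains are the cell's own readers of tyrosine
phosphorylation: probing a lysate with a labelled panel of ~100 GST-SH2
domains measures the global phosphotyrosine (pTyr) signaling state of the
sample. Two assay formats feed the pipeline:

- **Rosette arrays** (reverse-phase dot blots): one background-subtracted
  integrated density per probe per cell line, in four replicate spots, with
  a pervanadate-treated positive-control lysate and a phosphatase-treated
  negative control;
- **Far-Western blots**: per-probe lane profiles aligned to an anti-pTyr
  reference and quantified on a fixed grid of 20 molecular-weight bins
  (291 kDa down to an open `< 22 kDa` bin), giving `probe_bin` features
  such as `p85A_147.5`.

On these matrices the package runs the analyses such profiling studies use
to classify tumor cells and screen for drug-response biomarkers:

- **Filtering**: probes whose positive-minus-negative control difference is
  below `k_sd` negative-control standard deviations are dropped; bands are
  kept only when their across-line standard deviation exceeds 5 *and* at
  least 11 of 22 lines exceed intensity 5.0.
- **Two-way hierarchical clustering** with *uncentered correlation*
  (cosine similarity without mean subtraction, `d = 1 - Σxy/(‖x‖‖y‖)`) and
  complete ("full") linkage, with Cluster 3.0 / Java TreeView export
  (CDT/GTR/ATR).
- **Permutation cluster enrichment**: is a cluster of k lines containing x
  mutants surprising, given K mutants among N lines? Label permutations
  (with add-one smoothing) are cross-checked against the closed-form
  hypergeometric tail `P[X ≥ x]`.
- **Biomarker screens**: per-feature two-sided Mann-Whitney tests against
  dichotomous labels (EGFR mutation, MET activation) with Storey q-value
  FDR control (`q ≤ 0.1` significant), and Pearson correlation of binding
  against `ln IC50` with an `|r| > 0.5` flag.
- **Dose-response**: four-parameter logistic fits
  `y = d + (a − d)/(1 + (x/c)^b)` by Levenberg-Marquardt with multi-start,
  IC50 = `c`, and sensitivity classes (`< 10 nM` sensitive, `10–1000 nM`
  intermediate, `> 1000 nM` resistant).
- **TKI perturbation analysis**: `log2(treated/untreated)` fold changes,
  waterfall rankings, mean fold change per probe family (RAS activators,
  PI3Ks, Crk, Nck), change-significance flags (`p ≤ 0.125`), fold-change
  clustering and condition-correlation matrices.

A seeded **synthetic-data generator** (`make_cohort()`, `binding_truth()`,
`simulate_rosette()`, `simulate_lanes()`, `simulate_treatment()`,
`simulate_dose_response()`) emulates the whole study — 96-probe panel, 22
lines, genotype-driven effects, Gaussian far-Western bands, 4PL viability
curves — with known ground truth, so every stage is testable without any
raw blot image.

## Worked example

```r
library(sh2profiler)
library(dplyr)

panel   <- sh2_panel()                       # 94 SH2 + ShcA PTB + GST
cohort  <- make_cohort(22, 7, 9, 6, seed = 1)
truth   <- binding_truth(panel)              # known effect sizes
rosette <- simulate_rosette(panel, cohort, truth, n_replicates = 4, seed = 2)

report <- filter_probes_by_controls(rosette, k_sd = 2)
report
#> Filter report: 71 retained, 25 removed
#> thresholds: k_sd=2, positive=pos_control, negative=neg_control

mat <- apply_filter(
  select(average_replicates(rosette), -pos_control, -neg_control), report)

egfr <- setNames(cohort$egfr == "mutant", cohort$line_id)
hits <- significant_features(mann_whitney_screen(mat, egfr),
                             q_max = 0.1, pi0 = 1)
select(hits, feature, mean_pos, mean_neg, p, q, direction)
#> # A tibble: 7 × 6
#>   feature   mean_pos mean_neg        p       q direction
#>   <chr>        <dbl>    <dbl>    <dbl>   <dbl> <chr>
#> 1 Brk          4757.     907. 0.000247 0.00351 higher_in_positive
#> 2 CblA         5225.     880. 0.000247 0.00351 higher_in_positive
#> 3 CblB         4486.    1013. 0.000247 0.00351 higher_in_positive
#> 4 Txk          4621.     981. 0.000247 0.00351 higher_in_positive
#> 5 ShcA(ptb)    4096.     947. 0.000247 0.00351 higher_in_positive
#> 6 Grap2        4526.    1043. 0.000324 0.00384 higher_in_positive
#> 7 Grb2         7842.    1340. 0.000716 0.00726 higher_in_positive
```

The seven hits are exactly the probes the generator elevated in EGFR-mutant
lines (+2 log2 units); `mean_pos`/`mean_neg` are group means of binding
intensity, `q` the FDR-adjusted significance.

Clustering and enrichment:

```r
tree <- hcluster(median_center_rows(mat), axis = "samples")
cl   <- cut_tree(tree, k = 4)
ras  <- setNames(cohort$ras != "wt", cohort$line_id)
members <- cl$item[cl$cluster ==
                     names(which.max(table(cl$cluster[ras[cl$item]])))]
cluster_enrichment(members, ras, n_perm = 100000, seed = 3)
#> Cluster enrichment: 8/8 labelled in cluster of 8 (N=22, K=9)
#>   permutation p = 7e-05 (n_perm = 100000), exact p = 2.815e-05
```

All RAS-mutant lines co-cluster (the generator depresses their global pTyr
signal), and the permutation p agrees with the hypergeometric tail.

Dose-response:

```r
fit_4pl(simulate_dose_response(50, noise_sd = 0.05, seed = 4))
#> 4PL fit: IC50 = 47.31, hill = 1.08, top = 1.02, bottom = 0.0394 (rss 0.0357, n 24)
```

`run_pipeline(pipeline_config(seed = 1))` chains all stages
(simulate → quantify → preprocess → cluster → associate → perturb), writes
every stage product as TSV/JSON under the configured output directory and
returns a manifest of checksums, so a rerun with the same config and seed
is verifiably identical.

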