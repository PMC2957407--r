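---
title: "SH2 binding-profile analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SH2 binding-profile analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sh2profiler)
library(dplyr)
```

# The measurement and its model

SH2 profiling reads a cell's global tyrosine-phosphorylation state through
the binding of a panel of GST-SH2/PTB domain probes. Chemiluminescent
detection makes the raw signal multiplicative: probe affinity, lysate
amount, exposure and biological effects all act as factors. The package
therefore models intensity on the log2 scale,

$$\log_2 I_{ps} = \beta_p + \sum_k \delta_{pk}\,x_{sk} + u_s +
\varepsilon_{psr},$$

with per-probe baseline $\beta_p$, additive label effects $\delta_{pk}$
(EGFR mutation, RAS mutation, MET activation; $x_{sk}\in\{0,1\}$ per
sample), a line-level factor $u_s \sim N(0, \sigma_\ell^2)$ shared by all
probes of a sample, and replicate noise
$\varepsilon \sim N(0, \sigma^2)$. Working in log2 keeps downstream
fold-change analysis linear and matches how perturbation effects are
reported (log2 treated/untreated).

## The synthetic generator as study stand-in

`make_cohort()` and `binding_truth()` encode the conditions the analyses
are designed for:

- **22 cell lines**, of which 7 EGFR-mutant, 9 RAS-mutant (one of them
  NRAS rather than KRAS) and 6 MET-activation-positive; EGFR mutants draw
  TKI-sensitive IC50 values (log-normal around 5 nM), RAS mutants
  resistant ones (around 3000 nM), others intermediate (around 150 nM).
  The IC50 location parameters are our choice of realistic class centers,
  placed well inside the sensitive/intermediate/resistant windows so that
  class membership, not the draw noise, drives simulated drug response.
- **96 probes**: 94 SH2 domains, the ShcA PTB domain, and GST alone.
  Seven probes — Grb2, ShcA(ptb), Grap2, Brk, Txk, CblB, CblA — carry a
  +2 log2 effect in EGFR-mutant lines; MET activation adds +1.5 log2 on a
  broad probe set (half that in intermediate lines); RAS mutation
  depresses every pTyr-dependent probe by 1 log2 unit. The RAS magnitude
  is a modelling placeholder (global depression is reported only
  qualitatively in this assay literature), exposed as `ras_delta`.
- **26 low-signal probes** (GST plus 25 unnamed panel members) have no
  pTyr-dependent signal at all: their positive- and negative-control
  intensities coincide up to noise, so roughly half show a negative
  control difference. This is the structure the control-based filter is
  calibrated against (26 of 96 removed leaves the 70-probe analysis
  panel).
- **Noise defaults**: replicate sd 0.5 log2 units and line factor sd 0.5
  log2 units. With four replicates this yields per-line mean CVs around
  0.35, typical of replicated dot-blot densitometry.
- **Controls**: the negative control (phosphatase-treated lysate) is pure
  background; the positive control (pervanadate-treated lysate mix) sits
  at each probe's maximum effect state plus a 2 log2 boost, so it
  dominates every sample in expectation.

What the generator does *not* emulate: spatial blot artifacts, scanner
saturation, batch effects between the two duplicate experiments, probe
cross-reactivity, and any correlation between MET activation and
genotype. Passing tests therefore demonstrate the *statistical machinery*
recovers known truth under a faithful noise model — not that real blots
are free of the artifacts the model omits.

## Far-Western lanes and the molecular-weight grid

Lanes are simulated as sums of Gaussian bands on the molecular-weight
axis (sd 4 kDa) over a migration axis uniform in log(MW) — the standard
SDS-PAGE behaviour — plus nonnegative baseline noise. The default catalog
places an EGFR-family band at 185 kDa and a MET-associated band at
145 kDa; amplitudes follow the same log2 effect model as the rosette.

Quantification uses a fixed 20-bin grid whose boundaries form a geometric
ladder $b_i = 291\,r^i$ with $r = (22/291)^{1/19}$. This single rule
reproduces all three landmark labels the assay convention prints: the top
bin spans ~254–291 kDa (printed "256–291"), bin 4 is labelled 193.6
("MW194", where EGFR-family receptors run), and bin 6 is 147.5 ("MW148",
where the 145 kDa MET band falls). The grid is configurable via an
explicit boundary vector. Binning conventions: positions are 0-based,
bins 1-based from the largest MW; each bin is lower-inclusive /
upper-exclusive; MW at or above 291 kDa is clamped into bin 1 with a
warning (gels do not resolve above it); the bottom bin is open
(< 22 kDa). Binning partitions the axis, so bin totals conserve the
profile mass exactly.

Alignment to the anti-pTyr reference lane uses integer shifts only
(rigid translation, the way scanned blots are registered), chosen to
maximize cross-correlation within ±`max_shift` positions; a flat
reference is an error, and an optimum on the window edge is flagged.

# Filtering rules

- **Band filter**: keep a band iff its across-line *sample* (n−1)
  standard deviation exceeds 5 **and** at least 11 of 22 lines exceed
  intensity 5.0, both evaluated on raw (uncentered) values. The sample-sd
  convention is chosen because it is the spreadsheet default and makes
  the boundary case (eleven 10s, eleven 0s → sd ≈ 5.12) pass; population
  sd is available by passing precomputed thresholds. The filter is
  idempotent and its report partitions the features exactly.
- **Control filter**: drop a probe when mean(positive) − mean(negative)
  ≤ `k_sd` × sd(negative replicates). `k_sd = 2` by default; probes whose
  positive control falls below the negative are dropped at any threshold.
  Because the rule behind the historical 26-of-96 removal is not
  published, `calibrate_control_filter()` searches `k_sd` to match a
  target removal count and reports the value found — a reconstruction,
  and documented as such.
- **Missing values** propagate (never imputed); statistics skip features
  with fewer than 3 observed samples, with a reason code.

# Clustering

"Full linkage with uncentered correlation" is Cluster 3.0 terminology:
complete (maximum) linkage on $d = 1 - \sum x y / (\|x\|\|y\|)$, computed
*without* mean subtraction, range [0, 2]. The distance is scale-invariant
per item, so clustering is unaffected by per-probe rescaling — appropriate
for intensities with arbitrary per-probe gains. Missing values are
handled pairwise-complete; items sharing fewer than 3 observations with
every partner, or with zero norm, are excluded and reported. The
agglomeration is delegated to `stats::hclust`, and the test suite holds
it against a from-scratch brute-force agglomerator on random small
matrices, so the two routes stay independent. Complete linkage guarantees
monotone merge heights (no inversions).

Both axes are clustered independently on the same median-centered matrix.
Row medians are centered for clustering and display; this is the one
point where the historical description is ambiguous ("no normalization"
vs "median-centered"), so centering is an explicit, separate step the
caller controls. Dendrogram cutting (`cut_tree()`) is by explicit k or
height — cluster identities are never inferred automatically, since the
reference analyses chose clusters by inspection.

**Cluster enrichment.** For a fixed cluster of $k$ samples containing $x$
label-positives out of $K$ in a panel of $N$: the label vector is
permuted `n_perm` times (add-one smoothing,
$p = (1 + \#\{x^{perm} \ge x\})/(1 + n_\text{perm})$, so $p$ is never 0),
and the exact hypergeometric upper tail is reported alongside. Permuting
labels with the cluster fixed is exchangeable with re-drawing the
cluster, and the permutation estimate converges to the hypergeometric
tail; tests assert agreement within 3 binomial standard errors. For the
landmark configuration ($N=22$, $K=9$, $k=x=6$) the exact tail is
$\binom{9}{6}/\binom{22}{6} = 84/74613 \approx 1.13\times10^{-3}$, which
prints as 0.001 at 3 decimals.

# Biomarker screens

**Mann-Whitney.** Two-sided throughout (effects in either direction are
of interest). The exact null distribution is used when $n_1+n_2 \le 12$
and the data are tie-free; otherwise the tie-corrected normal
approximation with continuity correction. The exact path is verified
against complete enumeration over all partitions up to $n_1+n_2 = 10$.
Group means and standard errors accompany each record; direction is
`higher_in_positive`/`lower_in_positive`.

**q-values.** Storey's estimator: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.95$, smoothed with a df-3 cubic spline and read
off at $\lambda = 0.95$, then step-up
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With $\pi_0$ forced
to 1 this is exactly Benjamini-Hochberg, and that is also the automatic
fallback below 100 p-values — a ~70-probe rosette screen is too short for
a stable smoother, so its results are reported in BH mode unless the
caller overrides `pi0`. Significance is `q ≤ 0.1` (10% FDR).

**MET dichotomization** folds the intermediate category into "low" (only
clear positives count as high). **Activation categories** from
percent-of-maximum marker signal use marker-specific cutoffs — MET:
positive > 50%, intermediate 25–50%, negative < 25%; pTyr MW194:
positive > 25%, intermediate 10–25%, negative < 10% — with boundaries
belonging to the intermediate class (the ranges are quoted inclusively),
so the three classes partition [0, 100] without gaps.

**Correlation screen.** Pearson r of each feature against natural-log
IC50 (log base configurable); negative r means higher binding in more
sensitive lines. `|r| > 0.5` is flagged. Constant features are reported
as missing rather than dropped silently.

# Dose-response fitting

The 4PL $y = d + (a-d)/(1+(x/c)^b)$ is fitted to all replicate points
jointly (not to dose means) by Levenberg-Marquardt. Initialization:
$a = \max y$, $d = \min y$, $c$ at the geometric mid-dose, and both
$b = +1$ and $b = -1$ starts, keeping the lower-RSS fit — the slope sign
ambiguity is the one real multi-modality on 8-point curves. The fitted
curve is canonicalized to $a \ge d$ (the parameterization is invariant
under swapping asymptotes with $b \to -b$). $c$ is constrained to
[min dose/10, max dose×10]: outside that range the data carry no
information about the inflection and unbounded fits wander. Flat
responses are a hard error; hitting the $c$ bound sets a flag. Noise-free
curves are recovered to numerical precision; under additive viability
noise of sd 0.05 with 8 doses and 3 replicates the median relative IC50
error is below 10% (tested over 500 seeded curves). Sensitivity classes:
IC50 < 10 nM sensitive, 10–1000 intermediate (boundaries inclusive),
> 1000 resistant.

# Perturbation analysis

Fold changes are $\log_2((T + f)/(U + f))$ with floor $f$ = 1% of the
matrix-wide positive median intensity — small enough not to distort
mid-range values, large enough to bound fold changes where both signals
are near zero (0/0 maps to 0). The floor is configurable and recorded as
an attribute.

Family summaries average fold changes over the RAS-activator (Grb2,
Grb2(SH23), Grap, Grap2, ShcA, ShcA(ptb)), PI3K (p85A, p85B, p55G), Crk
(Crk, CrkL) and Nck (Nck1, Nck2) groups. The generator's default
inhibition shifts are negative for RAS activators, PI3Ks and Crks and
positive for Ncks, scaled by the line's sensitivity class; the class
scale factors (1, 1.6/3.1, 0.8/3.1) are set so that a fully sensitive,
intermediate and resistant line show RAS-activator means of −3.1, −1.6
and −0.8 log2 units under the EGFR inhibitor — the canonical gradient
this analysis is meant to display — and noiseless recovery of those
values is exact.

The per-feature change test between treated and untreated replicates is
an exact Mann-Whitney (the test family used everywhere else here; the
original threshold's test is unnamed), flagged at `p ≤ 0.125`, and
flagged features are summarized by median fold change and MAD. Condition
columns (line × treatment) can be clustered with the same machinery as
the primary matrices; `simulate_treatment()`'s optional per-(probe, line)
response profile — a property of the line, drawn from its own seed so
both treatments share it — reproduces the qualitative finding that a
line's two TKI conditions pair together before any cross-line pair.

# Numerical and reproducibility choices

- All randomness flows from explicit integer seeds through one helper
  that saves and restores the global RNG state; no function leaves RNG
  side effects. Derived stage seeds stay below $2^{31}$.
- Merge tie-breaks in `stats::hclust` are deterministic for a fixed
  distance matrix, and the oracle comparison is on sorted merge heights,
  which are invariant to tie order.
- `run_pipeline()` writes a manifest of SHA checksums for every stage
  output; identical config + seed reproduces identical checksums.
- Problem sizes in the tests are the study's own: 22 lines, 96 probes,
  720 bands, 100,000 permutations, 200-seed power loops, 500 fitted
  curves — chosen to exercise the methods at realistic scale while a full
  run of the suite stays in the minutes range.

# Known limitations

- The control-difference filter is a reconstruction; only its calibrated
  removal count is anchored, not the underlying statistic.
- $\pi_0$ estimation on short p-value vectors is unstable by nature; the
  BH fallback is deliberately conservative.
- The far-Western simulator draws band amplitudes independently per
  probe; real blots share lane-level exposure effects that would add
  correlation between bins of the same lane.
- No batch-effect correction or between-blot normalization is provided —
  the pipeline assumes inputs already on a common scale, as its reference
  workflow did.
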