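---
title: "Methods: stage-wise metabolic network analysis for paired tumor metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-wise metabolic network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metnam)
```

# Scope and data model

`metnam` analyzes LC–MS peak tables from paired tumor/adjacent tissue
cohorts. The unit of data is a `peak_table`: a samples × metabolites matrix
of non-negative MS responses together with sample metadata (patient id,
tissue type, tissue weight, TNM stage, clinical indices) and metabolite
annotations (chemical class, assigned internal standard, ionization mode).
All downstream results reference metabolite and sample *ids*, never
positions, and input order is preserved throughout. Raw spectra processing
(peak picking, MS² annotation) is out of scope: the pipeline starts from an
integrated, annotated peak table.

# Normalization and quality control

Tissue responses are normalized as

$$\tilde{x}_{sj} = \frac{x_{sj}}{\mathrm{IS}_{s,a(j)} \cdot w_s},$$

where $\mathrm{IS}_{s,a(j)}$ is the response of metabolite $j$'s assigned
spiked internal standard in sample $s$ and $w_s$ the tissue weight in mg;
pooled QC samples carry no weight and are normalized by internal standard
only. Dividing by a same-sample standard makes the result invariant to any
per-sample multiplicative factor (injection volume, ionization drift), which
the tests assert exactly. A zero or missing standard response flags the
affected cells missing rather than aborting the run; a non-positive weight
is a hard error because it indicates corrupted metadata.

Platform stability is summarized by the per-metabolite relative standard
deviation over pooled QC injections, $\mathrm{RSD} = 100\,s/\bar{x}$ with
the sample ($n-1$) standard deviation, reported as the fractions of
metabolites below 20% and 30%. RSD evaluation is reporting-only by default —
the summary does not remove metabolites — because the protocol it follows
reads as a quality report, not a filter; a filter can be applied manually
from the returned table.

Missing values follow a common metabolomics default, stated rather than
inherited: metabolites missing in more than 50% of samples (configurable)
are dropped, and remaining gaps are imputed with half the metabolite's
observed minimum as a limit-of-detection surrogate.

# Univariate screen

Tumor vs adjacent contrasts use the Wilcoxon signed-rank test on patient
pairs. Zero differences are dropped (the classical convention). With at
most 12 non-zero differences the two-sided p-value comes from full
enumeration of all $2^n$ sign assignments, which stays valid under tied
absolute differences where the tabulated signed-rank distribution does not;
larger samples use the tie-corrected normal approximation with continuity
correction. The 12-pair switchover keeps enumeration below 4096 assignments
per test. Group contrasts (clinical indices, scanned as all pairwise binary
contrasts of each categorical index on tumor-tissue values) use the
Mann–Whitney test with the same exact-below-12 policy. False discovery is
controlled by Benjamini–Hochberg step-up q-values (Benjamini–Yekutieli
available); BH is the default of the differential-correlation and
web-platform tools this pipeline parallels.

The fold change is defined as $\log_2$ of the *median of per-pair
tumor/adjacent ratios*. The source protocol reports directions without
defining a fold change; the per-pair median respects the paired design and
is robust to single outlying pairs.

Pathway over-representation is the upper-tail hypergeometric test of the
overlap between selected metabolites and user-supplied pathway sets (GMT
format), BH-corrected across pathways, with minimum pathway size 1.
Topology-weighted pathway impact (relative betweenness centrality over
curated pathway graphs) is deliberately not implemented: it requires
external pathway topologies, and the enrichment here is set-based only.

# PLS-DA

Classification uses NIPALS PLS1 on the ±1-encoded class with X-deflation
per component; prediction is the sign of the regression score. Auto-scaling
(mean-center, unit sample variance) is the only scaling applied. Component
selection maximizes $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ from stratified
5-fold cross-validation; scaling is refit inside each training fold so no
held-out information leaks into the model. Permutation validation refits
the full CV protocol under `B` label permutations (default 2000) and
reports $p = (\#\{Q^2_{perm} \ge Q^2_{obs}\} + 1)/(B+1)$, whose analytic
floor $1/(B+1) \approx 0.0005$ at $B = 2000$ is asserted in the tests. The
permutation statistic is $Q^2$ at the chosen component count by default;
cross-validated accuracy is available because web implementations of this
protocol offer several statistics without always naming the one used.

# Differential correlation network

For each metabolite pair, Spearman correlations are computed separately in
the two tissue groups (average ranks under ties; p-values from the
$t$ approximation, or exact permutation enumeration for $n \le 8$) and
compared with the Fisher-z statistic

$$z = \frac{\operatorname{atanh}\rho_A - \operatorname{atanh}\rho_B}
{\sqrt{1/(n_A-3) + 1/(n_B-3)}},$$

the convention of differential-correlation packages when applied to rank
correlations; the Fieller variance inflation $1.06/(n-3)$ is available
behind a flag. Pairs with BH-FDR < 0.05 form the undirected differential
network, edges annotated as correlation gain or loss from group A to B,
connected components reported as modules, and nodes ranked by degree with
ties sharing the better rank. The paired structure of the cohort is ignored
in this test — groups are treated as independent, as the established
differential-correlation tooling does — and this is a known approximation.
No within-group significance pre-filter is applied before the differential
test (the tooling's default); a flag exposes it.

# Acylcarnitine ratio panel

Eight ratios act as read-outs of mitochondrial β-oxidation enzymes:
(C16+C18)/C0 (CPT1), C14:1/C16 (inverse VLCAD), C4/C3 (inverse SCAD),
C2/C0, C8/C10 (inverse MCAD), and C10-OH/C10, C8-OH/C8, C4-OH/C4 (inverse
ECHS1). Each per-sample ratio is a quotient of summed normalized responses,
so per-sample normalization errors cancel exactly; the panel is tested
tumor vs adjacent with the paired Wilcoxon test. Missing any component of a
summed numerator or denominator marks the ratio missing for that sample (no
partial sums). An alias map normalizes the mixed acylcarnitine spellings
found in annotation sheets (`carnitine C4_0-OH`, `C4-OH`, `C8:0`). The
panel is a descriptive proxy: no claim about enzyme kinetics is made.

# Biomarker discovery and validation

Patients — never individual samples — are split 4:1 into discovery and
validation sets, so both members of a pair stay together. Candidate markers
are ranked by discovery-set p-value (ties: larger |log2 fold change|, then
id). Marker combination is a logistic regression on auto-scaled discovery
values (the combination rule is this package's stated choice; the protocol
it follows does not name one), scored by the linear predictor; under
perfect separation the score falls back to an AUC-oriented sum of scaled
markers with a warning. AUC uses the pair-counting (Mann–Whitney) identity,
with a trapezoidal ROC integration kept as an independent implementation
for cross-checking. The operating threshold is Youden-optimal on discovery
and applied unchanged to validation. The unit of ROC analysis is the tissue
sample (tumor vs adjacent), both members of each pair entering. An
information-leakage test asserts that perturbing validation samples changes
only validation metrics.

# Stage-wise network topology

For each TNM stage $t \in \{I, II, III\}$, a weighted network $G_t$ on the
common metabolite set carries edge weight $w_t = \rho_t$ (the stage-t
Spearman correlation) when the correlation is significant at $p < 0.01$,
and $w_t = 0$ otherwise — the zero participates as such downstream. Stages
with fewer than 5 tumor samples are excluded; on the emulated cohort
(13/24/39/4) this retains I–III. The monotone subnetwork $SG_t$ keeps the
edges of $G_t$ whose weight triple $(w_I, w_{II}, w_{III})$ (1) changes
monotonically, where an adjacent-stage change of at most 0.02 counts as
equality, and (2) differs by more than 0.05 in at least one adjacent stage
pair. The two written conditions — a difference filter and a monotonicity
filter — are implemented as one composed predicate, since the difference
filter's set is a superset of the final edge set. The 0.02 tolerance is
implemented as *relaxed comparisons* (each step may violate the monotone
order by at most 0.02); a strict mode drops the tolerance for sensitivity
analysis. Monotonicity is evaluated on signed weights, not magnitudes.

Hubs are the top 15 nodes per stage by degree within $SG_t$, with all nodes
tied at the 15th degree value included (deterministic and
order-independent); the hub set is the union over stages. For each hub $v$,
the informative triplet is the three star subgraphs of $v$'s incident edges
in $SG_I, SG_{II}, SG_{III}$, with per-edge correlation signs. An
adjacent-tissue reference network at the same alpha is attached for display
parity only.

Two properties of the edge rules are worth knowing. First, an edge
significant **only** in stage II is rejected (its triple $(0, w, 0)$ is
non-monotone), but an edge significant only in stage I or III passes (its
triple is a monotone step), so single-stage noise edges at the extreme
stages enter the subnetworks at roughly twice the per-stage false-positive
rate of the $p < 0.01$ filter. Recovery simulations therefore show high
sensitivity for planted monotone trajectories alongside a substantial
fraction of single-stage background edges among reported edges; hub and
triplet summaries, which concentrate on high-degree structure, are the
robust read-out. Second, because membership in $SG_t$ additionally requires
presence in $G_t$, an accepted trajectory like $0.8 \to 0.5 \to 0$ appears
in $SG_I$ and $SG_{II}$ but not $SG_{III}$.

# Synthetic cohorts and what they do (and do not) show

The generator emulates the cohort the pipeline targets: 80 patients with
paired tumor/adjacent samples, TNM counts 13/24/39/4, 234 metabolites
spread over the field's chemical classes with the ratio-panel
acylcarnitines always present, spiked internal standards, log-normal tissue
weights near 10 mg, and one pooled QC injection per 10 tissue samples with
multiplicative noise tuned to a 10% target RSD.

Latent log-intensities are drawn from a Gaussian copula. Correlation
targets are stated on the Spearman scale and mapped to the latent Pearson
parameter by the closed form $r = 2\sin(\pi\rho_s/6)$, avoiding calibration
loops; rank correlations are invariant to the exponentiation that follows.
Planted structure comes in two shapes: explicit pairs, and hub stars
realized through a single latent factor (hub = factor, partner loadings
from the target), which guarantees positive-definite blocks at any star
size — at the cost of implied partner–partner correlations equal to the
product of loadings. Tumor samples are stratified by stage with
stage-specific targets; adjacent samples get their own target (default 0).
About 55% of metabolites carry a planted tumor effect with |log2FC| drawn
from [0.5, 2] — the screened differential fraction the defaults aim to
emulate is a little over half of the panel; effect magnitudes are exposed
in the configuration because the emulated protocol reports none. Default
planted stars: a decreasing choline-centered star (0.8 → 0.5 → 0.1), an
increasing hydroxybutyrylcarnitine-centered star (0.3 → 0.55 → 0.8), and a
stage-constant long-chain FFA star present in tumor only, which feeds the
differential-correlation network but is invisible to the monotone filter.

Raw responses are assembled as latent intensity × assigned-standard
response × tissue weight, so `normalize_intensities()` recovers the latent
values exactly — with zero biological noise this is an exact end-to-end
identity, asserted in the tests. The generator does **not** simulate
chromatographic drift, batch effects, adducts, censored (left-truncated)
intensities, or heterogeneous per-metabolite QC variance; passing recovery
tests on these cohorts therefore demonstrates correctness of the
statistical machinery under its stated assumptions, not robustness to every
artifact of real LC–MS data.

# Numerical and design choices

* Exact-vs-approximate switchovers: signed-rank/rank-sum enumeration up to
  n = 12; Spearman exact permutation p up to n = 8 (memoized over all n!
  orderings of the observed, possibly tied, ranks).
* Two-sided exact p-values double the smaller tail and cap at 1.
* Constant columns: dropped with a warning before scaling (PLS-DA);
  correlations recorded as missing with a warning (networks).
* Hub ties and degree ties always resolve by inclusion or shared rank —
  no order-dependent selections anywhere.
* Cross-validation folds are stratified by class and fully determined by a
  recorded seed; every stochastic step (cohort generation, splits,
  permutations) takes an explicit seed and restores the caller's RNG state.
* Stage IV tumor samples reuse the stage-III correlation targets in the
  generator (too few patients to carry their own stable structure, matching
  the cohort design that excludes stage IV from network analysis).
* Problem sizes in the test-suite simulations (e.g. null calibration at
  n = 100 × 50 metabolites; component recovery at n = 80 × 20; 100
  brute-force network instances of ≤ 12 nodes) were chosen once as the
  smallest designs at which the checked properties are stable, and are
  stated in the tests.

# Known limitations

* The differential-correlation test ignores pairing between groups.
* Set-based enrichment only; no pathway-topology weighting.
* The monotone edge rules admit single-extreme-stage noise edges (see
  above); interpret edge-level output through hubs and triplets.
* Biomarker combination is limited to the two-marker logistic score the
  protocol reports; no multi-marker panels or bootstrap AUC intervals.
* The generator's QC noise is homogeneous across metabolites, so QC RSD
  summary fractions on synthetic cohorts are near 100% below both
  thresholds rather than the low-90s typical of real platforms.

# A worked micro-example

```{r example, eval = FALSE}
co <- generate_cohort(synthetic_config(
  n_patients = 20, stage_counts = c(I = 7, II = 7, III = 6),
  n_metabolites = 60, seed = 1))
pt <- handle_missing(normalize_intensities(co$peak_table))
diff <- differential_analysis(pt)
nam <- nam_analysis(pt)
rat <- compute_ratio_panel(pt)
```

The full orchestration, including report bundles and a provenance manifest,
is `run_pipeline(pipeline_config(...))`; `scripts/acceptance.R` runs it at
the emulated study scale and serializes the headline numbers.
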