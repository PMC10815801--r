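---
title: "Methods: aptamer panel discovery and evaluation with aptapanel"
author: "aptapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aptamer panel discovery and evaluation with aptapanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptapanel)
```

# Scope

`aptapanel` implements the in-silico analysis chain of a whole-cell SELEX
aptamer campaign against a tumor cell line, from raw sequencing reads to
candidate diagnostic panels and candidate protein targets:

1. **SELEX enrichment** — per-round FASTQ quality trimming, length
   filtering, exact-sequence frequency tables, and nomination of the most
   abundant final-round sequences as candidate aptamers.
2. **Binding affinity** — saturation-binding fits of flow-cytometry
   dose-response data, reporting the dissociation constant Kd.
3. **Panel diagnostics** — sensitivity/specificity/accuracy of aptamers and
   aptamer panels scored on a labeled tissue cohort, with stratified
   recognition summaries.
4. **Target shortlisting** — a three-stage proteomic filter cascade
   (fold change, membrane evidence, cross-line expression phenotype).
5. **Trajectory analytics** — Kabsch superposition RMSD, GROMOS
   conformational clustering, and hydrogen-bond occupancy for
   molecular-dynamics post-processing.

Every input the chain consumes can be simulated with known ground truth
(`gen_selex_rounds()`, `gen_binding_curve()`, `gen_recognition_cohort()`,
`gen_proteomic_tables()`, `gen_trajectory()`), so each stage is testable
without access to unpublished raw data.

Deliberately out of scope: flow-cytometry event gating and FCS parsing,
secondary/tertiary structure prediction, the MD engine itself, docking, and
MM/GBSA energetics. Those stages rely on external engines and servers whose
outputs this package treats as upstream inputs.

# SELEX read processing

## Sliding-window trimming

Reads carry per-base Phred scores. `sliding_window_trim()` scans windows of
`window` bases (default 4) left to right; at the first window whose **mean**
quality drops below `mean_quality_threshold` (default 20, the conventional
`SLIDINGWINDOW:4:20` setting) the read is truncated immediately before that
window's first base, and any trailing bases of the kept prefix individually
below the threshold are then dropped. Reads shorter than one window are kept
whole only if their overall mean meets the threshold. These semantics are
fully specified here — rather than delegated to an external trimmer — so
results are bit-reproducible. Two properties follow directly and are
enforced by tests: the output is always a prefix of the input, and raising
the threshold never lengthens the output.

Published descriptions of this trimming step sometimes quote the option
string (threshold 20) alongside prose mentioning Q30; the two disagree. The
package defaults to 20 and exposes the threshold as an explicit parameter so
either convention can be requested.

After trimming, `length_filter()` removes reads below `min_length`
(default 74 nt, i.e. a 76-nt library tolerating at most two clipped bases).
Counting is exact string matching of full surviving reads
(`count_frequencies()`); no near-duplicate clustering or reverse-complement
merging is attempted, because no edit-distance collapsing rule is part of
the published procedure. `rank_candidates()` sorts by final-round count with
lexicographic tie-breaks — a deterministic rule that makes top-k nomination
reproducible — and reports per-round frequency trajectories and
round-over-round enrichment ratios (flagged `NA` when the previous round has
frequency zero).

An open question in the source procedure is whether only full-length 76-nt
reads or all ≥ 74-nt survivors were counted; the package counts all
survivors, which is the more inclusive reading.

# Saturation-binding model

The response at aptamer concentration $X$ (nM) is modeled as total binding

$$y(X) = \frac{B_\max X}{X + K_d} + NS \cdot X + \mathrm{Background},$$

with maximal specific binding $B_\max$ (response units, e.g. MFI), the
dissociation constant $K_d$ (nM), a nonspecific linear slope $NS$ and a
signal floor. All four parameters are constrained nonnegative ($K_d > 0$).

`fit_kd()` minimizes the unweighted residual sum of squares (per-observation
weights are available as an option). Control rows are used for
initialization only: zero-aptamer controls estimate the Background prior and
an initial-library control at a known dose estimates an NS prior
(`estimate_background()`). The library control is *excluded* from the
least-squares residual because it follows the nonspecific line only — it has
no saturable term — and mixing it into the saturation model would bias every
parameter.

## Numerical strategy

The 4-parameter objective is multimodal: $B_\max/K_d$ trade-offs against the
linear $NS$ term create distinct local basins, and single-start
Levenberg-Marquardt demonstrably lands in the wrong one on some noisy data
sets. The fit therefore proceeds in three stages:

* **Variable-projection scan.** For fixed $(K_d, NS)$ the model is linear in
  $(B_\max, \mathrm{Background})$, so a coarse grid — 40 log-spaced $K_d$
  values spanning a decade beyond the dose range, 7 $NS$ values from 0 to
  the maximal data slope — with closed-form linear least squares locates the
  global basin cheaply.
* **Bounded Levenberg-Marquardt** (`minpack.lm::nlsLM`) from the
  variable-projection seed plus a small set of principled starts
  ($B_{\max,0}$ = response range, $K_{d,0}$ over dose quantiles, $NS_0$ from
  the control prior), keeping the lowest RSS.
* **Bounded quasi-Newton polish** (`optim` L-BFGS-B), because LM can stall
  when parameters sit exactly on the $[0, \infty)$ bounds.

Standard errors come from the analytic Jacobian at the final parameters.
Degenerate data (flat responses) return a converged flat fit with the Kd
flagged unidentifiable rather than a fabricated estimate; fits with
vanishing $B_\max$ carry the same flag. Fits require at least three distinct
positive doses.

Because replicate spread and fit standard error answer different questions,
`kd_replicate_fits()` reports both, labeled: the mean ± SD of Kd over
independent per-replicate fits (the conventional presentation) and the
pooled fit with its Jacobian-based SE.

## Recovery characteristics

The package's simulation study uses the assay's dose ladder
{25, 50, 100, 200, 400} nM with three replicates and truth
$B_\max = 100$, $K_d = 150$ nM, $NS = 0$, Background $= 0$ — the package's
own worked-example parameterization, with the Kd chosen inside the
100–200 nM range typical of unmodified cell-binding aptamers. Noiseless
curves invert to machine-level accuracy; with Gaussian noise of 2% and 5% of
$B_\max$ the median relative Kd error over 100 simulated data sets is about
0.08 and 0.2 respectively. Those numbers are a property of the design (five
doses spanning only ~2.7 × Kd, four free parameters), not of the optimizer:
coarse grid searches confirm the fits sit in the global basin. Published
Kd point estimates from actual assays are not reproducible here because the
underlying MFI records are not public; the simulation study is the testable
surrogate.

# Panel diagnostics

A cohort is a data frame of samples (class `adjacent`, `primary_tumor`, or
`metastatic`; molecular subtype; stage; grade; TNM) with one ordinal
staining-intensity column per aptamer (0 none, 1 `(+)`, 2 `(++)`,
3 `(+++)`).

* **Positivity** is intensity ≥ threshold, default threshold 1 (any
  staining). This is the only rule consistent with published index tables in
  which adjacent tissue showing `(+)` counts against specificity.
* **Tumor pooling**: primary and metastatic samples are pooled as "tumor"
  for cohort-level indices (90 tumor vs 10 adjacent in the worked example);
  again the only pooling that reproduces the published indices.
* **Indices**: sensitivity $TP/(TP+FN)$, specificity $TN/(FP+TN)$, accuracy
  $(TP+TN)/N$. Published formulas written with the Portuguese initialisms
  VN/VP are read as TN/TP. Integer percents use round-half-away-from-zero
  (12.5% renders as 13%), which is what the published tables use; one-decimal
  output is available via `percent_digits`. A zero-denominator index is
  flagged `NA`, never fabricated.
* **Panels** combine by the union rule: a sample is panel-positive if any
  member aptamer reaches the threshold (combined intensity = max over
  members). Hence sensitivity is nondecreasing and specificity nonincreasing
  in panel size — a property the tests verify exhaustively over all subsets
  on small cohorts.

`cohort_from_counts()` rebuilds a cohort from published *marginal* counts
(positives/total per class or per stratum). Marginals are exact but the
joint structure across aptamers is arbitrary, so only individual-aptamer
indices are meaningful on such cohorts; published multi-aptamer combination
rows require the unpublished per-sample matrix and are deliberately not
reproduced. Published stratified tables also contain minor internal
inconsistencies (e.g. a printed 3.5% where the counts give 1/28 = 3.6%); the
package always recomputes percents from counts rather than echoing printed
values.

# Target shortlist cascade

Candidate aptamer targets are nominated by three sequential filters over
protein records (`run_cascade()`):

1. **Fold change**: target-line abundance at least `factor` (default 2)
   times the control line, inclusive ("at least 2-fold" reads as ≥). The
   pseudocount guarding zero denominators defaults to 0 when all abundances
   are positive — so a ratio of exactly 2 survives — and otherwise to the
   smallest positive abundance in the table, applied to numerator and
   denominator; the value used is recorded in the result.
2. **Membrane evidence**: presence in a membrane-proteome data set AND
   predicted plasma-membrane localization, conjointly. Whether the published
   40-protein membrane set used one or both lines of evidence is not fully
   specified; the conjunction is one defensible reading and is flagged here.
3. **Expression phenotype**: status `over` in every cell line the aptamers
   recognize and `under` in every line they do not. `unknown` fails in
   strict mode (default) and is ignored in lenient mode. Statuses are input
   columns (published calls), not recomputed from abundances; an optional
   helper `derive_expression_status()` exists for when only abundances are
   available.

The filters are independent predicates, so reordering them never changes the
final shortlist (tested over all six orders), though intermediate stage
counts do change. Electrostatic-surface screening of shortlisted proteins
requires an external computation and is out of scope; reports leave room for
that annotation.

# Trajectory analytics

Trajectories are ordered coordinate frames (Å) over a fixed atom list with
replicate boundaries. Input formats: multi-model PDB (via bio3d) or a plain
whitespace table.

* **Superposition** uses the SVD-based Kabsch algorithm with the reflection
  guard (proper rotations only); RMSD is mass-unweighted over all supplied
  atoms, computed after superposition. Rank-deficient (collinear) inputs are
  rejected because the optimal rotation is not unique there; exactly
  identical frames short-circuit to RMSD 0.
* **GROMOS clustering** (`gromos_cluster()`, cutoff default 2.5 Å) operates
  on the pairwise RMSD matrix with superposition *per pair*, not against a
  shared reference — the canonical formulation. It repeatedly extracts the
  unassigned frame with the most unassigned neighbors within the cutoff
  (ties: lowest frame index) as a cluster centroid together with its
  neighbors. Clusters are relabeled by decreasing size, so cluster 1's
  centroid is the representative structure reported first.
* **Hydrogen bonds** use a geometric criterion left unspecified in many
  published workflows, so it is explicit and configurable here:
  donor-acceptor distance ≤ 3.5 Å and donor-hydrogen-acceptor angle ≥ 135°
  by default, recorded in every results table. Occupancy is the percentage
  of frames satisfying the criterion, pooled across concatenated replicates
  (mirroring reports that quote a single percentage over all replicates),
  with a per-replicate breakdown also emitted. The occupancy report lists
  only bonds above `min_occupancy` (default 20%), sorted descending.

RMSF is mentioned in some workflow descriptions but appears in no published
result the package mirrors; it is intentionally not implemented rather than
guessing at its intended use.

# Synthetic-data generators

All generators derive their RNG substream from one global seed plus a fixed
per-generator offset, so adding a generator never perturbs another's draws,
and every generator is bit-reproducible given its config.

* **SELEX rounds**: a 76-nt library with a 30-nt variable region between
  constant flanks (flanks configurable — primer sequences are typically not
  published). Planted sequences grow geometrically with a per-round
  enrichment factor against a uniform background of distinct random
  sequences; round counts are multinomial draws. Phred qualities are
  per-position Gaussian truncated to [2, 41] with an optional linear 3'
  degradation — a deliberately simple error model that exercises trimming
  without simulating platform-specific artifacts, PCR bias, or substitution
  errors. Passing tests therefore show the counting/ranking chain is
  correct, not that it is robust to every real-world artifact.
* **Binding curves**: the saturation model plus Gaussian noise, with
  zero-aptamer and initial-library control rows per replicate.
* **Recognition cohorts**: the default cohort shape mirrors the worked
  example (10 adjacent / 50 primary / 40 metastatic; subtype mix
  0.56/0.14/0.20/0.10); aptamers stain tumor and adjacent samples with
  separate Bernoulli rates and draw ordinal intensities for positives. The
  realized TP/FP/FN/TN are recorded and must equal what
  `build_contingency()` recomputes.
* **Proteomic tables**: planted targets pass all three filters by
  construction; decoy classes each fail exactly one designated filter
  (fold-change, membrane, or phenotype). Defaults (4 planted + 36 membrane
  decoys + 249 fold-change survivors failing membrane + 100 fold-change
  failures) reproduce the 289 → 40 → 4 cascade shape.
* **Trajectories**: frames are jittered copies of planted centers — random
  Gaussian clouds regenerated until pairwise superposed RMSD exceeds twice
  the clustering cutoff — split round-robin across centers. Planted hydrogen
  bonds occupy dedicated atom triples whose acceptor sits at 2.9 Å
  (satisfied) or 6.0 Å (violated) along the donor-hydrogen axis in exactly
  the designated fraction of frames; a ground-truth flag warns when jitter
  or center geometry risks cluster overlap at the stated cutoff.

# Problem sizes and runtime

The shipped tests and the reproduction script use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: SELEX
recovery over 20 seeds at 5 rounds × 2000 reads against 500 background
sequences; Kd recovery over 100 simulated curves per noise level; clustering
oracles over 100 random 15-frame trajectories; exhaustive panel search over
all 31 subsets of 5 aptamers on 50 random 20-sample cohorts. Full-scale
inputs (12 rounds × millions of reads, 500-ns trajectories) run through the
same code paths; only the frequency-counting and pairwise-RMSD stages grow
superlinearly, and the pairwise matrix is the practical bound (quadratic in
frames).

# Known limitations

* Exact-match counting treats every sequencing error as a distinct species;
  enrichment of a true winner is diluted across its error cloud at realistic
  error rates.
* The binding model assumes one saturable site plus linear nonspecific
  binding; cooperative or multi-site binding will bias Kd.
* Cohorts rebuilt from marginals cannot support panel-combination indices.
* The hydrogen-bond criterion is geometric only; no energetic or
  orbital-overlap refinement.
* GROMOS clustering is greedy and order-dependent by design; it is the
  field's convention, not a globally optimal partition.
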