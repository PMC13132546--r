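---
title: "Methods: co-dependency screening, 1:1 kinetics, and NSAF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-dependency screening, 1:1 kinetics, and NSAF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codepscreen)
```

This vignette explains the models behind the package's three workflows,
the tunable parameters and their defaults, the numerical choices made
where the design was genuinely open, what the synthetic generators do
and do not emulate, and the known limitations.

## The co-dependency overlap screen

CRISPR fitness screens across hundreds of cancer cell lines yield a
cell-line × gene matrix of dependency scores (more negative = the line
depends more on that gene). Genes acting in one pathway tend to have
correlated columns — their *co-dependency*. The screen turns that into a
candidate ranking:

1. For each seed gene (an established pathway member), compute the
   Pearson correlation of its column with every other gene's column,
   using pairwise-complete observations, and keep the top *k* partners.
2. Score every gene by the number of distinct seed lists containing it.
3. Report genes at or above a score cutoff as candidates.

### Parameters

* `k` (default 100): the length of each seed's co-dependency list, the
  public portal's convention for a gene page.
* `ranking` (default `"absolute"`): partners are ranked by |r|, so that
  strong *negative* co-dependencies — typical for a repressor of the
  pathway, such as RB1 against G1/S drivers — can enter the lists.
  `"signed_positive"` ranks by r descending instead; public portals do
  not document a single convention, so both are first-class and the
  choice is recorded in every output.
* `min_pairs` (default 25): a correlation over fewer than 25 shared cell
  lines is considered unreliable and returned as missing. This guards
  sparse columns; with ~hundreds of lines it rarely binds.
* `cutoff` (default 3) and `top_fraction` (default 0.05): an explicit
  integer cutoff wins when both are given; with `cutoff = NULL` the
  cutoff is derived as the smallest *attained* score whose tail holds at
  most `top_fraction` of scored genes. We deliberately define the cutoff
  over attained scores (not all integers) so that it is always a score
  some gene has, matching how such screens are reported ("score ≥ 3 was
  roughly the top 5%"); the achieved fraction is reported rather than
  asserted.
* Ties in the ranking key are broken by symbol, then Entrez id,
  ascending — top-k boundaries are reproducible to the byte.
* The score universe is the set of genes appearing in at least one
  top-k list, not the whole matrix: the percentile rule is meant to
  describe the distribution of *outputs*.

Seeds are scoreable (an established factor recovered by the other seeds
is a useful positive control) but are excluded from the candidate table
by default, since the point of the screen is novelty. Genes sharing a
symbol but not an Entrez id are scored separately rather than silently
merged. The screen also accepts portal-exported per-seed top-k lists
directly (`read_precomputed_codependency()`), bypassing the correlation
step, for reproducing results computed against a pinned portal release.

### What the generator emulates

`simulate_effect_matrix()` uses a latent-factor (spiked covariance)
model: each planted module m has a standard-normal factor over cell
lines, and gene g gets `loading(g, m) * f_m + N(0, noise_sd^2)`. With
uniform loading a and noise sd s, the expected within-module correlation
is `a^2 / (a^2 + s^2)` — the single knob the screen's assumption rests
on. Entries are masked missing uniformly at random.

It does **not** emulate: lineage or copy-number structure, screen-level
normalization artifacts (CERES/Chronos), heavy-tailed or heteroscedastic
noise, or correlated missingness. Passing the recovery tests therefore
shows the screen's logic is sound under its own statistical assumption,
not that real DepMap data satisfy that assumption.

Validation sizes: oracle-equivalence runs use 25 random matrices of up
to 50 genes × 60 lines checked gene-by-gene against an exhaustive
full-sort oracle; module recovery uses 100 replicates of a 40-gene ×
100-line matrix with one 6-gene module (loading 1.0, noise sd 0.5, 4
module seeds, k = 5).

## BLI kinetics: the 1:1 Langmuir model

A sensorgram R(t) tracks the nm shift of a ligand-coated biosensor tip
through baseline, association and dissociation phases. For a 1:1
interaction at analyte concentration C (molar):

* association: `R(t) = Req (1 − exp(−kobs t))` with
  `kobs = kon C + koff`
* dissociation: `R(t) = R0 exp(−koff t)`
* equilibrium: `Req(C) = Rmax C / (KD + C)`, `KD = koff / kon`

Units are carried explicitly (concentrations molar internally;
`conc_to_molar()` converts tagged nM/µM/mM inputs) — printed affinities
are meaningless without them.

### Preprocessing

* **Double reference subtraction**
  `(sample − reference) − (zero-analyte sample − zero-analyte
  reference)` removes drift and nonspecific signal, followed by y-axis
  alignment through the pre-association baseline. Time grids must match
  exactly; the package refuses to interpolate silently.
* **Reference drift modeling.** Reference and zero-analyte traces
  contain no binding signal, only slow drift plus noise. The pipeline
  therefore replaces each by a low-order polynomial fit
  (`ref_poly_degree = 2`) before subtraction. Subtracting raw traces
  would double the noise variance of the corrected curve; smoothing them
  with a running filter was considered and rejected because it turns
  white noise into low-frequency wobble that short fit windows cannot
  average away.
* **Savitzky–Golay smoothing** (window 11 points, order 3 by default —
  mild, and fully configurable) is applied to the corrected sample
  curve, *per phase segment*: filtering across the kinks at phase
  boundaries distorts precisely the first seconds of each phase that
  the rate fits use.
* **Interstep alignment** (`interstep_align()`) offsets the dissociation
  segment to be continuous with the last association point. It exists to
  correct well-transfer step artifacts in instrument data and is off by
  default in `fit_bli()`: applied to continuous curves it only injects
  the noise of two boundary points into the whole dissociation phase.

### Fitting

Per curve, nonlinear least squares (Levenberg–Marquardt, analytic
ladder of 3–4 perturbed restarts before declaring non-convergence) over
the first 20 s of association and 20 s of dissociation — short windows
are standard when later parts of a phase drift or deviate from 1:1
behavior.

Two identifiability choices matter at realistic noise:

* **Anchoring Req.** Over a 20-s window far from saturation, Req and
  kobs are nearly confounded (the curve is locally
  `Req·kobs·t`). The pipeline therefore measures the equilibrium
  plateau (mean of the last `plateau_window_s = 20` s of association),
  extrapolates it to full equilibrium through the fitted kobs (iterated
  to a fixed point), and fits the association window with kobs as the
  only free parameter. The unconstrained (Req, kobs) fit remains
  available (`req_mode = "free"` and in `fit_observed_rates()`).
* **Constraining the kobs line.** The 1:1 model fixes the intercept of
  `kobs = kon C + koff` at koff, and the dissociation phase measures
  koff far more precisely than extrapolating the line to C = 0. kon is
  therefore the slope of the inverse-variance-weighted regression
  constrained through the dissociation koff; the free-intercept line is
  computed alongside as the consistency diagnostic (`intercept_koff`
  should agree with the dissociation koff when the 1:1 model holds, and
  `r_squared` should be ~1).

The reported koff is the inverse-variance-weighted mean of the
per-curve dissociation fits: at low C the dissociation amplitude is
small and those curves carry little decay information. KD is reported
twice — kinetically as koff/kon (stored as exactly that ratio) and from
the steady-state hyperbola fit of Req against C (initialized at
KD = median(C), Rmax = 1.1·max(Req)). Agreement between the two is
itself a model check. Degenerate inputs error loudly: flat association
windows, all-nonpositive equilibrium responses, fewer than 3
concentrations, or a non-positive fitted kon.

### What the sensorgram generator emulates

`simulate_sensorgrams()` is the exact forward model above plus i.i.d.
Gaussian noise and a linear drift shared by matched reference curves,
sampled at 5 Hz (`dt_s = 0.2`, a standard instrument acquisition rate)
with 10 s baseline and 300 s association/dissociation phases. It does
not emulate mass-transport limitation, heterogeneous ligand, analyte
depletion, well-transfer step artifacts, or 1/f instrument noise — so
recovery results certify the estimator chain, not robustness to model
violations. Recovery validation uses 5 concentrations spanning
12.5–200 nM at 1% (of Rmax) noise, 20 generator replicates, plus a
noiseless run that must recover all parameters to ~1e-6 relative.

## NSAF quantification

Within one AP-MS run, `SAF_i = SpC_i / L_i` corrects spectral counts
for protein length; `NSAF_i = SAF_i / Σ_j SAF_j` makes runs of
different depth comparable (`pNSAF = 100·NSAF`). Implementation detail:
the ratio is computed from depth-normalized counts
(`(SpC/ΣSpC)/L`), which is algebraically identical but makes NSAF
*bit-exactly* invariant to multiplying every count in a run by the same
integer (IEEE division of scaled integers rounds identically).

Bait-vs-control comparison is a clearly-labeled descriptive ranking:
`log2((bait NSAF + ε)/(mean control NSAF + ε))` with pseudocount ε
defaulting to half the smallest nonzero NSAF across runs (scale-aware),
a protein absent from a run contributing 0 there, and a flag for
bait-present proteins at ≥ `fold_threshold` (default 2). It is **not**
a significance test and assigns no p-values; published interactome
studies typically use a dedicated enrichment statistic for that
purpose, which is out of scope here.

`simulate_spectral_counts()` draws each run's counts from a multinomial
with probability ∝ abundance × length — the sampling model NSAF
corrects for — with controls drawn from a separate background abundance
vector. Spike-in validation plants 5 preys at 4× abundance among 40
proteins (2000 spectra/run, 3 control runs, 100 replicates) and asks
that they top the fold ranking. The generator does not emulate
peptide-level identification, shared peptides, or FDR filtering.

## The command-line layer

`run_cli()` (wrapped by `exec/codepscreen`) dispatches `screen`,
`bli-fit`, `nsaf` and the three `simulate-*` generators. A `--config`
key-value file supplies defaults that explicit flags override; every
run writes a manifest (resolved parameters, input MD5 digests, package
version, timestamp, RNG seed) beside its outputs, and deterministic
subcommands are byte-reproducible across runs. Warnings about dropped
columns and skipped seeds are on by default — silent data loss is the
main failure mode of screens. Generator subcommands require an explicit
`--seed`.

## Known limitations

* The screen is a deterministic counting procedure; it attaches no
  significance to a score, and the "no prior link to the pathway"
  triage of candidates is a human annotation passed through, never
  computed.
* Pearson co-dependency assumes roughly linear, outlier-free
  relationships; no partial correlation or covariate correction is
  offered.
* The BLI module fits 1:1 kinetics only; systems with biphasic behavior
  need models outside its scope, and vendor binary files are not
  parsed.
* NSAF enrichment is descriptive; treat the fold ranking as triage, not
  inference.
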