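---
title: "Annotating modular ascarosides and measuring their phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating modular ascarosides and measuring their phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndmmtools)
```

This vignette explains the models and procedures behind `ndmmtools`, the
assumptions they make, the defaults they ship with, and the choices made
where the design was genuinely open. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## 1. The chemistry layer

### Formulas and masses

A modular ascaroside is assembled from a small set of components: a dideoxy
sugar (C6H12O4; ascarylose and paratose are isomers and therefore
mass-identical), a fatty-acid side chain whose hydroxy-acid precursor is
CnH2nO3 (saturated) or CnH(2n−2)O3 (one double bond), an optional ureido
head group at the sugar 4'-position (ureidoisobutyric acid C5H10N2O3 for
UBAS, ureidopropionic acid C4H8N2O3 for UPAS), and an optional second
ascaroside unit linked at the 2'- or 4'-position (dimers, DASC). Every
condensation bond — glycosidic or ester — removes one H2O, so the neutral
formula is a pure element-bookkeeping exercise:

```{r}
assemble_ndmm(side_chain(7))   # sugar + C7 chain - H2O = C13H24O6
```

Monoisotopic atomic masses are hard-coded to seven decimals, and ion m/z
values subtract (cations) or add (anions) one electron mass, 0.0005486 Da.
The electron correction matters: at m/z ~400 it is worth 1.4 ppm, and
printed measured-vs-theoretical deviations in the low-ppm range are only
reproducible with it. Supported adducts are `[M+H]+` and `[M+Na]+` in
positive mode and `[M−H]−` in negative mode, the only ion forms relevant
for these compound classes in electrospray ionization.

The `ppm_error()` convention is signed internally
(`1e6 * (observed − theoretical) / theoretical`); reports use the absolute
value rounded to one decimal, matching the unsigned convention of published
Δ-ppm annotations.

### Diagnostic fragments

Collision-induced dissociation cleaves modular ascarosides at predictable
positions, and each complex class leaves a characteristic ion:

* **DASC** — the terminal side chain is lost; the surviving fragment is the
  first ascaroside still bound to a bare sugar, i.e.
  `formula(first unit) + C6H12O4 − 2 H2O`, detected as `[M+Na]+`. This is
  how the identity of the *first* unit of a dimer is established by MS.
* **UBAS** — the head-plus-sugar cation C11H19N2O5+ (`[M+H]+`), shared by
  every UBAS compound, which is what makes a targeted fragment screen for
  the whole class possible.
* **UPAS** — the ureidopropionic acid anion C4H7N2O3− (`[M−H]−`).

Fragment m/z values are computed from theoretical masses, never from
printed measured values: two printed fragment masses are internally
inconsistent with their own formulas (one by ~8 ppm, one by ~17 ppm,
plausibly transcription errors), and a screen anchored to theoretical
masses is reproducible and self-consistent.

### Nomenclature

The structure-based grammar is
`(head-)(linkage-(first unit)-)asc-(ω)(Δ)C<n>`: an optional `4'-UB-` or
`4'-UP-` head (head groups are only defined at the 4'-position), an
optional parenthesized first ascaroside with its attachment position, then
the terminal unit with optional ω (terminal-carbon attachment) and Δ
(one double bond) markers. `parse_name()` and `render_name()` are exact
inverses on canonical names; the tests verify the round-trip over every
name the grammar can produce for chain lengths 3–11 (the observed range,
asc-ωC3 through asc-C11). Dimers whose linkage is experimentally
unresolved carry an explicit `"unresolved"` flag and have no canonical
name — rendering them is an error rather than a silent guess.

## 2. The screen

`build_library()` enumerates candidates exhaustively from configured
building blocks; `match_spectrum()` accepts a candidate when any configured
adduct's theoretical m/z falls within `precursor_tol_ppm` of the precursor.
Defaults are 5 ppm for precursors and 10 ppm for fragments: consistent
published assignments on high-resolution qTOF instruments sit below ~5 ppm,
and fragment ions (lower m/z, lower signal) warrant a looser bound. Both
are configurable because the right values are instrument-dependent.

Two honesty rules are enforced structurally. First, mass-identical
candidates are *always* reported as one isomer set (`candidates`,
`n_isomers`), because 2'- vs 4'-linkage and ascarylose vs paratose are
indistinguishable by mass; only NMR resolves them. A set's
`fragments_confirmed` is true when a peak matches *any* member's diagnostic
ion — members can predict different fragments (dimers differing in which
unit is first), which is exactly how MS/MS narrows an assignment. Second,
ties are never broken by invention: results are sorted by |ppm| then name,
and every co-optimal candidate is kept.

Detection calls use the ion-intensity threshold of 1.0×10³: at or above it
a compound is *quantifiable*, between zero and the threshold it is *trace*,
and trace detections are excluded from the comparative analyses (they
remain visible in screen output). Presence/absence for the comparative
layer is decided on replicate means — the published heat-map convention —
rather than per-replicate; this is a documented, configurable decision,
since the alternative (any replicate above threshold) is defensible too.

## 3. Profiles

`aggregate_replicates()` averages peak areas with missing
compound-replicate records treated as zero (absence of detection), dividing
by the number of recorded replicates per species. Two standardizations are
provided because they serve different purposes:

* `within_class_percentages()` — each compound relative to its class total
  per species, with monomeric and dimeric UBAS standardized separately.
  This is a *visualization* scaling: it keeps rare classes readable when
  simple ascarosides dominate total production. A class with zero total
  yields zeros, not NaN.
* `close_composition()` — all compounds to 100% per species. This is the
  *analysis* scaling used upstream of Bray–Curtis, since closure removes
  absolute production-rate variation (culture density, growth rate) that
  would otherwise masquerade as profile divergence.

Both are invariant to per-species rescaling of raw areas, and both closures
are exact to 1e-9 in the tests.

## 4. Comparative statistics

### Mk likelihood and model selection

The two-state Mk model has rates `q01` (gain) and `q10` (loss) per unit
branch length. The transition matrix has the closed form
`P(t) = Π + (I − Π) exp(−(q01+q10) t)` with `Π` the stationary
distribution, so no matrix exponential is needed. Likelihoods come from
Felsenstein pruning with an equal (1/2, 1/2) root prior. Fitting maximizes
over log-rates with L-BFGS-B inside [1e-9, 1e3], from four starts centered
on a parsimony-informed rate (state changes per unit tree length); the
multi-start guards against the flat ridges that small trees produce.
Impossible data (e.g. differing tips under zero rates) yield `-Inf` with an
explicit `impossible` attribute — R's native infinity is already a
non-silent sentinel and propagates correctly through optimization, so no
arbitrary large-negative constant is used. ER (one rate) is nested in ARD
(two rates); `select_model_lrt()` rejects ER when twice the log-likelihood
gap exceeds the chi-square(1) critical value at α = 0.05. The pruning
implementation is verified against brute-force enumeration over all
internal-node states on trees of up to five tips, and against an
independent reference implementation.

### Stochastic character mapping

Maps are drawn by forward-filtering/backward-sampling: the pruning pass
gives each node's conditional likelihood, node states are sampled root-down
from those conditionals, and each branch history is then simulated
conditional on its endpoint states — rejection sampling first (500
attempts), falling back to exact uniformization bridge sampling when
rejection is impractical (high rates, unlikely endpoint pairs). Node-state
frequencies over maps are checked against the analytic marginals from the
two-pass algorithm (`mk_marginals()`), and every history's change count is
bounded below by the Fitch parsimony score.

With `rate_uncertainty = TRUE`, each map draws its Q from a Metropolis
posterior sample on log-rates: gamma(shape 2) priors centered on the ML
prefit, 1000 burn-in iterations, thinning interval 10, proposal SD 0.5.
These hyperparameters are deliberately mild regularization — enough to keep
rates proper when traits are nearly constant — and are exposed as
configurable internals rather than hidden constants.

### The D statistic

For a binary trait, nodal values are computed tip-to-root by averaging
daughters, and `d` is the sum over internal nodes of the absolute
difference between daughter values. The observed `d` is scaled between two
null expectations — tip-label shuffles (phylogenetic randomness, D = 1) and
Brownian motion thresholded at the observed prevalence (D = 0):

`D = (d_obs − mean d_Brownian) / (mean d_random − mean d_Brownian)`

The published description of this statistic delegates the nodal-value
estimator to its original implementation without restating it; the
daughter-averaging down-pass used here is validated by calibration instead
of by matching any specific implementation: over 200 simulated traits per
regime the mean D must land in [0.9, 1.1] under shuffles and
[−0.15, 0.15] under Brownian-threshold simulation. Thresholding uses ranks
(the k largest latent values become 1s, k = observed prevalence count) so
every Brownian replicate has exactly the observed prevalence. One-sided
permutation p-values are converted to two-sided as `2·min(p_low, p_high)`
capped at 1. D is undefined — and raises an informative error — for
constant traits and singletons (one species differing from all others).
Defaults are 10,000 permutations per null; the package's own calibration
runs use 1,000 to keep runtimes in seconds at 32 tips, a problem size at
which the extra permutations change D's Monte-Carlo error negligibly.
Benjamini–Hochberg FDR flags (default q = 0.10, via `stats::p.adjust`) are
computed separately for the D = 0 and D = 1 test families.

### Compositional comparison

Bray–Curtis dissimilarity (`Σ|x−y| / Σ(x+y)`) is computed in-package (and
cross-checked against vegan to 1e-12 in tests); the Mantel test uses
Spearman correlation with midranks over lower triangles and joint
row/column permutations, `p = (1 + #[ρ_perm ≥ ρ_obs]) / (n_perm + 1)` with
999 permutations by default; NMDS delegates to vegan's `monoMDS` (Kruskal
stress-1, monotone regression), keeping the best of 20 restarts — the first
from monoMDS's default start, the rest random — which in practice is ample
for matrices of a few dozen objects. Both permutation procedures are
bit-reproducible given a seed.

## 5. What the simulators emulate — and what they do not

`simulate_tree()` builds pure-birth clade subtrees grafted onto a pure-birth
backbone, rescaled ultrametric with root depth 1 (the chronogram
convention), default 32 tips in four named clades (10/7/6/5) plus a 4-tip
outgroup — the shape of the real study system. The true species topology is
published only as a figure, so clade memberships are encoded, not the exact
topology; branch lengths are synthetic. `simulate_mk_trait()` evolves states
by exponential waiting times from an equal-prior root;
`simulate_threshold_trait()` thresholds Brownian tip values at rank;
`simulate_profiles()` mixes standardized Brownian and independent latent
values by `signal_strength` and closes through a softmax (strictly positive
compositions — Bray–Curtis is degenerate on all-zero rows), with 46
compounds by default, a realistic quantifiable-compound count.
`simulate_spectra()` plants precursors and diagnostic fragments at
theoretical m/z with Gaussian ppm error and adds uniform decoy peaks over
the m/z 50–1300 scan window; decoys are resampled to sit at least 50 ppm
from any candidate ion so that recall and specificity are well-defined
properties of the screen, not of decoy luck.

Passing tests on these inputs shows the machinery is correct and
calibrated; it does not show that real chromatograms are this clean. The
generators model no isotope patterns, no co-elution, no retention-time
information, no intensity-dependent mass error, and no inter-batch
variation. Presence/absence of real trace compounds near the 1.0×10³
threshold will be sensitive to extraction efficiency in ways no synthetic
spectrum reproduces.

## 6. Problem sizes and numerical choices

The test suite and acceptance script use: 100 random trees of ≤ 5 tips for
the likelihood oracle; 2,000 stochastic maps on a 16-tip tree for the
marginal-frequency check (3 Monte-Carlo SE bound, floored at 4 counts where
the normal approximation degenerates near probability 0 or 1); 200
replicate traits per calibration regime on 32-tip trees with 1,000
permutations each; 200 replicates at 999 permutations for the Mantel null
and 200 ER-simulated traits for the LRT null (band: 0.05 ± the 99% binomial
interval). These sizes make the whole suite run in a few minutes while
keeping Monte-Carlo error well inside every acceptance band. Ultrametricity
is checked as relative tip-depth spread below 1e-6 and violations warn
rather than stop, since only the Brownian-threshold null assumes clock-like
depths. The optimizer nestedness tolerance (ARD may fall below ER by at
most 1e-3 before erroring) absorbs bounded-optimizer noise without masking
real convergence failures.

## 7. Known limitations

* Chain lengths outside 3–11, multiple double bonds, and sugars beyond the
  ascarylose/paratose pair are not representable.
* Highly modular NPAR/PASC compounds enter at formula level through a
  registry (name → formula → class); their side-chain combinatorics are out
  of scope, as is stereochemistry and NMR evidence generally.
* The Mk machinery is strictly two-state; multi-state or correlated-trait
  models are out of scope.
* The LRT's chi-square(1) reference is asymptotic; at 32 tips its realized
  level can drift a few points above 5% in finite samples, which the
  acceptance band acknowledges.
* Quantification across runs (alignment, normalization, imputation) is
  deliberately not addressed: inputs are assumed to be comparable peak
  areas.
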