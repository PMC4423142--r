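---
title: "Methods: descriptors, CDFS-MLR, GA-PLS and the applicability domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, CDFS-MLR, GA-PLS and the applicability domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyroqsar)
```

This vignette is the package's own account of the science it implements:
the molecular descriptors, the two model-building routes (stepwise MLR
inside a combined data splitting–feature selection strategy, and
genetic-algorithm PLS), the validation machinery, and the design decisions
taken where the methodology left genuine freedom.

## The modelling problem

The motivating dataset is a series of 30 L-tyrosine-scaffold inhibitors of
MMP-2 with activities expressed as pIC50 (−log10 of the molar IC50). A
descriptor matrix of ~1168 computed molecular properties is reduced by
constant-column removal and a collinearity filter to a pool of a few
hundred (291 in the reference study), from which small multiple linear
regression models (4–7 descriptors) are selected on a 24-compound
calibration set and judged on a 6-compound validation set. This is an
extreme small-n / large-p regime: every design decision below is shaped by
the fact that, with 24 observations and ~290 candidate columns, the largest
*spurious* absolute correlation among inert descriptors is ~0.6 —
comparable to the marginal correlation of a genuinely informative
descriptor.

## Descriptors

All 3D descriptors are computed on the structure exactly as supplied
(hydrogens included if present — the usual convention for 3D descriptor
engines; a caller can delete hydrogens beforehand for H-depleted values).
Weighted descriptors use carbon-scaled atomic property weights
`w_i = prop(element_i)/prop(C)` with property schemes `u` (unit), `m`
(mass), `e` (Sanderson electronegativity), `p` (polarizability), `v` (van
der Waals volume); the per-element table ships as a CSV so values are
reproducible.

* **IC1** — atoms are partitioned by (atomic number, degree, multiset of
  neighbour (atomic number, bond order) pairs); IC1 is the Shannon entropy
  (bits) of the class sizes. It is a size/branching-heterogeneity measure:
  0 for a homonuclear diatomic, log2(n) when every atom is unique.
* **3D-MoRSE** — `Mor(s) = Σ_{i<j} w_i w_j sinc(s·r_ij)` with signal k
  mapped to `s = k − 1` Å⁻¹ over the 32-signal catalogue (so Mor01 is the
  plain pair-weight sum). This numbering is the convention of the
  descriptor engine the study used; it makes the s = 0 identity
  `Mor01 = Σ w_i w_j` a sharp unit test.
* **RDF** — `RDF(R) = Σ_{i<j} w_i w_j exp(−B(R − r_ij)²)`; names encode the
  radius in tenths of an Å on the grid 1.0–15.5 step 0.5 (RDF115 = 11.5 Å).
  The smoothing parameter B is not encoded in the name and is not printed
  in most reports; the default **B = 100 Å⁻²** (a ~0.1 Å window) is the
  common engine default and is configurable. One reference table glosses
  "RDF135e" as radius 3.5; the name-based radius (13.5 Å) is used, since
  the naming grid is unambiguous.
* **GATS** — the standard Geary spatial autocorrelation estimator at a
  topological lag: ordered-pair sums, `Δ` = ordered-pair count. For i.i.d.
  weights its expectation is ~1, which the test suite verifies by
  Monte-Carlo; this property pins down the ordered-sum convention against
  half-weight variants that appear in the literature.
* **GETAWAY (HATS/R/Rmax)** — built on the molecular influence matrix
  `H = M(MᵀM)⁻Mᵀ` of centered coordinates (pseudo-inverse for planar or
  linear geometries, so Σh_i equals the coordinate rank). `R7e0` is read as
  the *maximal* R autocorrelation at lag 7 weighted by electronegativity,
  per its tabulated description.
* **WHIM** — eigenanalysis of the weighted covariance of centered
  coordinates (weights normalized to sum 1): L are the eigenvalues
  (directional size), E the inverse-kurtosis accessibilities
  `E_m = L_m² n / Σ t_im⁴`, and G the directional symmetries. Published
  WHIM symmetry formulas differ in detail; here `G = 1/(1 + H)` where H is
  the binary entropy of the matched/unmatched split under mirror matching
  of axis scores within **sym_tol = 0.1 Å**. Matching visits atoms by
  decreasing |score| and pairs each with its best mirror candidate, so the
  index is invariant to atom input order and eigenvector sign; the
  properties G ∈ (0,1] and G = 1 for perfectly centro-symmetric
  arrangements are tested rather than any engine-specific value.
* **Shape profiles** — `SP_k = [(2/(n(n−1))) Σ_{i<j} r_ij^k]/k!`, the k-th
  distance-distribution moment scaled by k! (Randić-profile variants
  differ in the scaling; the k! variant keeps high orders like SP20 in a
  numerically sane range).
* **Quantum indices** — the printed-source convention is
  `η = ½(E_HOMO + E_LUMO)`, `S = 1/η`, `χ = ½(E_HOMO − E_LUMO)`,
  `ω = χ²/2η`, which is the sign-swap of the textbook conceptual-DFT
  definitions; both are implemented behind a flag, default as printed,
  because the packaged equations were built with the printed values.

## Preprocessing

Near-constant columns are dropped when the standard deviation is below
1e-8 (absolute) or the modal value covers more than 90% of rows — the
thresholds are not prescribed anywhere, so round defaults are used and
exposed as arguments. The collinearity filter scans pairs with |r| > 0.9 in
decreasing |r| and keeps the member with the higher |cor(·, y)|, ties going
to the earlier column for determinism; the result provably contains no
surviving pair above the cutoff, and the filter is idempotent. Splits are
uniform random without stratification (an activity-sorted systematic mode
exists for reproducibility studies); 30 compounds at the default 20%
validation fraction give the 24/6 split of the reference study.

## Stepwise MLR and CDFS

`stepwise_mlr()` is classic forward-entry (smallest partial-F p < 0.05) /
backward-removal (p > 0.10) selection, deterministic under ties (earlier
column wins), with a term cap defaulting to one descriptor per five
compounds. Two behaviours deserve comment:

* **Entry-scan multiplicity.** With m candidates the minimum of m uniform
  p-values is below 0.05 essentially always once m is large, so uncorrected
  stepwise on a 291-column pool admits a spurious descriptor nearly every
  cycle — the term cap, not the entry test, is what stops it. The
  `adjust = "sidak"` option corrects the best candidate's p-value to
  `1 − (1 − p)^m`, making the pure-noise entry rate family-wise ~5%; in
  that mode a single dominant predictor among decoys is selected *exactly*.
  The default remains uncorrected, matching standard stepwise software and
  because corrected entry cannot initiate at all when individual marginal
  correlations are modest (the 291-column regime above).
* **Model-size cap churn.** Inside CDFS the pooled-set search uses a looser
  cap (n/3 instead of n/5) so that a spurious early entrant can later be
  displaced by true descriptors plus backward removal, instead of jamming
  the search at the cap.

`cdfs_general_model()` repeats the 80/20 split ten times (seeded), runs
stepwise on each calibration subset, retains models with R²_c > 0.95
(read as R², with an `"r"` option, because the retained reference models
all print R²_c well above 0.95), pools the union of their descriptors, and
runs a final stepwise restricted to that pool on a fresh seeded split.

**General-model choice.** The natural rule "maximize Q²_LOO over the
visited models, ties to fewer descriptors" turns out to be systematically
anti-parsimonious: a descriptor that the search picked *because* it
correlates with the calibration residuals by chance also inflates the
leave-one-out statistic (the held-out row participated in its selection),
so pure Q²-maximization essentially never prunes, and the exact informative
subset is often not even on the greedy path because decoys interleave with
true descriptors. The implemented rule therefore (a) augments the candidate
set with a Q²-guided backward-elimination sequence from the final stepwise
model, which does visit the informative subset whenever the final model
contains it, and (b) returns the *smallest* candidate whose Q²_LOO is
within `q2_tol = 0.01` of the best — a one-standard-error-style rule; Q²
differences below ~0.01 at 24 compounds are noise, not evidence for a
larger model. On the canonical synthetic bundle this recovers the exact
5-descriptor truth in 20/20 seeded runs, versus ~2/20 for pure
Q²-maximization.

## GA-PLS

PLS is the single-response NIPALS algorithm on centered (unscaled — the
final equations are quoted in raw descriptor units) data, with the latent
model collapsed to ordinary-space coefficients; with as many components as
the rank of X it reproduces OLS, a tested identity. Cross-validated Q² uses
genuine deleted predictions (leave-one-out by default, leave-n blocks
otherwise), and one training-fold fit yields the predictions of every
nested component count at once, which is what makes GA fitness evaluation
affordable.

The GA is a seeded binary chromosome search: tournament selection (size 2),
single-point crossover (p = 0.9), per-gene mutation (1/pool size), elitism
(2), population 100 by default within the conventional 80–125 band,
initial gene-on probability 0.1 so early models are sparse. Fitness is the
leave-n-out Q² of the encoded subset (PLS components chosen internally by
LOO up to min(5, n − 2)) minus a sparsity penalty of **0.005 per selected
descriptor**, which operationalizes "smallest subsets among equally
predictive ones": 0.005 is well below any meaningful Q² difference but
breaks the tie against padding. Elitism makes the best-ever fitness
non-decreasing — asserted on every run — and the whole search is
bit-reproducible for a fixed seed. Fitness values are cached per subset, so
converged populations cost little.

## Validation and applicability domain

Q²_LOO and RMS_CV for linear models use the hat-matrix identity
`e_(i) = e_i/(1 − h_ii)`, proven equal to the explicit refit loop in the
tests. R²_p is the squared Pearson correlation of predicted versus observed
on the validation set — deliberately documented as sign- and scale-blind.
Y-randomization refits the fixed descriptor subset on seeded permutations
of y (identity permutation redrawn) and flags whether every permuted R² and
Q² falls below the original.

The applicability domain follows the Williams-plot construction: leverages
`h_q = x_qᵀ(X_cᵀX_c)⁻¹x_q` on the intercept-augmented calibration design
restricted to the model's descriptors (matching per-model domain plots, not
the full matrix), standardized residuals scaled by the calibration residual
standard error (a per-point deleted-variance option exists; the simple
scale is the default because the reference construction does not state a
choice), the ±2 response-outlier band, and warning leverage
`h* = 3(k + 1)/n` — 0.75 for a 5-descriptor model on 24 compounds. For the
4-descriptor GA-PLS-style model the same formula gives 0.625; a reported
value of 0.5 corresponds to k = 3 in this formula, and the package always
computes h* from the actual k.

## The synthetic-data generator

`make_regression_dataset()` emulates the statistical shape of the
post-filter modelling problem: standard-normal descriptor columns, optional
correlated decoy blocks (common-factor construction at within-block
correlation 0.95, to exercise the collinearity filter), and an activity
that is an exact sparse linear function of k true descriptors plus Gaussian
noise. Defaults are the study dimensions: n = 30, p = 291, 5 true
descriptors, signal-to-noise ratio sd(signal)/σ = 10 — strong enough that
selection-recovery tests are sharp, weak enough that they are not
degenerate. True coefficients have magnitudes U(1, 3) with alternating
signs, a realistic spread of effect sizes; true columns are never placed
inside collinear blocks so the ground truth stays identifiable.
`make_qsar_bundle()` adds the canonical 24/6 split. What the generator does
*not* emulate: real descriptor marginals (heavy tails, discreteness),
block-correlation between true descriptors, and activity heteroscedasticity
— so passing recovery tests demonstrate the selection machinery, not
real-data performance. Recovery rates are measured on the fixed canonical
bundle across seeded runs of the (stochastic) selection procedure; across
freshly drawn datasets the rate is lower (~70%), because some draws contain
decoys whose dataset-level spurious correlation exceeds the true marginal
correlations, which no greedy forward search can overcome.

`make_point_cloud_molecule()` provides descriptor unit-test substrates:
uniform random coordinates in an 8 Å box with a random spanning tree as
bond graph, so the molecule is always connected and every topological lag
up to the tree diameter exists.

## Numerical choices and degenerate inputs

Rank decisions use SVD with tolerance `max(dim)·max(d)·eps`; coincident-atom
geometries error rather than return NaN leverages. Undefined descriptor
values (zero weight variance, empty lag set) propagate as `NA`, and the
near-constant filter treats mostly-`NA` columns as removable — silent zeros
would corrupt selection. PLS deflation stops early if X is exhausted below
a 1e-12 norm floor. Stepwise ties are broken by column order everywhere;
the add/remove loop carries a 50-cycle guard against deterministic
oscillation near the term cap. Splits, permutations, GA runs and bundles
restore the caller's RNG state, so library calls do not perturb user
simulations.

Test problem sizes were chosen to keep the full suite comfortably
reproducible on a single CPU: 20 pseudo-molecules for invariance sweeps,
500 replicates for the stepwise type-I calibration, 20 seeded runs (at 15
GA generations, which is past the empirical convergence point of ~8) for
the recovery rates.

## Known limitations

* Descriptor values are validated by closed forms, invariance and
  brute-force oracles — not by matching any specific commercial engine's
  output; engines differ in H-handling, weight tables and symmetry
  tolerances, and reproducing one bit-for-bit is out of scope.
* The packaged reference equations predict from *supplied* descriptor
  values; recomputing the original study's descriptor matrix would require
  its exact optimized geometries, which were never published.
* Greedy stepwise selection in the small-n / large-p regime is
  fundamentally fragile; CDFS mitigates split instability but cannot beat
  dataset-level spurious correlation. GA-PLS, which searches subsets
  jointly, is the more robust route on such data.
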