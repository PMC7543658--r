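---
title: "Global and local ADP analysis: models, parameters and design choices"
author: "adpvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global and local ADP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpvalid)
```

## Why model B-value distributions at all

Isotropic atomic displacement parameters (ADPs, B values, Å²) are
proportional to the positional variance of an atom about its refined
centre. They absorb genuine thermal and static disorder, but also every
modelling error that leaves an atom without supporting density: a misplaced
side chain or an absent ligand refines to an inflated B. Two consequences
drive this package:

* **Globally**, the B values of a well-behaved single-domain crystal follow
  a shifted inverse-gamma distribution (SIGD) — the inverse-gamma is the
  conjugate shape for a variance, and scaling of the experimental data adds
  an arbitrary overall shift `B0`. Structures with several mobility regimes
  (loosely packed domains, partially disordered chain ends) show a
  *mixture* of SIGDs, and the modes track spatial domains.
* **Locally**, neighbouring atoms form an elastic network and must share
  mobility. An atom whose B departs drastically from its spatial
  environment has either the wrong occupancy or the wrong element.
  "Drastic" depends on resolution: at 3 Å a 50 vs 100 Å² difference
  matters less than 10 vs 15 Å² at 1.5 Å, so raw B differences are
  converted into **relative occupancies** of a point Gaussian atom at the
  structure's resolution limit.

## The global model and the staged fit

The mixture density is `sum_k pi_k f_k(B)` with

`f(B) = beta^alpha / Gamma(alpha) (B - B0)^(-alpha-1) exp(-beta/(B - B0))`, `B > B0`.

Direct EM on this mixture from naive starts is unstable: the likelihood is
unbounded as any component's `B0` approaches its smallest responsible data
point with small `alpha`, and components collapse onto single points. The
fit therefore proceeds in four stages (`fit_sigd_mixture()`):

1. **Peak-height transform** (`peak_height()`): each B is mapped to the
   central density of a point Gaussian atom truncated at
   `s_max = 1/d_max`: `rho(0) = ∫_0^{s_max} 4 pi s^2 exp(-B s^2/4) ds`.
   The map is strictly decreasing and, at working resolutions, spreads the
   low-B end and compresses the high-B tail, so mobility regimes that
   overlap in B space separate in peak-height space. This is where mode
   counting happens.
2. **Mode counting** (`count_modes()`): Gaussian KDE with Silverman's
   rule-of-thumb bandwidth `h = 0.9 min(sd, IQR/1.34) n^(-1/5)` on a
   512-point grid spanning the data range ± 3h. Local maxima are accepted
   as modes when their *topographic prominence* (height above the key
   saddle toward higher ground) is at least 1% of the global maximum;
   maxima closer than `h` merge into the taller one. Prominence, rather
   than raw height, is essential: KDE tails wiggle, and a tail ripple can
   exceed 1% of the peak in height while having essentially zero
   prominence. Mode counts are capped at 5 — real structures essentially
   never support more than 3.
3. **Gaussian warm start** (`gmm_warm_start()`): a plain 1-D Gaussian
   mixture EM in peak-height space, initialized at the KDE mode locations.
   Its converged responsibilities — not just its centroids — are carried
   to the next stage, which is more information than mapping means back
   one by one (the package still exposes `invert_peak_height()` for
   mapping individual peak-height values to B).
4. **SIGD EM over B**: the mixture EM runs on B values, since the target
   density is a density over B. The E step is the standard posterior
   responsibility; the M step re-fits each component by
   responsibility-weighted constrained maximum likelihood
   (`fit_sigd()`), warm-started at the component's current parameters and
   *kept only if it improves* the weighted likelihood. The M step being a
   generalized (improve-or-hold) step makes the observed-data
   log-likelihood provably non-decreasing, which the implementation
   asserts and the tests check on every fit.

### Numerical choices

* `fit_sigd()` optimizes `(log alpha, log beta, B0)` by L-BFGS-B from a
  method-of-moments start (`alpha = (m-B0)^2/v + 2`,
  `beta = (m-B0)(alpha-1)`, exact for inverse-gamma moments), falling back
  to Nelder–Mead with a penalty if the bounded optimizer fails; it never
  returns a fit below its start.
* The shift is constrained to `B0 <= min(b) - eps` with
  `eps = 1e-3 (max(b) - min(b))` for single fits — the likelihood is
  unbounded without a margin — and, inside the mixture M step, below the
  0.1% responsibility-weighted quantile of the data, which keeps supports
  valid while letting upper components sit far above the global minimum.
* Densities are floored at 1e-300 inside likelihoods so that a shift
  crossing a data point yields a huge finite penalty instead of `-Inf`,
  which bounded quasi-Newton methods cannot digest.
* EM: relative log-likelihood tolerance 1e-6, at most 500 iterations;
  components with weight below 0.01 are pruned and EM restarted once.
  Ties in hard labels go to the lower component index; components are
  reported in ascending order of their means.
* `peak_height()` uses the erf closed form; for `B s_max^2 / 4 < 1e-4` the
  two closed-form terms cancel catastrophically, so a short alternating
  series takes over (the branch point is covered by a continuity test).
  Closed forms are verified against adaptive quadrature to 1e-9 relative
  in the suite.

## The local estimators

For a scrutinized atom with ADP `B1` and a comparator carrying the
environment's ADP `B2`, two questions are asked (both with point Gaussian
atoms, scattering factor `exp(-B s^2/4)`, truncated at `s_max`):

* **Peak height** (`occ_peak`): what occupancy `c` makes the comparator's
  central peak equal the atom's? `c = rho_B1(0) / rho_B2(0)`. Unbounded
  above as `B1 -> 0`; an artefact of using only the density at the centre.
* **Total density** (`occ_total`): what `c` best matches the whole
  density, by Parseval's theorem the least-squares answer
  `c = ∫ s^2 exp(-(B1+B2)s^2/4) ds / ∫ s^2 exp(-B2 s^2/2) ds`. Bounded by
  `2^(3/2) ≈ 2.83` (approached only as `B1 -> 0` at infinite resolution),
  so it systematically underestimates — a conservative flag.

Both have closed infinite-resolution limits, `(B2/B1)^(3/2)` and
`(2 B2/(B1+B2))^(3/2)`, used as convergence checks. These estimators are
deliberately *not* folded together with the model's refined occupancy
column: they are expressions of local ADP differences and a starting point
for occupancy refinement, not a replacement for it. Element-specific
scattering factors are intentionally omitted; for local ADP *differences*
point atoms suffice, and all uses are ratios where the constant prefactor
cancels.

### Environments and flags

`build_contexts()` gathers, for each atom, all atoms within **4.2 Å**
(default) excluding the atom's own residue, and summarizes them by the
exact **median** B — the median, not the mean, because environments
routinely contain a few outliers of exactly the kind being hunted. At
least **4 neighbours** are required for an estimate. `scan_atoms()` flags
`c_total <= 0.7` as `lighter` and `>= 1.3` as `heavier`; these defaults
bracket the regimes seen in practice (a wrong rotamer at ~0.64; metals
modelled as waters at ~1.36–1.37) and are fully configurable.
`ligand_report()` compares the ligand's median B with the median over all
non-ligand, non-water atoms within the radius of any ligand atom; waters
are excluded from ligand environments because they are freely re-placed
during rebuilding and drag the median toward the ligand's own regime,
while waters *are* retained as scan centres (misassigned metals are the
textbook catch).

## The synthetic-fixture generator

`build_toy_structure()` writes a minimal, valid PDB file whose ground
truth is known exactly: atoms on a jittered cubic lattice (spacing 1.8 Å,
jitter 0.15 Å) in spatially contiguous blocks, one per mixture component,
with B values drawn from the component SIGDs — emulating the
domain-per-mode structure of real multimodal crystals. Each lattice atom
is its own one-atom residue so that neighbour exclusion rules are
exercised without protein topology. Planted anomalies carry their indices
back to the caller: a water at half its environment's median B (a metal in
disguise), an atom at twice its environment (a misplaced atom), an 8-atom
ligand whose uniform B is chosen by numerically inverting `occ_total` to a
target relative occupancy (default 0.5), and an octahedrally coordinated
water site.

Two fixture regimes are used deliberately:

* **Published parameter sets** (the bimodal and trimodal mixtures and the
  unimodal entries of the test helpers) reproduce realistic, heavy-tailed
  ADP regimes for the *global* pipeline: recovery of weights, means and
  mode counts at n = 6000–9000 is the package's main statistical test
  (seed-fixed; the trimodal mode count is checked across 20 seeds with an
  allowance for the expected KDE failure rate).
* The **anomaly fixture** uses a narrow unimodal background
  (`alpha = 50, beta = 1470, B0 = 5`; mean 35 Å², sd ≈ 4.3 Å²), i.e. a
  very well-ordered structure. This is a design requirement, not a
  convenience: "the planted anomaly is the top-ranked flag" is only a
  well-posed ground truth when the background cannot produce a factor-2
  ADP excursion by chance (tail probability here ~1e-5 per atom). Under a
  broad, literature-typical background (`alpha ≈ 4`) natural tail atoms
  legitimately outrank a factor-2 plant — that is correct behaviour of the
  scan, but it makes the fixture's "truth" ambiguous.

What passing on these fixtures does **not** show: real structures have
bonded geometry, correlated ADPs along chains, solvent shells, alternate
conformations and anisotropy — none of which the lattice emulates. The
fixtures validate the estimators and the fitting machinery, not the
field-wide error rates of the method.

## Problem sizes and reproducibility

Simulation sizes in the suite (50 000 draws for single-component recovery,
6000/9000 for mixture recovery, 500-atom lattices for scans) were chosen
as the smallest sizes at which the published parameter regimes are
statistically recoverable at the asserted tolerances; they keep the whole
suite in the minutes range on a laptop. All stochastic steps take explicit
integer seeds (`rsigd`, `sample_mixture`, `build_toy_structure`,
`fit_sigd_mixture`); identical seed and spec give byte-identical fixture
files, and identical CLI invocations give byte-identical reports.

## Known limitations

* Anisotropic ADPs, crystallographic symmetry expansion for neighbour
  searches, and TLS-style parameterizations are out of scope; an atom
  close to a symmetry axis can carry a legitimate half occupancy that the
  scan will flag.
* `occ_total`'s `2^(3/2)` ceiling means extreme heavy-atom mismatches
  saturate rather than grow; rank by `|log c_total|` (as `scan_atoms`
  does), not by the raw value.
* Mode multiplicity says nothing about its cause — packing, disorder, or
  mismodelling; interpretation needs the mode-colored model
  (`write_mode_colored_model()`) and the maps.
* The EM is the standard mixture EM; no acceleration or damping is
  applied, and with heavily overlapping components the responsibilities
  (not the fit) can remain genuinely ambiguous.
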