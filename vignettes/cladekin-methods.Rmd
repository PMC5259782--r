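---
title: "Methods: residue scans, distance trees, and allosteric kinetics in cladekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residue scans, distance trees, and allosteric kinetics in cladekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladekin)
```

`cladekin` implements a two-pronged workflow for tracing an enzyme's
regulatory phenotype to individual residues: a comparative-sequence prong
(which residues separate the regulatory classes?) and a biochemical prong
(do the kinetics confirm the assignment?). This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and the limits of what the synthetic-data tests demonstrate.

## The residue scan

### Model

The scan treats an aligned protein family, stratified into clades
(taxonomic orders in the motivating PEPC case), as a samples-by-columns
table and applies two filters.

*Reference-unique* (`reference_unique_positions()`): a column is reported
when the reference sequence carries a non-gap residue that differs from
the residue of **every** other sequence. This is the strict reading of
"unique to the reference": one sequence contrasted against all others,
regardless of clade. `X` (unknown) in the reference never counts.

*Clade-discriminating* (`discriminating_positions()`): a column is
reported when the target clade's consensus frequency is at least
`conservation_threshold` and the target consensus residue differs from
the consensus residue of **each** contrast clade. Candidate sites
(`candidate_screen()`) are the intersection, reported in ascending column
order with reference-frame positions attached.

### Parameters and defaults

* `conservation_threshold = 0.9`. "Highly conserved" has no canonical
  number; 0.9 requires near-fixation in the target clade while tolerating
  one divergent member in clades of ten or more. It is exposed as an
  argument and on the command line, and raising it can only shrink the
  site set (monotonicity is property-tested).
* `other_gap_policy = "treat-as-mismatch"`. A gap in another sequence
  counts as "different from the reference" and stays in the consensus
  denominator. The rationale: an indel at a position is evidence that the
  position is not conserved there, which is what both filters are probing.
  The alternative (`"ignore-gapped-rows"`) drops gapped rows from the
  comparison and the denominator; it is preferable when the alignment has
  long ragged termini that would otherwise flood the unique set.
* `strict_contrast = FALSE`. "Different from those in either contrast
  clade" is read permissively — different from each contrast clade's
  *consensus* — because order-level signatures are consensus properties.
  The strict variant (absence from every contrast member) is available
  for workflows that cannot tolerate a single contrast carrier.
* Consensus ties are broken by a fixed alphabetical amino-acid ordering.
  A tie means the data do not identify a consensus; any deterministic rule
  is as defensible as any other, and a fixed ordering keeps runs and the
  tie's documentation stable.

### Coordinates

Positions are 1-based on the ungapped sequence including the initiator
methionine — the numbering used when a residue is named "E954" in a
~150 kDa subunit. The maps are built by counting non-gap characters
(`cumsum`), are bijective between non-gap columns and positions, and are
property-tested as such on fuzzed gapped alignments.
`equivalent_position()` composes two maps through the shared column and is
symmetric whenever both endpoints are non-gaps.

## The phylogeny stage

Tree inference here exists to support clade-grouping statements (are the
*Chroococcales* PEPCs one cluster?), not to estimate divergence dates or
rates. Accordingly it is distance-based by design: p-distances with
pairwise deletion over a chosen column set (gap-free columns by default),
Poisson correction $d = -\ln(1-p)$ for multiple hits, neighbor joining,
and column bootstrap. Maximum-likelihood inference is deliberately not
re-implemented; an externally computed ML tree can be read with
`read_newick()` and interrogated with `is_monophyletic()` exactly like a
native one.

Numerical choices:

* A sequence pair with no mutually ungapped column, or with $p = 1$ under
  the Poisson model, has no finite distance; both raise errors with
  guidance rather than propagating `Inf` into NJ.
* Negative NJ branch lengths (possible on non-additive matrices) are
  clamped to zero with the deficit moved to the sibling edge — the
  standard practice — and reported via a message. On additive matrices NJ
  is exact, which is property-tested against 100 random trees at 1e-9.
* Bootstrap resamples **columns** with replacement (same count),
  rebuilds the tree per replicate, and annotates each internal bipartition
  of the point tree with the percentage of replicates containing it. A
  replicate whose resampled columns produce a distance failure is skipped
  with a warning and the denominator adjusted. The seed is a required
  argument: support values are only meaningful when reproducible.

## The kinetics stage

### From absorbance to velocity

The coupled assay reads PEPC turnover as NADH oxidation by malate
dehydrogenase: absorbance at 340 nm falls linearly while the assay is in
its initial-rate regime. `initial_rate()` uses
$v = |\text{slope}| / (\varepsilon \, l) \times V$ with
$\varepsilon_{340}(\text{NADH}) = 6.22\ \text{mM}^{-1}\text{cm}^{-1}$,
path length 1 cm and volume 1 mL by default — the standard constants for
this assay; all three are arguments. The default window is the longest
prefix of the trace with linear $r^2 \ge 0.99$ (minimum 4 points), which
backs off automatically when substrate exhaustion bends the trace; a
fixed `first-k-points` window is available. A rising trace means no NADH
consumption; the velocity is reported as 0 with a warning rather than as
a negative rate. One enzyme unit is 1 µmol NADH consumed per minute.

### Parameter estimation

`fit_michaelis_menten()` implements the classical Lineweaver–Burk route —
unweighted ordinary least squares of $1/v$ on $1/[S]$, $V_{max} =
1/\text{intercept}$, $K_m = \text{slope}/\text{intercept}$ — because that
is the method the motivating analyses used, and a direct nonlinear
least-squares route (Levenberg–Marquardt on $v = V_{max}[S]/(K_m+[S])$,
initialised from the LB estimate) as the statistically preferred
cross-check. On noiseless data the two agree to better than $10^{-6}$
relative (tested). Replicates are averaged to velocity means *before* the
reciprocal transform by default (`average_replicates`), so a noisy low
velocity cannot dominate the reciprocal regression; pooling is available.

Under the package's own noise model (multiplicative Gaussian error,
5% CV, triplicates), simulation shows NLS with a lower median $K_m$ error
than LB (about 4.6% vs 4.9%), but not uniformly better per dataset — with
roughly constant CV the reciprocal transform is approximately
variance-stabilising, so the classical plot is less fragile than its
reputation. Both routes are therefore reported by the pipeline.

Failure modes are explicit: non-positive velocities are dropped from the
reciprocal fit with a warning; a non-positive fitted $1/v$ intercept (no
saturation, as for a catalytically dead variant) is a fit *error*, not a
nonsense parameter pair.

### Effectors, inhibition modes, optima

Relative activity is each effector replicate as a percentage of the mock
mean (mock ≡ 100%), summarised as mean ± sample SD with a paired
two-tailed t-test against mock when replicate counts match. Fixed,
half-saturating-substrate panels are analysed **only** this way — a
single-concentration measurement cannot support $K_m$ inference.
`classify_inhibition_mode()` labels the $(V_{max}, K_m)$ change pattern
with a relative-change threshold of 0.15 (changes below 15% count as
"unchanged"; the threshold is an argument). The joint-increase pattern
gets its own label because dicarboxylate effectors of cyanobacterial PEPC
raise both parameters, which the textbook competitive/noncompetitive
dichotomy does not name. `find_optimum()` is an argmax over the measured
grid — no interpolation, because assay grids are coarse and a fitted peak
would manufacture precision; ties go to the lower grid value (logged) and
boundary maxima carry a warning. `inhibition_vs_ph()` compares each
higher pH against the lowest one and flags inhibition enhanced at
alkaline pH when relative activity drops.

Degrees of freedom in the paired t-test are $n-1$; zero-variance
differences raise a "degenerate" error instead of returning $p = 0$. SDs
are sample (n−1) SDs throughout; a single replicate has no SD and says
so.

## The synthetic-data generators

The generators define the conditions under which the pipeline is tested.

* `generate_clade_msa()` draws a root sequence uniformly over the 20
  amino acids, derives clade consensuses by per-column divergence
  (default probability 0.1), adds within-clade substitution noise
  (default 0), plants reference-unique and candidate columns, and applies
  per-residue indels (default 0). Substitutions are uniform over the 19
  alternative residues — only conservation patterns matter to the scan,
  so no empirical rate matrix is used. Planted columns are kept gap-free
  and noise-free so ground truth is exact; two invariants make recovery
  properties clean: no column is all-gaps, and indels never gap *all* of
  the reference's clade-mates in a column (otherwise a background column
  becomes genuinely reference-unique at zero noise, which is a property
  of gaps, not a scan defect).
* `generate_assay_dataset()` draws $v = V_{max} f_V [S] / (K_m f_K +
  [S]) \times (1 + \text{cv}\,z)$ with $z$ standard normal per replicate
  and $(f_V, f_K)$ the effector's multiplicative factors. Noise is
  multiplicative because effector-panel SDs scale roughly with the mean.
  Default replicate count is 3 and the default protein amount 4 pmol =
  0.6 µg, the assay amounts of the motivating study. `assay_traces()`
  inverts the velocity–slope relation to emit linear A340 traces, so the
  trace-reduction stage can be tested as an inverse pipeline (identity to
  1e-9 noiseless).
* `generate_activity_profile()` produces a Gaussian-shaped unimodal
  profile with the peak, width and grid as parameters.

All generators are pure functions of (config, seed); regenerated outputs
are byte-identical, which is tested.

What passing these tests shows — and does not. Exact round-trips prove
the fitting and reporting machinery is algebraically correct, and the
property suites prove the advertised invariants under the stated noise
models. Real assay data have correlated drift, instrument dead time, and
non-Michaelis behaviour near zero substrate; real alignments have
alignment error, compositional bias and rate heterogeneity that uniform
substitutions do not emulate. Conclusions about a real enzyme family
still require the user's own sequences and titrations; the package's
claim is that, given them, the arithmetic between input and conclusion is
sound.

## Problem sizes

The shipped tests run the scan oracle on alignments up to 10 × 200,
planted-truth recovery on 100 random configurations, NJ exactness on 100
random additive matrices, parameter recovery on 200 seeded noisy
titrations, and the paired-t type-I simulation on 10,000 null datasets —
sizes at which every suite completes comfortably on a single CPU while
keeping Monte-Carlo standard errors small relative to the asserted
bounds.

## Known limitations

* The scan has no phylogeny-aware conservation weighting and no
  entropy/mutual-information scoring; it is the exact two-filter rule,
  which is what makes its output auditable.
* NJ on Poisson-corrected distances can differ from ML topologies when
  rates vary strongly across lineages; bootstrap supports quantify
  resampling stability, not model adequacy.
* The Lineweaver–Burk route inherits the classical plot's sensitivity to
  errors at low substrate; the NLS cross-check is reported alongside it
  for that reason.
* The aliphatic index is exposed in both the Ikai-weighted form (default)
  and as a plain A/V/I/L percentage, since "ratio of Ala, Val, Ile, Leu"
  is ambiguous between the two in informal usage.
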