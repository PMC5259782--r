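# cladekin

Linking protein-family sequence variation to enzyme regulation: a
clade-discriminating residue scan over protein alignments, distance-based
phylogenetics with bootstrap support, and allosteric enzyme-kinetics
analysis — with seeded synthetic-data generators so the whole pipeline can
be exercised against known ground truth.

The package is motivated by cyanobacterial phosphoenolpyruvate carboxylase
(PEPC), where tolerance to allosteric inhibition by dicarboxylates
(malate, aspartate, fumarate) tracks a single residue that is conserved
within one taxonomic order (lysine in the *Nostocales*) but divergent in
others (glutamate in *Synechocystis*, order *Chroococcales*). Finding such
a residue is a specificity-determining-position problem; confirming it is
an enzyme-kinetics problem. `cladekin` covers both ends.

## What it does

**Residue scan** (`candidate_screen()`): given an aligned protein FASTA
and an `id → order` clade table, find the alignment columns where

1. a chosen reference sequence carries a residue different from *every*
   other sequence (`reference_unique_positions()`), and
2. a target clade is conserved (consensus frequency ≥ 0.9 by default) for
   a residue that differs from each contrast clade's consensus
   (`discriminating_positions()`).

Sites are reported in the reference's own ungapped coordinates via
gap-aware coordinate maps (`column_to_position()`,
`equivalent_position()`), the convention in which a residue is called
"E954". `known_site_conservation()` audits user-supplied functional
positions; `aliphatic_index()` gives the Ikai thermostability proxy
`100·(X_Ala + 2.9·X_Val + 3.9·(X_Ile + X_Leu))`.

**Phylogeny** (`pairwise_distances()`, `neighbor_joining()`,
`bootstrap_support()`): Poisson-corrected distances `d = −ln(1−p)` over
low-gap columns, NJ tree, column-resampled bootstrap percentages, and
bipartition tests (`is_monophyletic()`). This is a deliberately light
distance-based stand-in for likelihood tree inference, sufficient for
order-level grouping claims; externally computed trees can be imported as
Newick.

**Kinetics** (`initial_rate()`, `fit_michaelis_menten()`,
`effector_table()`): initial velocities from A340 traces of the
NADH-coupled assay (`v = |slope|/(6.22·l)·V`, in enzyme units = µmol
NADH·min⁻¹), Michaelis–Menten fits by the classical Lineweaver–Burk
double-reciprocal regression (`1/v` on `1/[S]`; intercepts `1/Vmax` and
`−1/Km`) with a nonlinear least-squares cross-check, relative-activity
panels versus mock with paired two-tailed t-tests, inhibition-mode
classification from the (Vmax, Km) change pattern, and pH/temperature
optimum detection.

**Synthetic data** (`generate_clade_msa()`, `generate_assay_dataset()`,
`generate_activity_profile()`): seeded generators that emit the same
formats the analysis consumes, paired with ground-truth records — planted
scan columns, true kinetic parameters, effector factors, profile peaks.

## Worked example

```r
library(cladekin)

# simulate a 3-order alignment with one planted candidate column …
sim <- generate_clade_msa(msa_sim_config(length = 200, indel_prob = 0.02,
                                         planted_candidate = 150, seed = 1))
scan <- candidate_screen(sim$alignment, sim$ref_id,
                         scan_params("Nostocales",
                                     c("Chroococcales", "Oscillatoriales")))
scan[, 1:5]
#> # A tibble: 1 × 5
#>   column reference_position reference_residue target_residue target_frequency
#>    <int>              <int> <chr>             <chr>                     <dbl>
#> 1    150                147 P                 G                             1
```

The planted column 150 is recovered, reported at reference position 147
because indels upstream shifted the ungapped numbering — exactly the
bookkeeping that relates homologous positions such as 954 and 946 in two
PEPCs.

```r
# … and a noiseless substrate titration at the wild-type parameters
d <- generate_assay_dataset(assay_sim_config(
  variants = tibble::tibble(variant = "SyPEPC",
                            vmax = 1.74 * 0.6e-3,   # units, 0.6 µg enzyme
                            km_mM = 0.34),
  cv = 0, n_reps = 1, seed = 1))
fit <- fit_michaelis_menten(d$rates, method = "LB")
glance(fit)
#> # A tibble: 1 × 5
#>      vmax    km method r_squared n_points
#>     <dbl> <dbl> <chr>      <dbl>    <int>
#> 1 0.00104 0.340 LB             1        6
specific_activity(fit$vmax, pmol = 4, ug = 0.6)
#> # A tibble: 1 × 3
#>   units_per_mg units_per_pmol implied_mass_kda
#>          <dbl>          <dbl>            <dbl>
#> 1         1.74       0.000261              150
```

The double-reciprocal stage hands back the generating parameters — Km
0.34 mM, specific activity 1.74 units/mg from 4 pmol (0.6 µg) of enzyme,
implying the expected ~150 kDa subunit.

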