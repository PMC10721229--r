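# mabsolkit

Solution-biophysics analysis for antibody fragments (and other proteins) in
electrolyte: the complete post-simulation and experimental-fit pipeline that
connects molecular trajectories of a protein plus ions to the quantities
measured by small-angle neutron scattering (SANS) and static light
scattering (SLS).

Monoclonal-antibody Fab and Fc fragments are ~50 kDa, ellipsoidal, charged
(+11e and +2e at pH 7 in the canonical case) proteins whose solution
behaviour — size, hydration, ionic double layer, and mutual attraction or
repulsion — controls formulation stability. This package implements, in
base-R S3 style, every analysis stage of that workflow:

| stage | functions |
|---|---|
| size & shape per frame | `radius_of_gyration`, `rg_distribution`, `axis_dimensions`, `sasa` |
| hydration / ion shells | `surface_rdf`, `rescale_rdf`, `coordination_number`, `survival_probability` |
| electric double layer | `net_charge_profile`, `debye_fit`, `pb_debye_length` |
| free energy & virial | `wham`, `pmf_to_b22`, `b22_report` |
| scattering estimators | `guinier_fit`, `q_from_angle`, `sls_debye_fit` |
| synthetic ground truth | `gen_protein_trajectory`, `gen_ion_cloud`, `gen_umbrella_windows`, `gen_sans_curve`, `gen_sls_series` |
| formats | GRO / PDB / XYZ / XVG / CSV readers and writers, `select_atoms` |

## The models at the core

**Radius of gyration.** Per frame over a selection,
`Rg² = Σᵢ mᵢ (rᵢ − R_com)² / Σᵢ mᵢ`. Anatomical dimensions (long axis LA,
width W, height H) are absolute components of marker-pair
centre-of-mass distance vectors along the gyration-tensor principal axes.

**Surface-distance RDFs.** Each solvent/ion atom is binned by its minimum
(minimum-image) distance to any protein atom and counts are divided by the
bin width, so the integral of the profile to `r` *is* the mean number of
atoms within `r` of the surface. The cumulative ion imbalance gives the
net charge `Qnet(r) = Q_protein + n₊(r) − n₋(r)`, fitted by
`A₀ exp(−r/ζ)` on 0.25–1.0 nm; the Poisson–Boltzmann closed form
`ζ = sqrt(ε_r ε₀ k_B T / (2 e² N_A C'))` gives 0.79 nm for ε_r = 78,
C = 0.15 mol/L, T = 300 K.

**WHAM → B22.** Umbrella windows (harmonic restraints on the inter-protein
centre-of-mass distance) are combined by the self-consistent weighted
histogram equations into a potential of mean force ΔG(r); the second
osmotic virial coefficient follows from
`B22 = −(2π N_A / Mw²) ∫ (g(r) − 1) r² dr`, `g(r) = exp(−ΔG(r)/RT)`,
with a hard-core rule below the sampled range and a bulk tail above.
Negative B22 means net attraction, positive net repulsion.

**Scattering estimators.** Guinier: `I(q) = I(0) exp(−q²Rg²/3)` fitted on
the self-consistent region `q·Rg ≤ 1.3`. SLS Debye plot: `KC/Rθ` versus
concentration has intercept `1/Mw` and slope `2·B22`.

Every generator knows its ground truth, so each estimator is validated by
parameter recovery; closed forms (hard-sphere and square-well B22,
spherical-cap SASA, two-state Markov survival) back the quadratures.

## Worked example

```r
library(mabsolkit)

# double layer around a +11e protein in ~150 mM 1:1 salt
spec <- ion_cloud_spec(protein_charge = 11, target_zeta = 0.79,
                       box_edge = 12, n_ion_pairs = 148, seed = 42)
ions   <- gen_ion_cloud(spec, n_frames = 400)
prot   <- select_atoms(ions, species == "protein")
rdf_na <- surface_rdf(ions, prot, select_atoms(ions, species == "cation"), bin_width = 0.02)
rdf_cl <- surface_rdf(ions, prot, select_atoms(ions, species == "anion"),  bin_width = 0.02)
debye_fit(net_charge_profile(rdf_na, rdf_cl, q_protein = 11))
#> Exponential decay fit (nls, window 0.25-1.00 nm, 38 points):
#>   A0 = 10.8279 e, zeta = 0.8240 nm, rms residual = 0.032 e
pb_debye_length(eps_r = 78, conc = 0.15, temperature = 300)
#> [1] 0.7853757   # prints as 0.79 nm at 2 decimals

# PMF reconstruction and virial coefficient for an Fc-like pair
pmf     <- analytic_pmf("gaussian_well", well_depth = 14, well_center = 3.6,
                        well_width = 0.25, r_range = c(3, 8))
windows <- gen_umbrella_windows(pmf, umbrella_protocol(samples_per_window = 20000, seed = 7))
b22_report(windows, mode = "fc")
#> PMF profile: 200 bins on 3.013-7.987 nm, min -13.82 kJ/mol at 3.587 nm
#>   zero reference at r = 7.987 nm; converged in 14114 iterations
#> B22 = -1.4331e-03 mol mL / g^2 (Mw = 49635 g/mol, T = 300 K)
#>   grid [3.01, 7.99] nm: -1.4471e-03; core (hard_core, r < 3.01): 1.3996e-05
#>   quadrature error estimate: 1.62e-06

# experimental-side estimators on synthetic instrument data
guinier_fit(gen_sans_curve(rg = 2.65, noise_sd = 0.01, seed = 1))
#> Guinier fit: Rg = 2.6535 nm, I(0) = 100.2 (40 points, q in 0.038-0.485 1/nm)
#>   q_max * Rg = 1.287 (criterion 1.30), R^2 = 0.99727
sls_debye_fit(gen_sls_series(mw = 49635, b22 = -7.77e-2, noise_sd = 0))
#> Debye plot: Mw = 49635 g/mol, B22 = -7.7700e-02 mol mL / g^2
#>   slope = -1.5540e-01 +/- 1.4e-17 (2 x B22), 8 points
```

The fitted ζ = 0.824 nm sits within the Monte-Carlo sampling error of the
generating 0.79 nm; the reconstructed well depth −13.8 kJ/mol recovers the
planted −14 kJ/mol well; the Guinier and Debye-plot fits return the
generating Rg, Mw and B22.

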