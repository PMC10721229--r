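---
title: "Models and methods behind mabsolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mabsolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabsolkit)
```

mabsolkit analyses proteins — in the canonical use case the Fab and Fc
fragments of an IgG monoclonal antibody, ~50 kDa ellipsoidal bodies with
net charges of order +11e and +2e at neutral pH — in monovalent
electrolyte. This vignette is the package's own account of the models it
implements, the conventions and tunable parameters, what the synthetic
generators do and do not emulate, and the numerical choices that were
genuinely open.

Units are global: distances nm, energies kJ/mol, charges e, masses g/mol,
times ps, temperatures K. Physical constants are pinned to CODATA 2018
values in `phys_constants`.

## Structural metrics

`radius_of_gyration()` evaluates the mass-weighted
$R_g^2 = \sum_i m_i (\mathbf r_i - \mathbf R_\mathrm{com})^2 / \sum_i m_i$
per frame. Selections are assumed whole (no minimum-image wrapping across
a selection): the package analyses trajectories in which molecules have
already been made whole, as is standard after post-processing. A
cross-check identity — $R_g^2$ equals the trace of the mass-weighted
gyration tensor — is enforced in the test suite through two independent
code paths.

`rg_distribution()` bins per-frame values at 0.01 nm by default. That
width was chosen to resolve conformational bimodality of the kind seen in
flexible fragments, where competing compact/extended states sit ~0.15 nm
apart; it is a plain argument if data need coarser bins.

`axis_dimensions()` quantifies the anisotropy of an ellipsoidal protein as
three anatomical dimensions: long axis (LA), width (W) and height (H). Per
frame the mass-weighted gyration tensor of the selection is diagonalised;
eigenvectors sorted by descending eigenvalue define PA1–PA3. For each of
three user-supplied marker pairs (residue groups at opposite ends of an
axis) the distance vector between the two groups' centres of mass is
projected on the pair's assigned axis and the absolute component is
reported. Two conventions deserve note:

* **Marker semantics.** Dimensions are distances between marker-group
  *centres of mass* projected on principal axes — not the maximum atomic
  pair distance. When a source describes both, the centre-of-mass reading
  is adopted: it is stable under thermal noise and is the quantity a
  reflectivity model actually consumes.
* **Axis assignment across frames.** Axes are ordered by eigenvalue in
  every frame; this is the anatomical assignment whenever the three
  moments are distinct. Only inside a nearly degenerate eigenvalue pair
  (relative gap below `degeneracy_tol`, default 1e-6) is the order
  ambiguous, and there it is tie-broken by overlap with the previous
  frame's axes, with a warning. A global "match the previous frame"
  permutation was rejected: on trajectories whose frames are not
  temporally correlated (e.g. the synthetic generator's independent
  rotations) it scrambles the anatomical labels, while for smooth MD data
  it coincides with eigenvalue ordering anyway.

`sasa()` is a Shrake–Rupley implementation: each atom's sphere is inflated
by the probe radius (default 0.14 nm, a water probe) and covered with a
deterministic Fibonacci lattice (default 960 points; quadrature error well
under 1% for protein-like packings, and the suite checks 960 vs 4000
points agree to 0.5%). Neighbour search uses a grid cell list. Radii come
from a small, explicit Bondi table keyed by element — an unknown element
is an error, never a silent default — or from per-atom values supplied
directly, which is how bead models are handled.

## Solvation shell and double layer

`surface_rdf()` implements the *surface-minimum-distance* RDF: every
species atom contributes to the bin of its minimum (minimum-image,
orthorhombic boxes only) centre-to-centre distance to any protein atom,
and bin counts are divided by the bin width and averaged over frames. No
solvent-excluded surface is constructed and no van der Waals offsets are
applied: "distance to the protein surface" means exactly this minimum
atom-centre distance. The defining property — the integral of the profile
up to $r$ equals the mean number of species atoms within $r$ — is what
`coordination_number()` evaluates. Because the profile is a histogram
(piecewise constant), that integral is computed exactly as bin sums plus a
partial final bin; a trapezoid on bin centres would break the count
identity at the bin scale, so the exact form is used.

The default bin width is 0.002 nm for hydration/ion work (first peaks sit
near 0.3 nm and are sharp); the ion-cloud analyses in the tests use
0.02 nm, which is ample for exponential decays with ζ ≈ 0.8 nm.

`rescale_rdf()` reproduces the bulk-normalisation procedure: a straight
line is least-squares fitted on a stated window (default 1–2 nm, where
structuring has decayed) and the whole profile is divided by that line,
mapping bulk behaviour to 1. If the fitted line crosses zero inside the
profile's support the operation aborts — dividing by it would manufacture
structure.

`net_charge_profile()` accumulates
$Q_\mathrm{net}(r) = Q_\mathrm{protein} + n_+(r) - n_-(r)$ for monovalent
ions on the shared cation/anion grid; on a neutral box the drop over
$[0, L/2]$ equals $-Q_\mathrm{protein}$ as an exact integer identity,
which the tests assert to 1e-9.

`debye_fit()` fits $A_0 e^{-r/\zeta}$ by Levenberg–Marquardt nonlinear
least squares (via minpack.lm) in *linear* space on the window
0.25–1.0 nm — the bulk ionic-cloud region outside the adsorption layer.
Linear space is the default because weakly charged proteins can drive
$Q_\mathrm{net}$ through zero, which log-space regression cannot
represent; a log-linear mode exists for strictly positive data and doubles
as the starting-value heuristic. The RMS residual is always reported so
deviations from exponential decay are quantifiable rather than hidden.

`pb_debye_length()` evaluates the Poisson–Boltzmann screening length for a
1:1 electrolyte,
$\zeta = \sqrt{\varepsilon_r \varepsilon_0 k_B T / (2 e^2 N_A C \cdot 10^3)}$
(C in mol/L). Note an erratum-style caveat: the formula sometimes appears
in print with the ratio inverted; the form implemented here is the
standard one and reproduces the well-known benchmark of 0.79 nm for pure
water (ε_r = 78) at 150 mM and 300 K, which is also the package's fastest
acceptance check.

`survival_probability()` offers both standard residence estimators over a
cutoff shell (default 0.35 nm): *intermittent*
$P(t) = \langle h(t_0) h(t_0{+}t)\rangle / \langle h(t_0)\rangle$ and
*continuous* (the product over the whole window, so one excursion kills
the event). Both are labelled on the result because published analyses
frequently leave the choice implicit; intermittent is the default. The
continuous curve is non-increasing and never exceeds the intermittent one;
the intermittent estimator is validated against the closed form of a
two-state Markov occupancy process.

## WHAM and the virial coefficient

`wham()` combines umbrella windows (restraint centres $x_i$, spring
constant $k$, samples) over a common grid by the self-consistent
equations

$$p_j = \frac{\sum_i n_{ij}}{\sum_i N_i e^{f_i/RT} e^{-U_i(x_j)/RT}},
\qquad e^{-f_i/RT} = \sum_j e^{-U_i(x_j)/RT} p_j,$$

iterated until $\max_i |\Delta f_i| < 10^{-8}$ kJ/mol (cap $10^5$
iterations; hitting the cap is an error that reports the final residual,
never a silent return). The default iteration runs in linear space with
the bias factors precomputed — safe here because every window contains its
own centre, where the bias factor is 1 — and a fully log-sum-exp
stabilised path (`method = "logsumexp"`) is available and tested to agree.
The default 200 bins resolve a 0.1 nm window ladder comfortably; adjacent
windows must share an occupied bin or the gap is reported by index.

Conventions: $\Delta G(r) = -RT \ln p(r)$ is shifted so the reference is
exactly zero. Three reference choices exist: the largest sampled bin
(default), a user-named $r$, or `"plateau"` — zero *mean* over the last
0.5 nm of the sampled range. The plateau convention exists because a
single far-edge bin carries the fewest samples; its noise rigidly shifts
the whole profile, and any downstream exponentiation (the virial integral)
turns a 0.3 kJ/mol shift into a ~12% error. `b22_report()` therefore
defaults to the plateau reference while `wham()` alone keeps the
single-bin convention.

Uncertainties come from a Bayesian bootstrap (default 50 replicates when
enabled): samples within each window are reweighted with Dirichlet(1)
weights and WHAM is re-solved from a warm start. The suite also checks
the conventional convergence diagnostic that first-half and full-sample
profiles agree within bootstrap error.

`pmf_to_b22()` evaluates
$B_{22} = -\frac{2\pi N_A}{M_w^2}\int_0^\infty (g(r)-1) r^2\,dr$ with
$g = e^{-\Delta G/RT}$, trapezoid on the PMF grid, $r$ in cm inside the
integral so the result carries mol·mL/g². Below the sampled range the
default *hard-core* rule sets $g = 0$ (two proteins cannot overlap there);
its contribution is reported separately so its influence is auditable.
Above the range the *bulk* rule sets $g = 1$ (zero contribution), which
requires the PMF to be zero-referenced at its upper end within 0.5 kJ/mol
— violating that is an error demanding re-referencing, because a non-zero
plateau would integrate to an infinite tail. The quadrature error estimate
is the trapezoid/Simpson difference on the same grid. The spherical
approximation is retained exactly as stated: no orientational averaging.

Sign conventions are tested: purely repulsive profiles give $B_{22} > 0$,
attractive wells $B_{22} < 0$, and pointwise-deepening a well never
increases $B_{22}$.

## Scattering estimators

`guinier_fit()` fits $\ln I = \ln I_0 - (R_g^2/3) q^2$ iteratively: fit,
recompute the limit $q_\mathrm{max} = 1.3/R_g$, refit, until the point set
is stable. The criterion is the standard dimensionless $q R_g \le 1.3$.
Two robustness choices: (i) the initial set is the lowest-q decile but
widens progressively if noise leaves that narrow window without a negative
slope; (ii) a two-state cycle in which a single point sits exactly on the
limit is resolved to the smaller set — this preserves the self-consistency
invariant $q_\mathrm{max} R_g \le 1.3$ — while genuine oscillation remains
an error that reports both candidate sets. With per-point uncertainties
the fit is weighted by $(I/\sigma_I)^2$, the delta-method weight for
$\ln I$.

`sls_debye_fit()` is ordinary least squares of $KC/R_\theta$ on
concentration: intercept $1/M_w$, slope $2 B_{22}$. Concentrations enter
in mg/mL at the interface and are converted to g/mL internally so
$B_{22}$ emerges in mol·mL/g². A non-positive intercept (unphysical
apparent molecular weight) is an error flagging calibration problems, as
is a rank-deficient design. `sls_optical_constant()` provides the standard
Rayleigh $K = 4\pi^2 n_0^2 (dn/dC)^2 / (N_A \lambda^4)$ for users starting
from raw Rayleigh ratios (defaults λ = 633 nm, dn/dC = 0.185 mL/g — the
mL/g unit is the physically sensible reading of the occasionally
misprinted "mg/L" — n₀ = 1.33); supplying $KC/R_\theta$ directly is the
primary path.

## The synthetic-data generators

The generators produce every input the pipeline consumes, with known
ground truth. They are statistical, not physical: no force field, water
model or integrator is emulated, so passing tests demonstrate estimator
correctness, not MD realism.

* `gen_protein_trajectory()`: a bead shell on an ellipsoid (default
  semi-axes chosen so the marker-derived dimensions are 7.8/5.75/4.55 nm,
  the crystal-structure values used for Fab-like bodies), rigid random
  rotation + translation per frame, optional isotropic "breathing" scale
  factor $1 + a u$, $u \sim U[-1,1]$, $a \in [0, 0.5)$. The shell is
  reflection-symmetrised so the body-frame gyration tensor is exactly
  diagonal; the principal axes then coincide with the geometric semi-axes
  and the dimension fixture is exact rather than lattice-limited. What it
  does not emulate: internal conformational dynamics, solvent, or
  anisotropic fluctuations.
* `gen_ion_cloud()`: a single central "protein" atom, `n_ion_pairs`
  neutral cation/anion pairs uniform in the half-box sphere, and exactly
  $|Q_\mathrm{protein}|$ excess counter-ions with radial density
  $\propto e^{-r/\zeta}$ (inverse-CDF sampling). Every frame conserves
  total charge exactly; the ensemble-mean net charge decays as
  $Q_\mathrm{protein} e^{-r/\zeta}$, so `debye_fit()` recovery is a
  well-posed Monte-Carlo test with no electrostatics solver involved. The
  defaults (+11e, 148 pairs, 12 nm box, ζ = 0.79 nm) mirror a Fab-like
  fragment in ~150 mM NaCl; the concentration is nominal metadata — the
  generator does not reproduce any particular solvent-volume convention.
  Ion–ion correlations, finite ion size and co-ion adsorption (which real
  force fields show) are deliberately absent.
* `gen_umbrella_windows()`: per window, a bank of up to 256 independent
  vectorised Metropolis chains samples
  $\exp\{-[\Delta G(x) + \tfrac{k}{2}(x - x_i)^2]/RT\}$ on the PMF's
  support, with 1000 burn-in steps, 10× thinning and proposal scale
  $2.4\sqrt{RT/k}$ — burn-in and thinning sized so kept samples are
  effectively decorrelated and WHAM error bars are meaningful.
  An overall acceptance rate below 0.05 aborts — that regime means the
  spec is pathological (e.g. a spring too weak to confine the walker in
  the support). The default protocol is the standard fragment–fragment
  ladder: 51 windows, 3.0–8.0 nm, 0.1 nm spacing, k = 1000 kJ/mol/nm²,
  300 K. In the large-k limit the window variance approaches $RT/k$
  (equipartition), checked at 10%.
* `gen_sans_curve()` / `gen_sls_series()`: Guinier-law curves with
  *multiplicative* Gaussian noise (count-statistics character; negative
  intensities are resampled, not clipped) on a q grid spanning 0.1/Rg to
  2.5/Rg, and linear Debye-plot series with *additive* noise (instrument
  character).

Temperature defaults to 300 K everywhere.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data sized for a
single-CPU minute-scale budget while leaving comfortable statistical
margins: WHAM recovery of a 14 kJ/mol Gaussian well (centre 4.5 nm, width
0.3 nm — mid-ladder values fixed once, since only the depth and the
window layout are externally prescribed) uses 5×10⁴ samples per window,
where the reconstruction error is ≲ 0.4 kJ/mol everywhere; the end-to-end
windows→WHAM→B22 comparison in the acceptance script uses 2×10⁵ samples
per window because the statistical window-stitching error of the
reconstructed profile (a zero-mean $N^{-1/2}$ effect) is exponentiated by
the virial integral, so the free-energy profile must be resolved a few
times more finely than the 10% bound on B22 implies; the ion-cloud
recovery pools
2500 frames (~770k ion positions); Guinier calibration uses 200 noise
realisations.

Other numerical decisions, collected: WHAM tolerance $10^{-8}$ kJ/mol on
window free energies with a linear-space default and log-sum-exp option;
bootstrap 50 replicates with logged seeds; histogram-exact coordination
integrals; minimum-image for orthorhombic boxes only, with triclinic
boxes rejected loudly; GRO written at the format's native 3 decimals (nm),
PDB and XYZ converted from Å on read; 0-based internal thinking never
leaks — all atom ids are 1-based as in the file formats.

## Known limitations

* Readers are in-memory; a 54k-water MD frame series should be subset
  (e.g. strip water) before loading, as the package does not stream.
* Minimum-image support is orthorhombic only.
* `axis_dimensions()` requires marker groups as input; the package ships
  no residue-to-marker mapping for real antibody structures (those
  assignments are structure-specific), and the ellipsoid generator is the
  reference fixture instead.
* The virial integral retains the spherical approximation; orientational
  averaging over anisotropic PMFs is out of scope.
* The survival-probability estimators are the two standard definitions;
  windowed origin spacing beyond "all origins" is not implemented.
* Synthetic generators validate estimators, not force fields: agreement
  on generator output says nothing about how a particular force-field /
  water-model combination behaves on real proteins.
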