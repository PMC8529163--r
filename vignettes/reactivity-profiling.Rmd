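---
title: "Reactivity profiling and pharmacokinetic screening with cdftscreen"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdftscreen)
```

## What this package computes

`cdftscreen` implements the computational half of a phytoligand screening
study: conceptual density-functional-theory (CDFT) reactivity descriptors for
a set of candidate ligands, consistency diagnostics for the underlying
electronic-structure data, finite-difference local reactivity on volumetric
electron densities, rule-based interpretation of bioactivity and ADMET
prediction tables, docking-table analytics, and Ellman-assay dose-response
math. The electronic-structure calculations themselves (Kohn–Sham DFT on the
N, N−1 and N+1 electron systems) and the web-server ADMET predictors are out
of scope: the package consumes their tabulated outputs, or synthetic
stand-ins generated with properties known by construction.

## The global descriptor model

All global descriptors derive from the vertical ionization potential $I$ and
electron affinity $A$ of a ligand (eV throughout):

$$\chi = \frac{I+A}{2}, \qquad \eta = I - A, \qquad S = \frac{1}{\eta},
\qquad \omega = \frac{\chi^2}{2\eta},$$
$$\omega^- = \frac{(3I+A)^2}{16\eta}, \qquad \omega^+ = \frac{(I+3A)^2}{16\eta},
\qquad \Delta\omega^\pm = \omega^- + \omega^+ .$$

$\chi$ is the Mulliken electronegativity, $\eta$ the global hardness
(resistance to charge transfer; the hardest ligand is the least reactive),
$S$ the softness, $\omega$ the Parr electrophilicity index, and
$\omega^-/\omega^+$ the Gázquez electrodonating/electroaccepting powers whose
sum is the net electrophilicity. Two conventions deserve a note, because the
literature varies:

* **Softness is $1/\eta$, not $1/(2\eta)$.** The reference descriptor table
  this package regenerates satisfies $S\eta = 1$ cell by cell (e.g.
  $1/5.6238 = 0.1778$), which fixes the convention unambiguously.
* **Nucleophilicity is a referenced scale**: $N = \varepsilon_\mathrm{HOMO} -
  \varepsilon_\mathrm{HOMO}^\mathrm{ref}$, conventionally anchored at
  tetracyanoethylene. The reference orbital energy is exposed as a parameter
  with default $-8.7924$ eV, the value implied jointly by four of the five
  rows of the shipped reference table. The fifth row (Chloramphenicol
  monoglucoronide, printed $N = 2.8369$) is inconsistent with any single
  reference energy that fits the other four (it implies $N \approx 1.4650$);
  the package flags this cell and excludes it from reproduction checks
  rather than guessing which value is right.

$I$ and $A$ come from either route the field uses: the Koopmans-in-DFT (KID)
approximation $I = -\varepsilon_\mathrm{HOMO}$, $A =
-\varepsilon_\mathrm{LUMO}$ (`vertical_ia_koopmans()`), or total-energy
differences of the three charge states, $I = E(N{-}1) - E(N)$,
$A = E(N) - E(N{+}1)$ (`vertical_ia_delta_scf()`). The KID diagnostic
(`kid_check()`) quantifies how far the two routes disagree:
$J_I = |\varepsilon_\mathrm{HOMO} + E(N{-}1) - E(N)|$,
$J_A = |\varepsilon_\mathrm{LUMO} + E(N) - E(N{+}1)|$,
$J_{HL} = \sqrt{J_I^2 + J_A^2}$, with a configurable pass tolerance
defaulting to 0.05 eV — small enough to certify a functional as
Koopmans-compliant, large enough to absorb SCF convergence noise.

```{r global}
ia <- ionization_data(I = 6.19380, A = 2.07540)   # Rutine
unlist(global_descriptors(ia, ligand_id = "Rutine")[2:9])
```

Electrophilicity classes follow the Diels–Alder-calibrated scale: strong
above 1.5 eV, moderate between 0.8 and 1.5 eV, marginal below 0.8 eV. The
scale's published inequalities are strict on both sides, leaving the two
boundary values unassigned; this package assigns each boundary to the weaker
class (1.5 eV → moderate, 0.8 eV → marginal), a conservative choice that
never upgrades a compound on a tie.

## Local reactivity

With integer electron differences ($\Delta N = 1$, matching the N, N±1
species actually computed), the nucleophilic and electrophilic Fukui
functions and the dual descriptor are voxelwise differences of densities on
a shared grid:

$$f^+(\mathbf r) = \rho_{N+1}(\mathbf r) - \rho_N(\mathbf r), \quad
f^-(\mathbf r) = \rho_N(\mathbf r) - \rho_{N-1}(\mathbf r), \quad
\Delta f = f^+ - f^- .$$

Regions with $\Delta f > 0$ are electrophilic (prone to nucleophilic
attack); $\Delta f < 0$ marks nucleophilic sites. Exact normalizations
($\int f^\pm = 1$, $\int \Delta f = 0$) are checked by plain Riemann
summation — cube grids are uniform, so higher-order quadrature buys nothing
the tolerance does not already absorb. Truncated real-world cubes
under-integrate, so a failed normalization **warns with the measured
integral instead of aborting**; the default tolerance of $10^{-2}$
electrons reflects what a well-padded production cube achieves.
Condensed-to-atom indices accept charges from any population analysis
(the condensed scheme is charge-convention agnostic): $f_k^+ = q_k(N) -
q_k(N{+}1)$, $f_k^- = q_k(N{-}1) - q_k(N)$, whose column sums are exact
consequences of total-charge bookkeeping.

## Rule-based pharmacokinetic screening

Bioactivity scores partition into three classes: active above 0, moderately
active in $[-0.50, 0]$, inactive below $-0.50$. The two boundary scores are
read as inclusive into the moderate class ("between −0.50 and 0.00" taken at
face value), making the partition total and exhaustive — a property the test
suite asserts on random inputs and both boundaries.

ADMET thresholds ship as a JSON rulebook (property, comparator, threshold,
verdict text) rather than code, because the source rules mix prose
thresholds with tool-specific conventions: Caco-2 permeability high above
0.90; intestinal absorption poor below 30%; skin permeability low for
log Kp above −2.5; blood–brain barrier readily crossed above logBB −0.3 and
brain distribution poor below logBB −1; T. pyriformis toxicity above −0.5;
boolean predictions (P-gp, CYP isoforms, AMES, hERG I/II, hepatotoxicity,
skin sensitisation) pass through as flags. CNS permeability is reported with
no verdict: no published cutoff backs one, and the engine refuses to invent
thresholds. Narrative claims that contradict their own stated rules (the
source text calls one compound's Caco-2 value of 0.737 considerable under a
>0.90 rule, and calls it the only one under 30% absorption although all
five qualify) are *not* encoded; the thresholds are.

Docking analytics are deliberately simple order statistics over the
transcribed results table: complex count, global extremes, best ligand per
protein (most negative affinity, ties broken by more hydrogen bonds, then
lexicographically), per-ligand means.

## Dose-response analysis

Percent inhibition is $(1 - A_\mathrm{sample}/A_\mathrm{control}) \times
100$. The printed form of this equation is ambiguous about operator
precedence; the implemented reading is forced by the physics — inhibition
must be 0 when the sample equals the uninhibited control and 100 at full
inhibition, which only the parenthesized form satisfies.

IC50 comes from a four-parameter logistic,
$y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + (IC_{50}/x)^h)$,
fitted by Levenberg–Marquardt least squares. The source analysis reports
IC50 values without naming its fitting method, so the method is an explicit
design choice here, recorded in the fit object's `method` field. The free
Hill slope guards against assuming ideal one-site kinetics;
initialization is bottom = min(y), top = max(y), IC50 = geometric median
dose, $h = 1$, with the slope bounded below at 0.05 to keep the model
identifiable. Non-convergence sets `converged = FALSE` with the solver
message — never a silent bad fit. The wet-lab IC50 values (22.39, 206.31,
96.43 µg/mL) appear only as generator ground truths for recovery studies:
no raw absorbances exist to re-derive them from.

The Scherrer utility $D = k\lambda/(\beta\cos\theta)$ converts X-ray peak
broadening to crystallite size (Å → nm). The source's "36 mm" crystallite
size is self-evidently a nm typo, and since the peak FWHM behind it is
unpublished, the utility is validated by hand-computed cases instead.

## What the synthetic generators emulate — and what they do not

Every pipeline stage has a generator whose outputs carry their own oracle:

* `gen_species()` builds triplets with $\varepsilon_\mathrm{HOMO} = -I$,
  $\varepsilon_\mathrm{LUMO} = -A$, $E(N{-}1) = E(N) + I$,
  $E(N{+}1) = E(N) - A$, so the Koopmans and ΔSCF routes agree exactly and
  KID deviations are exactly zero; a perturbation parameter injects a KID
  error of precisely known size. Defaults reproduce the five demo ligands'
  implied $(I, A)$ pairs, so the shipped demo regenerates the reference
  descriptor table.
* `gen_density_triplet()` sums isotropic atom-centered Gaussians, each
  normalized in closed form to its electron count, with the charged species
  redistributing exactly one electron as specified; the box must clear 5σ
  around every atom or the generator refuses, stating the required padding.
  Default study grid: 32³ voxels on a 24-bohr cube, two atoms with 6 and 4
  electrons — small enough for seconds-scale turnaround, fine enough that
  quadrature error sits near $10^{-4}$.
* `gen_admet_table()` draws numeric properties from uniform ranges that
  straddle every rulebook threshold, so both verdict branches of every rule
  occur; `gen_dose_response()` adds seeded Gaussian noise (default study
  condition: 2 percentage points, an optimistic plate-reader noise floor)
  to an exact 4PL curve.

These synthetic data are deliberately idealized: Gaussian blobs have no
density cusps, basis-set structure, or truncation artifacts; synthetic
triplets have no SCF noise; noise on dose-response curves is homoscedastic.
Passing tests therefore demonstrate that the *analysis machinery* is exact
and stable, not that real Kohn–Sham cubes or real assay plates behave this
well — with real inputs, the normalization warnings and KID diagnostics are
the instruments that surface data-quality problems.

## Numerical choices

* Hartree→eV uses the CODATA 2018 factor 27.211386245988; conversion is
  involutive to machine precision and happens only at I/O boundaries (eV is
  canonical internally).
* Cube I/O follows the de-facto standard dialect: positive atom counts ⇒
  bohr units, z-fastest value ordering, six values per line on write;
  round-trips preserve values to the 6-significant-figure format precision.
* Reproduction tolerance against the 4-decimal reference table is an
  absolute 0.005 eV — the worst-case error inherited from re-deriving
  $(I, A)$ from rounded $\chi, \eta$ inputs.
* Descriptor identities ($\omega^- - \omega^+ = \chi$, $S\eta = 1$, ...)
  are asserted at $10^{-10}$ relative, i.e. exact up to floating point.
* Problem sizes in the test suite and analysis scripts: 1000 random
  $(I, A)$ pairs for the identity suite, 16³/32³/64³ grids for refinement
  monotonicity, 100–200 seeded replicates for IC50 recovery — sizes at
  which every property is already sharply resolved.

## Known limitations

Only integer-ΔN (finite difference) Fukui functions are provided — no
fractional-occupation or spin-resolved variants; grids must share geometry
exactly (no resampling between mismatched cubes); the docking module
analyzes result tables and does not score poses; the rule engine interprets
predictions and does not predict; Gaussian log/checkpoint parsing is future
work (energies enter via the species table). Which side of the dual
descriptor's sign convention a visualizer paints is not encoded either —
the region summary reports both lobes symmetrically.
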