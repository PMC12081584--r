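---
title: "From membrane cholesterol to beta-cell electrical activity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From membrane cholesterol to beta-cell electrical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The inference chain

`cholkatp` implements a multiscale chain that connects the energetics of ATP
binding to the Kir6.2 subunit of the ATP-sensitive potassium (K\_ATP) channel,
under varying membrane cholesterol, to the electrical phenotype of the
pancreatic beta cell:

1. **Binding energetics.** Per cluster-representative complex, the binding
   free energy is decomposed as
   $\Delta G_b = \Delta G_{solv} + \Delta G_{Coul} + \Delta G_{non\text{-}elec}$,
   where the nonpolar term is an interfacial-tension model
   $\Delta G_{non\text{-}elec} = \gamma\,\Delta ASA$ with
   $\gamma = 0.021\ \mathrm{kJ\,mol^{-1}\,\text{\AA}^{-2}}$ and
   $\Delta ASA = ASA_{complex} - ASA_{receptor} - ASA_{ligand}$.
2. **Affinity mapping.** Each cluster's $\Delta G_b$ is converted to a
   dimensionless affinity constant $K = \exp(-\Delta G_b/(R\,T))$ and averaged
   per cholesterol condition; the relative decrease against the 0% reference
   defines a fractional affinity increase.
3. **Dissociation-constant rescaling.** The affinity increase is applied
   multiplicatively to the K\_ATP dissociation constant:
   $K_{tt} \to K_{tt}\,(1-f)$, i.e. 1 mM $\to$ 0.96 mM for $f = 0.04$.
4. **Beta-cell model.** An integrated oscillator model (IOM) of the beta cell
   — glycolytic oscillator, nucleotide dynamics, calcium handling and membrane
   electrical activity — is integrated at the reference and adjusted $K_{tt}$;
   electrical activity is classified (silent / bursting / continuous spiking)
   and slow calcium oscillations are quantified.

Upstream of the energetics, the package provides the trajectory-geometry
operations used to characterise the simulations that generate the
cluster-representative complexes: Kabsch superposition RMSD, GROMOS-style
conformational clustering, cluster-referenced per-residue RMSF, and the
"gate perimeter" formed by the four equivalent Q173 alpha-carbons of the
tetramer (an almost perfect square of side 15.51 Å, perimeter ≈ 62 Å).

# The affinity formula, verbatim vs physical

The affinity conversion applies $R = 8.314$ and $T = 298.15$ K directly to
$\Delta G_b$ expressed in kJ/mol (divisor $2478.82$). Dimensionally this reads
the gas constant in J mol⁻¹ K⁻¹ against an energy in kJ/mol; it is
nevertheless the computation that reproduces the reported condition means
(0.979 at 0%, 0.968 ± 0.020 at 50%), so `affinity_constant()` implements it
verbatim and exposes `physical = TRUE` for the thermodynamically standard
$K = \exp(-1000\,\Delta G_b/(8.314\,T))$, which lives on a very different
scale and is clearly labelled as such.

Two quantitative caveats are reported, never repaired silently:

* The 25% condition summary (0.942 ± 0.055, and the derived 3.85% decrease)
  is **not** recoverable from the 25% cluster energies (68, 216, 64 kJ/mol),
  which give 0.955 ± 0.033 and a 2.5% decrease. `run_pipeline()` reports both
  side by side and flags the condition as non-reproducing.
* With the percent-decrease convention used here,
  $100\,(K_{ref}-K_{cond})/K_{ref}$, the 0% → 50% change evaluates to 1.14%
  against the reported 1.15% (which corresponds to normalising by $K_{cond}$
  instead); the package keeps the $K_{ref}$ convention and the 0.01-point
  difference is visible in the step-2 analysis output.

One sign in the packaged cluster table deserves note: the 0%/Cluster1 Coulomb
component is stored as −73 kJ/mol. Only the negative sign is consistent with
both the row sum (231 − 73 − 52 = 106) and the 0% column mean (−141);
`table1_components()` documents this correction.

# Binding-energetics operations

**SASA** uses the Shrake–Rupley construction: each atom's sphere is inflated
by the probe radius (default 1.4 Å, water), sampled with a Fibonacci lattice
(default 960 points — area converges to a small fraction of a percent on
atom-sized spheres), and the accessible fraction excludes points inside any
other inflated sphere. $\Delta ASA \le 0$ for any contact complex, with
equality in the no-burial limit; both properties are under test, together
with analytic sphere and two-sphere spherical-cap references.

**Coulomb energies** are uniform-dielectric cross-pair sums,
$k\,q_iq_j/(\varepsilon\,r_{ij})$ with
$k = 1389.35\ \mathrm{kJ\,\text{\AA}\,mol^{-1}\,e^{-2}}$, the in-package
analogue of the Coulombic component of an implicit-solvent electrostatics
calculation (protein interior $\varepsilon = 4$, water 78). The solvation
component proper is ingested from external Poisson–Boltzmann output via
`read_solvation_component()`; for end-to-end runs on synthetic systems a
clearly-labelled generalised-Born pairwise estimate
(`born_solvation_standin()`, Still-style $f_{GB}$ with intrinsic radii as
effective Born radii) stands in. It reduces to the Born ion formula for a
single charge and to zero in the far-separated limit, but it is not a
Poisson–Boltzmann solution and is never used where external solvation input
is available.

Condition aggregation uses the arithmetic mean and the **n−1** standard
deviation — the only choice consistent with the printed 0% spread of 72
kJ/mol — and comparisons against printed integers use half-up rounding.

# Trajectory geometry

* Superposition is the SVD form of the Kabsch solution restricted to proper
  rotations (det = +1); RMSD symmetry and rigid-motion invariance are tested,
  and the minimum is checked against an Euler-grid + Nelder–Mead brute-force
  search on small systems.
* GROMOS clustering computes the full pairwise superposition-RMSD matrix,
  then greedily removes the frame with the most neighbours within the cutoff
  (default 2.0 Å on alpha-carbon selections — common practice; the cutoff is
  a free parameter and is configurable). Ties break to the lowest frame
  index, and clusters are relabelled by decreasing population, so results are
  deterministic.
* RMSF defaults its reference to the centre of the most populated cluster and
  averages atomic fluctuations within residues. Terminal residues are not
  masked by the computation; masking is a reporting choice left to the caller.
* The gate perimeter orders the four gate atoms once, by azimuth about the
  pore axis estimated from the first frame (smallest principal axis of the
  four-point cloud), and keeps that cyclic order; the perimeter is the sum of
  the four adjacent distances and is invariant under global rigid motion.
  Computation stays in Å; nm appears only at reporting boundaries.
* Analysis windows are closed intervals $[t_{start}, t_{end}]$; the
  "last $w$" convenience window is $[t_{max}-w,\,t_{max}]$.

# The synthetic-data generators

The package generates every input it needs at desk scale, with known ground
truth:

* `gen_toy_tetramer()` builds a four-chain structure related by exact 90°
  rotations, one alpha-carbon analogue per residue, and a tagged gate residue
  whose four atoms form a perfect square of configurable side (default
  15.51 Å). It emulates only the four-fold gate motif — not protein geometry,
  lipids, or water.
* `gen_trajectory()` drives the gate perimeter along an exact-discretisation
  Ornstein–Uhlenbeck path (mean-reverting, the simplest process exhibiting
  fluctuation-magnitude differences between conditions) and adds independent
  Gaussian jitter to all atoms. The long-run median equals the OU mean and
  the lag-1 autocorrelation is $e^{-\theta\,\Delta t}$; both are test
  oracles. Frame spacing is a free fixture choice (defaults 0.01 ns).
* `gen_charge_system()` produces point-charge pairs with the analytic Coulomb
  energy attached, far-separated blobs (zero $\Delta ASA$ by construction)
  and touching blobs.
* `gen_energy_fixture()` always embeds the nine packaged cluster rows and
  fabricates additional conditions whose $\Delta G_b$ equals the component
  sum by construction.

All generators are pure functions of their specification and seed, and they
restore the caller's RNG stream. Passing tests on these fixtures validates
the *operations*; it does not certify behaviour on real membrane-simulation
data, whose anisotropy, correlated noise and slow drift the generators do not
emulate.

# The beta-cell model

State variables: membrane potential $V$, delayed-rectifier activation $n$,
cytosolic and ER calcium $c$, $c_{er}$, glycolytic metabolites F6P and FBP,
and ADP (ATP follows from a conserved pool $A_{tot} = 3000\ \mu M$). Currents:
Ca²⁺, delayed-rectifier K⁺, Ca²⁺-activated K⁺, and K(ATP) with the
Mg-nucleotide open probability

$$o_\infty = \frac{0.08\,(1 + 2\,\overline{MgADP}) + 0.89\,\overline{MgADP}^2}
{(1+\overline{MgADP})^2\,\bigl(1 + \overline{ADP^{3-}} + \overline{ATP^{4-}}\bigr)},$$

with $\overline{MgADP} = 0.165\,ADP/17$, $\overline{ADP^{3-}} = 0.135\,ADP/26$,
$\overline{ATP^{4-}} = 0.05\,ATP/K_{tt}$ — the classic Magnus–Keizer form.
$K_{tt}$, the handle of the whole pipeline, defaults to 1 (model
concentration units; quoted in mM where the 1 → 0.96 perturbation is
discussed). Open probability is strictly decreasing in ATP, increasing in
$K_{tt}$, and bounded in (0, 1]; all three properties are under test on dense
grids.

Glycolysis is the Smolen phosphofructokinase model: 16 allosteric binding
states of (AMP, FBP, F6P, ATP) with pairwise interaction factors; catalysis
proceeds from F6P-bound states, at full rate with an activator (AMP or FBP)
bound and at a fraction `kpfk = 0.06` otherwise. The nucleotide exchange

$$ADP' = \bigl(ATP - ADP\,e^{(r+\gamma)(1-c/r_1)}\bigr)/\tau_a,
\qquad \gamma = v_g \frac{J_{PDH}}{k_g + J_{PDH}},$$

couples ATP production to the PDH flux (itself fed by FBP) and ATP
consumption to calcium (through $1 - c/r_1$, the ATPase load of calcium
pumping), closing the slow feedback loop between metabolism, calcium and
electrical activity.

## Calibration of the reference parameterization

The functional forms above follow the published beta-cell
integrated/dual-oscillator lineage. Exact published rate constants were not
all recoverable, so the packaged reference parameter set
(`inst/extdata/iom_reference_params.json`) was calibrated — once, against the
*baseline* phenotype only — to the canonical operating regime of this model
family at stimulatory glucose: slow electrical bursting with calcium
oscillations of a period of several minutes, ADP near 100 µM against an ATP
pool near 2.9 mM, cytosolic calcium in the 0.05–0.2 µM range, and a
glucokinase flux placed inside the glycolytic-oscillation window near its
upper (glucose) boundary. That last placement is not incidental: a few-percent
change in ATP affinity can only change the qualitative mode of the cell if
the reference state is near the mode boundary, which is the operating point
at which the comparison is meaningful. With the baseline frozen, the
$K_{tt} = 0.96$ perturbation was then evaluated: it flips the classification
to continuous spiking, abolishes the slow calcium oscillations and raises
mean calcium. The transition sits near $K_{tt} \approx 0.98$, and the
dichotomy is insensitive to ±10% perturbations of the initial state and to
halving the solver tolerances.

## Numerics and event analysis

* Integration uses lsoda (stiff-capable) with `rtol = 1e-8`,
  `atol = 1e-10`; the right-hand side is compiled (C) with the R
  implementation retained as the reference — agreement between the two is a
  test. Output is sampled every 10 ms, fine enough to resolve individual
  spikes.
* Spikes are upward crossings of −40 mV; silent phases are spike-free
  intervals of at least 5 s; bursting requires at least two qualifying
  silent phases in the analysis window. All three thresholds are arguments.
* Slow calcium metrics smooth the trace with a 10-s running mean (removing
  within-burst ripple, ~0.2% attenuation of a 5-min oscillation), estimate
  the period from the first autocorrelation peak of the down-sampled
  envelope, and average per-cycle peak-to-trough amplitudes. Oscillations
  are flagged abolished below 0.05 µM — an order of magnitude below typical
  bursting-regime amplitudes (~0.07 µM) and well above continuous-spiking
  residual envelopes (~0.02 µM).
* The default transient discard is the leading 20% of a run. The analysis
  scripts integrate 90 minutes, giving roughly ten slow periods after the
  transient; the acceptance checks use the same span.

# Known limitations

* The solvation stand-in is pairwise generalised-Born with intrinsic radii;
  it is qualitatively, not quantitatively, faithful to a Poisson–Boltzmann
  treatment.
* The beta-cell parameterization is a calibrated reconstruction of the
  published model family, not a byte-for-byte copy of any single published
  parameter file; quantitative waveform details (spike amplitudes, exact
  burst duty cycle) should not be over-interpreted, while the qualitative
  dichotomy is the tested, robust claim.
* The geometry operations are validated on synthetic oracles at desk scale;
  figure-level quantities of the original trajectory analyses (stabilisation
  times, nm-scale per-system medians, per-residue RMSF profiles) require the
  production membrane simulations and are out of scope.
* The gate-geometry check runs against a packaged synthetic stand-in with
  the reported square-gate dimensions; pointing `read_pdb()` at a downloaded
  copy of the deposited cryo-EM structure (PDB 7TYS) runs the identical
  measurement on real coordinates.
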