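---
title: "Master-equation modeling of branched actin networks and endocytic force generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master-equation modeling of branched actin networks and endocytic force generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actinME)
```

## The model

Dendritic (Arp2/3-branched) actin networks generate force at membranes: new
filaments nucleate as branches off existing ones, at a fixed oblique angle,
wherever a nucleation-promoting factor (NPF) is present on the membrane.
`actinME` evolves the *expected* spatial distribution of F-actin subunits,
`rho`, deterministically — a master equation (ME) in which branching is a
directional spreading term — rather than simulating individual filaments.
One deterministic run replaces an ensemble of stochastic simulations, which
makes parameter fitting and bifurcation-style scans affordable.

All geometry lives on a lattice of spacing a/2 = 1.35 nm, half the 2.7 nm
step added per polymerized subunit; filaments run at +/-45 degrees to the
membrane normal, so one subunit advances a branch one lattice row
vertically and one laterally.  A branch nucleated from a mother subunit
polymerizes "instantly" to its final length (capping, at about 1/s, is fast
compared with the seconds-scale processes modeled), depositing one subunit
per lattice row between the mother and its tip.  The per-row deposition is
cut off near the membrane by a Boltzmann factor in the local linear
repulsion (the same repulsion that generates the pushing force), which
is what confines the
network to the cytoplasmic side without imposing a hard wall on `rho`.

Three processes drive `d rho/dt`:

* **branching** — at rate `kbr(r, y) * N(t)` per mother subunit, where
  `kbr` is a Gaussian layer of width `sigma_br` riding on the membrane,
  restricted to the NPF (Las17) ring `rL_in < r < rL_out`, and `N(t)` is
  the NPF count.  The deposition from a mother at `(r, y + y')` is spread
  uniformly over the azimuthal circle of branch-end radii
  `R = sqrt(y'^2 + r^2 - 2 r y' cos(theta))` (64-point uniform quadrature
  with linear radial interpolation of number density);
* **spontaneous nucleation** — `knuc(r, y, t)`, a Gaussian layer of width
  `sigma_nuc` over a central spot `r < r_nuc`, riding on the invagination
  tip; it stands for NPF-independent nucleation (severed fragments, Dip1)
  and builds the passive, membrane-attached filaments that transmit the
  pulling force;
* **severing** — first-order decay at `ksev`, the lumped cofilin-driven
  turnover rate.

A deliberate modeling choice concerns where the branching rate is
evaluated.  Evaluating it at the *deposited daughter* site would delete,
every generation, all branch mass extending past the NPF footprint; the
network would be subcritical at the fitted rates and, contrary to
expectation, could never spread beyond the ring.  `actinME` therefore
evaluates `kbr` at the *mother* subunit: branches born in the NPF region
carry their full deposition wherever their 45-degree geometry takes it.
The F-actin distribution then extends up to one filament length outside
the ring, as a finite-branch network must.

## Validation against an explicit-filament simulator

The deterministic ME is checked against a stochastic simulator that holds
every filament explicitly on the same lattice, with branch events drawn by
fixed-increment tau-leaping from the same rates and geometry
(`run_stochastic_obstacle()`, `run_ensemble()`).  The test problem is a
branched network growing against a flat rigid obstacle that opposes
polymerization with a constant force: the obstacle carries an NPF strip,
and at every step it is repositioned so that the linear repulsion from
actin penetrating past it balances the external force.  Runs start from
400 filaments of 50 subunits (20,000 subunits).

Two nontrivial behaviors emerge and agree between the two methods: the
steady F-actin count grows *linearly* with the applied force, while the
obstacle velocity is *independent* of it.  The network self-organizes: a
larger load recruits a proportionally denser contact layer, leaving the
load per contact subunit — and hence the ratchet-limited intercalation
rate — unchanged.  The acceptance suite asserts the linearity (R^2), the
velocity constancy, and that the ME count trace lies inside the stochastic
95% ensemble band.

The instantaneous-polymerization assumption can be probed with the
simulator's `mode = "explicit"` option, in which branches elongate subunit
by subunit at `k_on * G` and cap at `k_cap`.

## The endocytosis model

Clathrin-mediated endocytosis in budding yeast must invaginate the plasma
membrane against roughly 0.2 MPa of turgor pressure.  The model couples
four components, advanced together with an explicit first-order step
(default `dt` = 0.01 s):

1. **NPF (Las17) feedback.**
   `dN/dt = (k_0 / 2) N (N_full - N) - alpha N F_br`, with `F_br` the
   branch flux per Las17 (`branch_flux()`).  Branching carries a per-event
   probability `alpha` of knocking the Las17 molecule off the membrane —
   the negative feedback that shapes the transient patch.
2. **Membrane shape family.** Solving the axisymmetric Helfrich problem
   under turgor is out of scope; the model consumes a pretabulated family
   of 80 equilibrium profiles at depths 0.1–8.0 `R_Pi` with the pulling
   force `f_in(y_I)` attached (`stand_in_family()`, or
   `load_shape_family()` for an externally computed table).  The built-in
   generator produces Gaussian domes that become Omega (neck-under-bulb)
   profiles beyond `d_omega`, and a continuous force curve rising steeply
   from zero to its single maximum `f_max = 725` pN at `d_fmax`, then
   decreasing (snap-through-like) on the Omega branch.  The steep initial
   rise reflects the turgor cost of even shallow deformations; a
   shallow-rise curve would make lift-off impossible, because at low
   per-filament load the inner filaments out-ratchet the outer ones.
3. **Force balance.** The pushing force is generated where ring-network
   density leaks past the membrane: `f_out = k_rep * sum(count * depth)`
   over the forbidden zone (only ring radii push; the spot filaments are
   the pulling attachment).  Each step the membrane plane is repositioned
   so `f_out` balances `f_in` at the current depth; before the clutch
   engages turgor pins it flat, and a small nominal contact force
   (`f_pin` = 1 pN) regularizes the zero-force contact at the moment of
   engagement.
4. **Molecular clutch.** Below `F_min` subunits of F-actin there is
   nothing at the patch center for the outer network to grip, and the
   depth `y_I` is held at zero.  Above it the network is treated as rigid
   and `dy_I/dt = v_out - v_in`: `v_out` is the measured force-balance
   recession of the membrane plane (the deposition-limited rate at which
   the network intercalates new subunits at the contact — the same
   emergent velocity the obstacle validation measures), and `v_in` is the
   Brownian-ratchet speed of the sparse inner filaments under their
   per-filament share of the pulling load,
   `v_in = (a/2) k_on G exp(-f_fil * (a/2) / kT)`.  This asymmetric
   closure is deliberate: the bare ratchet speed applied to the outer
   network (load shared over hundreds of lattice tips, hence under 1 pN
   per tip) would drive the invagination to the edge of the shape table
   within a second, an order of magnitude faster than the network can
   actually build material — inconsistent with the model's own validated
   force-generation mechanism.  Keeping the ratchet form for `v_in` is
   what bounds the admissible nucleation rate from above: halving the
   per-filament load (for example by doubling `knuc`) makes the inner
   filaments push the tip back out and stunts the invagination.
5. **Shape selection.** Given the updated `y_I`, the nearest tabulated
   profile is selected and `f_in` linearly interpolated between the
   bracketing depths; the branching layer is rebuilt on the ring height
   and the nucleation layer on the tip.

The run starts from the measured initial condition: a ring of filaments
one subunit per cell at the ring inner radius over one zero-force filament
length, 20 Las17 molecules, a flat membrane and vanishing forces.

## Parameters

Core kinetic values (the wild-type fitted set): `kbr_max` = 2.59e-3 /s,
`knuc_max` = 15e-3 /s (both scaled per lattice site), `ksev` = 0.36 /s,
`k_0` = 7.24e-5 /s, `alpha` = 0.082, zero-force branch length
`lbar_max` = 60 subunits (= `k_on G / k_cap` with `k_on` = 11.6 /uM/s,
`G` = 5.3 uM, `k_cap` = 1 /s).

The geometric and mechanical entries are modeling choices of this package
(tagged "non-paper" in the provenance table) and were set once, by the
constraints the model itself is built around, before being frozen:

* `rL_in`/`rL_out` = 32/64 nm — Las17 ring radii (superresolution scale);
* `sigma_br` = 30 nm, `y_br` = 90 nm — branching-layer width and cutoff.
  The width is the smallest that makes the branched network robustly
  supercritical at the fitted rates while Las17 is still at patch-typical
  counts; a much wider layer quenches the patch (branch flux outruns
  recruitment too early);
* `sigma_nuc` = 10 nm, `y_nuc` = 20 nm, `r_nuc` — nucleation layer; the
  spot radius is set so that the default model hands ~30 pN to each
  pulling filament at the 725 pN force maximum (the published calibration
  constraint for the nucleation rate), counting
  `F(r < rL_in) / (2 y_nuc / a)` pulling filaments;
* `N_full` — Las17 packing capacity of the ring.  At the printed
  recruitment constant `k_0`, the observed ~20 s rise of Las17 requires
  the capacity term to be in the low thousands ((k_0/2) N_full sets the
  early exponential rate); a capacity of low hundreds would freeze Las17
  at its initial count for the whole patch.  Dense 2-d packing of the
  ring annulus at a few nm^2 per molecule gives the same order.
* `k_rep` — the linear actin–membrane repulsion.  It controls both the
  softness of the contact (penetration reach `kT ln(lbar_max) / (k_rep *
  a/2)`) and, through the force balance, the deposition-limited recession
  speed, i.e. how fast the invagination deepens while the patch is
  productive.  It is calibrated against the default-model invagination
  depth; stiff values (reach under one lattice row) deadlock the discrete
  deposition front entirely.
* `F_min` = 1000 subunits — clutch threshold; `R_Pi` = 10 nm, `d_fmax`,
  `d_omega` — shape-family scales.

## Numerical choices

Explicit first-order stepping with `ksev * dt` and the per-step branching
gain well below 0.05; `dt` = 0.01 s by default, 0.02–0.05 s in the test
suite.  The azimuthal quadrature uses 64 uniform angles (tests show 64 vs
128 changes the total source by well under 0.1%); the on-axis cell is
treated as a disk of radius half a spacing.  The lattice extends
dynamically below the receding membrane.  The force balance is solved by
bisection on the membrane offset (piecewise-linear monotone overlap
force); shape changes re-tabulate the per-column membrane crossings, which
represent Omega overhangs exactly via an even-odd rule.  Branch lengths
are floored to integer subunit counts; checkerboard parity (the 2D stencil
maps each x+y sublattice to itself) is preserved and tested.

## Fitting

The four kinetic parameters (`k_0`, `kbr_max`, `ksev`, `alpha`) are fitted
by minimizing the normalized mean-square difference between model and
target Las17/F-actin time courses (`fit_loss()`), with a random
accept-if-lower search (`random_search_fit()`): joint log-normal
perturbations of all four parameters, a proposal accepted only when it
strictly lowers the loss, stopping after a configurable number of
consecutive rejections (about 300 attempts in total is typical).  Two
properties of the problem matter in practice.  First, branching and
severing partially compensate (both scale the net growth rate), so the
loss surface has a diagonal ridge; joint proposals ride it, while
one-parameter-at-a-time moves stall (we tested both).  The proposal scale
shrinks in two refinement phases over the evaluation budget (full scale,
then one half, then one quarter), which lets the walk first traverse the
ridge and then localize the minimum; several hundred evaluations are
needed, matching the published ~300-attempt protocol.  Second, the
severing rate is identified by the post-peak decay
of the F-actin curve, so the target window must extend several seconds
past the patch maximum; targets truncated at the peak leave `ksev`
pinned only through the ridge and recovery to 15% becomes unattainable.

## What the synthetic data do and do not show

The fitting module recovers parameters from synthetic time courses
generated by the forward model plus multiplicative noise
(`synthesize_targets()`).  This validates the loss surface and the
accept-if-lower search — it does not validate the model against biology;
fluorescence-calibrated counts carry correlated errors, uneven sampling
and patch-to-patch variability that the synthetic generator does not
emulate.  Likewise the stand-in membrane family has the right topology
(dome-to-Omega transition, single force maximum) but is not a Helfrich
solution; profile-sensitive quantities (exact forbidden-zone shape near
the neck) inherit that approximation.

## Problem sizes and observation window

Default runs use a 110-cell radial lattice (149 nm), 64 quadrature angles
and `dt` = 0.01 s over 30 s of model time.  All reported maxima (`F_max`,
`N_max`, `y_I_max`) are taken over this 30 s window — the wild-type patch
lifetime; under strong perturbations the delayed patch runs out of the
window and its maxima collapse, which is what produces the sharp decline
at deep branching inhibition.  The test and acceptance suites run the
same code at `dt` = 0.03–0.035 s with 32 angles (full-model runs and
scans), 25-run ensembles at 60 s for the obstacle protocol, and the
fitting recovery on a deliberately coarse forward model (`dt` = 0.12 s,
70 radial cells, 8 angles, 28 s horizon) whose targets are generated by
the same solver, so the recovery experiment is self-consistent.  These
sizes keep every reported number reproducible on a single CPU in minutes
while remaining inside the regime where the numerics are converged (the
dt-convergence and quadrature-convergence tests bound the residual
discretization error: moving `dt` from 0.01 to 0.03 shifts the default
invagination depth by about 4%).

## Known limitations

* Filaments are rigid and the network above `F_min` is perfectly rigid;
  no elastic relaxation, no semiflexibility.
* Only +/-45-degree branches; no azimuthal density structure (the 3D
  model is azimuthally symmetric by construction).
* Scission, coat-protein dynamics and myosin activity are absent; the
  patch simply disassembles once severing outruns branching.
* The Las17 equation treats recruitment logistically with a single
  capacity parameter; spatial NPF organization within the ring is not
  modeled.
* The clutch is a sharp threshold; a graded engagement would smooth the
  lift-off transient.
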