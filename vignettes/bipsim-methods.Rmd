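---
title: "bipsim: model, observables and protocols"
author: "bipsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bipsim: model, observables and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical model

`bipsim` simulates a solution of multi-domain chromatin-binding proteins
together with a chromatin fibre, at the coarse-grained resolution where one
polymer bead of diameter $\sigma$ represents roughly 1 kbp of chromatin
(about 10 nm).  All computation is in reduced units: $\sigma$ for length,
$k_BT$ for energy, $\tau$ for time, bead and dimer mass 1.

**Chromatin** is a bead-spring fibre: WCA excluded volume between all beads,
FENE springs between consecutive beads ($K_f = 30\,k_BT/\sigma^2$,
$R_0 = 1.6\sigma$, the standard Kremer-Grest choice) and a Kratky-Porod
bending energy $U = K_b(1-\cos\theta)$ on consecutive bond angles.  The
default $K_b = 3.7\,k_BT$ is chosen so that the worm-like-chain radius of
gyration of a 1000-bead fibre, $R_g = \sqrt{l_p L_c/3}$, is comparable to
the default confinement box of 35$\sigma$.  For a discrete chain the
realised tangent decorrelation length is $-1/\ln\langle\cos\theta\rangle
\approx 3.2\sigma$ at this $K_b$, slightly below the continuum value.

**Proteins** are rigid dimers of seven spheres (diameter $0.5\sigma$): one
sphere for the dimerised chromoshadow domain (CSD), and one per protomer
for the chromodomain (CD), hinge and N-terminal extension (NTE).  The
reference geometry (`dimer_geometry()`) is mirror-symmetric about the CSD,
has maximal extent $\approx 1.43\sigma$, puts both CDs on one exterior face
— so both can contact a single polymer bead, which makes the coating
binding mode geometrically cheap — and hinges/NTEs on the opposite face.
Exact sphere placement is a modelling choice; the geometry is fully
configurable (a `role x y z` table), and the integrator works in the
principal frame computed at construction.

**Interactions.**  All sphere pairs of distinct bodies repel via WCA
(contact distance = sum of radii).  Two attraction classes use a truncated,
shifted Morse-like well
$U(r) = \varepsilon[(1-e^{-a(r-r_0)})^2 - 1] - U_{\mathrm{shift}}$:

| class | pairs | $a$ | $r_0$ | $r_c$ |
|---|---|---|---|---|
| HC | CD sphere – polymer bead | 4 | 0.75 | 1.1 |
| HH multivalent | hinge – NTE (any) | 4 | 0.5 | 1.0 |
| HH limited valence | hinge – NTE (bonded only) | 10 | 0.5 | 0.65 |

Because of the cutoff shift the quoted $\varepsilon$ is not the realised
well depth (the depth is $\varepsilon(1+U_{\mathrm{shift}}/\varepsilon)$,
about $0.75\varepsilon$ for the multivalent class); quoted energies of the
two variants must not be compared directly.  The energy is continuous at
the cutoff; the radial force retains a small discontinuity there, which a
Langevin thermostat absorbs without measurable artefacts at
$\Delta t = 10^{-3}\tau$.

In the **limited-valence** variant the attraction acts only on explicitly
bookkept exclusive bonds: each hinge and each NTE holds at most one bond,
so a dimer binds at most four partners.  Bonds form when a free hinge-NTE
pair approaches within $r_{\mathrm{on}} = 0.55\sigma$ (nearest candidates
first, deterministic tie-break) and break beyond
$r_{\mathrm{off}} = 0.62\sigma$; the hysteresis gap prevents force
chattering.  A short cutoff alone cannot enforce exclusivity (two spheres
can both touch a third at 60 degrees), which is why the bond table is
explicit.

**Confinement.**  Production runs confine everything in a cubic box
(default $l_x = 35\sigma$) with WCA-form walls acting on sphere centres
with contact parameter equal to the sphere radius.  Periodic boundaries are
available for calibration tests.

# Dynamics

A BBK-style Langevin velocity-Verlet integrator advances beads and rigid
dimers at $\Delta t = 10^{-3}\tau$.  Dimers carry a unit quaternion and a
lab-frame angular momentum; orientations advance by an exponential-map
rotation with the mid-step angular velocity and are renormalised each step.
Friction is $\gamma = 1$ per unit mass for translation; the rotational
friction tensor follows from distributing the same per-mass friction over
the constituent spheres, which for equal sphere masses makes the friction
torque exactly $-(\gamma/m)\,\mathbf{L}$.  Thermal noise obeys the
fluctuation-dissipation relation per degree of freedom (body-frame
rotational components with variance $2\gamma I_k k_BT/\Delta t$); the
sampler is a 128-layer ziggurat over a seeded xoshiro256++ stream, one
named stream per run, draws in fixed particle order, so every run is
bit-reproducible and a checkpointed run continues its trajectory exactly.
With $\gamma = 0$ the integrator is deterministic NVE, used by the
energy-conservation and reversibility tests.

Pair interactions use a cell-list/Verlet list (skin $0.3\sigma$, rebuild
when any site moves more than half the skin).  Pair lists are emitted in a
canonical (i ascending, j ascending) order; since pairs beyond cutoff
contribute exactly zero force, the accumulated forces are bitwise
independent of when the list was rebuilt — this is what makes the
`skin = 0` equivalence and exact-restart contracts hold to the last bit.
The production kernel evaluates the attraction classes from 4096-bin
tables on $r^2$ (linear interpolation, relative error $\sim 10^{-6}$);
single-shot force evaluation (`total_forces()`) and every oracle
comparison use the exact analytic forms.

# Observables

**Separation depth.**  The box is tiled into $N_{sb}$ sub-boxes (125 for
the production composition; rescaled to keep the mean occupancy of ~8
dimers per sub-box when the system is scaled) and each dimer is counted
once by its CSD-sphere centre.  Each sub-box contributes its density
deviation from the overall mean, normalised by the deviation expected for
strong phase separation, with reference densities $\rho_+ = 0.5$ (dense)
and $\rho_- = 0$ (dilute).  Three conventions are implemented:

* `split` (default): $|\rho_i - \rho|$ normalised by $(\rho_+-\rho)$ for
  sub-boxes above the mean and by $(\rho - \rho_-)$ below.  For an ideal
  uniform mixture at the production composition this gives a baseline of
  0.148 (the package's Monte-Carlo oracle reproduces this), and it tends
  to 1 on strong separation — the two limits a useful order parameter
  needs.
* `folded`: magnitude terms with the reference chosen by the
  $\rho_i > \rho_+/2$ rule.  Its uniform-phase baseline is
  $\sqrt{2/(\pi\cdot 8)} \approx 0.28$, and sub-boxes that are dense yet
  below $\rho_+/2$ produce terms larger than 1.
* `signed`: the signed terms with the same rule; identically $\approx 0$
  in a uniform phase.  Retained for audit.

All three are reported by the protocol layer (`phi_sep`,
`phi_sep_folded`, `phi_sep_signed`).

**Binding modes.**  A CD is bound when its centre is within the HC cutoff
of a bead centre; its bound bead is the nearest such bead (the only
parameter-free choice).  Dimers are `unbound`, `dangling` (one CD),
`coating` ($|i-j| < 2$) or `bridging` ($|i-j| \ge 2$), with the bound
fraction $f_{tot}$ and the coverage $f_c$ (fraction of beads contacted by
at least one CD).

**Bond decorrelation.**  The indicator $y_{ij}(t)$ marks interacting
protein pairs per sampled frame (attraction-range contact for the
multivalent variant, active bond for limited valence).
`bond_correlation()` returns the normalised autocovariance pooled over
time, pairs and repeats; with global-mean centring a frozen bond pattern
stays at 1 and an all-constant process is reported as degenerate.  A
per-pair-centred variant (equal to the variance-weighted mean of per-pair
autocorrelations — an algebraic identity the tests verify) is available.
`fit_decorrelation_time()` fits a stretched exponential
$\exp[-(\Delta t/\tau_{HH})^\beta]$, $\beta \in (0,2]$, and flags fits
with relative standard error above 50% as unreliable.
`residence_time()` is the censored mean run length of contiguous contact.

**Clusters and droplets.**  Two dimers are linked when any inter-dimer
sphere pair is within its attraction cutoff or within 1.05 steric contact;
clusters are connected components.  The largest cluster is the droplet,
with $R_d = \sqrt{5/3}\,R_{g,\mathrm{cluster}}$ (the uniform ball with the
same radius of gyration), $\rho_{HD}$ the dimer density inside the $R_d$
sphere about the cluster centroid and $\rho_{LD}$ the density of the rest
of the box.  On synthetic constant-density balls $R_d(N)$ scales as
$N^{1/3}$ to within 1%.  `fractal_dimension()` is the least-squares
mass-radius slope over $r \in [1\sigma, R_g]$ (3 for compact droplets,
below 3 for gels; clusters under 30 dimers are refused).
`mixing_index()` labels the two droplet halves through the centroid and
reports $1 - |n_A - n_B|/(n_A + n_B)$ averaged over the two half-volumes.

# Protocols

`equilibrate_and_measure()` runs independent seeded replicates, discards an
equilibration window (default the first half), and guards stationarity
with a Mann-Kendall trend test at the 5% level on the separation depth and
$R_g$; non-stationary points are flagged but still reported.
`phase_scan()` classifies regimes: droplet at $\phi_{sep} \ge 0.5$;
absorbing droplet additionally at $f_{tot} \ge 0.5$; coating when a
non-droplet point exceeds its weak-interaction baseline by more than three
standard errors; a droplet whose small-$\varepsilon_{HC}$ counterpart is
not a droplet is a bridging-induced (BIPS) droplet.  Crossovers are
located by linear interpolation between grid points.
`density_scan()`, `hysteresis_ramp()` (piecewise-linear energy ramp during
integration, hysteresis area $\int(f_{up}-f_{down})\,d\varepsilon_{HC}$)
and `quench_protocol()` (interactions switched on instantaneously from a
non-interacting equilibrium start; relax, then measure) complete the
experiment set.

**Separated-configuration starts.**  Deep inside a two-phase region,
coarsening from a gas is diffusion-limited: at desk scale a quench at
$\varepsilon_{HH} = 8$ still has ~10 clusters after $10^3\tau$.
`condensed_start()` therefore pre-assembles the proteins in a ball at a
density near the expected dense phase (0.4 dimers/$\sigma^3$) and relaxes;
if the droplet phase is not stable at the chosen energies the ball simply
evaporates (at $\varepsilon_{HH} = 2\,k_BT$ it disperses within tens of
$\tau$), so the construction is two-sided.  Gas-start coarsening (the
separation depth rising from its mixed baseline) is asserted separately in
the test suite.

**Scaled compositions.**  `scale_composition()` scales $N$, $L$ and the box
volume by the same factor, preserving both number densities to better than
1%, and the sub-box count follows `sub_box_side()` so the mean occupancy
stays fixed.  The problem sizes used by the shipped tests and the
acceptance script are package choices made for single-CPU turnaround: the
mixed-phase point runs the full composition ($N = L = 1000$,
$l_x = 35\sigma$) with 4 seeds over 60$\tau$ windows (the sub-box
statistic is stationary after a few $\tau$); the dense-droplet point runs
the quarter-scale composition ($N = L = 250$, $l_x \approx 22\sigma$) from
condensed starts over 250$\tau$; scans and directional checks use factors
0.08–0.15 of the production composition.  Production-scale defaults
(5×10^3 τ, ≥4 seeds) remain the package defaults in `scan_spec()`.

# What the synthetic fixtures do and do not show

`generate_fixture()` builds uniform gases, constant-density balls, pairs of
balls, straight and ring chains, perfectly coated polymers and exact
two-state Markov (telegraph) bond series.  These give every observable a
construction oracle — known $R_d$, known mode fractions, known
autocovariance $e^{-(k_{on}+k_{off})\Delta t}$, known mean residence time —
without running any physics.  Passing those tests validates the
*estimators*; it says nothing about the force field.  The dynamical tests
(equipartition, Einstein relation, persistence length, coarsening
direction) validate the *dynamics* against closed-form physics; the
phase-behaviour tests then probe the *model*, and are the only place where
finite size and finite run length genuinely limit what can be concluded.

# Numerical choices and degenerate inputs

* $\Delta t = 10^{-3}\tau$; the FENE term aborts the run with an explicit
  "bond overstretched" error if a bond reaches $R_0$ (the symptom of a too
  large timestep), and non-finite coordinates are reported with the
  offending site.
* Limited-valence candidate bonds are admitted in ascending distance with
  an (id, id) tie-break, so bond resolution is deterministic.
* Zero-variance bond series, absent droplets, clusters below 30 dimers and
  non-decaying correlation curves raise explicit errors rather than
  returning numbers.
* The separation depth of a raw count vector requires the sub-box volume
  and mean density explicitly; nothing is inferred.
* Initial placement is rejection-sampled with bounded retries and fails
  with "packing infeasible" rather than degrading.

# Known limitations

* The radial force is discontinuous (by $O(\varepsilon)$) at the
  attraction cutoffs; acceptable under a thermostat, not for
  microcanonical production.
* The condensation threshold of the multivalent variant depends strongly
  on the attraction range.  With the default $a = 4/\sigma$,
  $r_c = 1.0\sigma$ several hinge-NTE links form per dimer pair and the
  droplet phase already appears near
  $\varepsilon_{HH} \approx 2.5$–$3\,k_BT$ (a pre-assembled droplet
  evaporates at 2 but persists at 3).  Mapping a particular experimental
  or literature threshold therefore requires calibrating $a$ and $r_c$,
  not only $\varepsilon$.
* At scaled sizes, long-lived satellite clusters depress the separation
  depth of the dense-droplet phase (each satellite occupies an
  otherwise-empty sub-box); values of ~0.75–0.85 rather than ~1 should be
  expected until coarsening completes.
* Hydrodynamic interactions, electrostatics and sequence heterogeneity of
  the fibre are out of scope; all beads are equivalent binding sites.
* The time unit is not calibrated to physical seconds; dynamical
  quantities ($\tau_{HH}$, residence times) are comparable between
  parameter sets, not absolutely.
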