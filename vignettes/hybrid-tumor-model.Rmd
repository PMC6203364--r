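---
title: "A hybrid cellular-automaton model of invasive tumor growth under chemotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid cellular-automaton model of invasive tumor growth under chemotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`tumorca` simulates the growth of an avascular, invasive solid tumor under
chemotherapy by coupling three scales:

1. **Pharmacokinetics (organ scale).** A two-compartment PBPK system tracks
   the mean drug concentration in a vascularized pool `C1` (plasma-fed
   tissue) and an avascular pool `C2`:
   \[
   \frac{dC_1}{dt} = k_{21}\frac{V_2}{V_1} C_2 - (k_{12}+k_{10}) C_1 +
   \frac{S(t)}{V_1}, \qquad
   \frac{dC_2}{dt} = k_{12}\frac{V_1}{V_2} C_1 - k_{21} C_2 .
   \]
   After a bolus, `C1` decays much faster than `C2`. The PBPK module does not
   feed the tissue solver at runtime; it motivates the *shape* of the
   boundary condition below — a fast decay time for vascularized
   micro-environments and a slow one for avascular micro-environments.

2. **Drug transport (tissue scale).** The concentration \(\phi\) on a
   regular \(N^3\) grid obeys a diffusion–reaction equation
   \[
   \partial_t \phi = \nabla\!\cdot\!\big(D(\mathbf r,t)\nabla\phi\big)
   - K_{met}\,\phi - \lambda_{14}\, n\,\frac{\phi}{\phi + \phi_0},
   \]
   with first-order chemical decomposition \(K_{met}\) and Michaelis–Menten
   cellular uptake proportional to the local dimensionless tumor-cell
   occupancy \(n \in [0,1]\). Drug enters through a spherical Dirichlet
   shell whose value follows the dosing schedule: constant, or the
   infusion–decay logistic
   \(C(t) = C_0 / (1 + \exp[(t \bmod \tau_{cycle} - \tau_{decay}) /
   (\tau_{decay}/10)])\), optionally restricted to a spatial region of the
   shell (localized vasculature). Heterogeneous diffusivity follows a
   gas-diffusion relation: \(D = \eta D_0\) in voxels holding tumor cells
   and \(D = D_0\,\rho_{0,ECM} / (\rho_{ECM} + \rho_{res})\) in matrix, so
   degraded matrix is the most permeable.

3. **Cell dynamics (cell scale).** A cellular automaton on the Voronoi
   tessellation of a random hard-sphere packing. Sites are matrix patches
   (with density \(\rho_{ECM}\)) or tumor cells — proliferative, quiescent,
   necrotic, or invasive. Daily rules: quiescent cells deeper than
   \(\delta_n = a L_t^{2/3}\) below the surface turn necrotic; proliferative
   cells divide into an adjacent matrix site with probability
   \(P_{div} = p_0 \, P_{\gamma,\phi} \,(1 - r/L_{max})\,(1-\rho_{ECM})^2\);
   proliferative cells deeper than \(\delta_p = b L_t^{2/3}\) or without
   space turn quiescent; a daughter with few invasive neighbors mutates to
   the invasive phenotype with probability \(\gamma\); invasive cells make
   up to \(\mu\) attempts per day to chew through adjacent matrix
   (each attempt removes a Uniform\([0,\chi]\) amount of density) and step
   outward when a target is fully degraded, leaving a degraded trail — and
   never divide again. The sole drug effect is the division-reduction
   factor \(P_{\gamma,\phi} = 1 - (1-P_\gamma)\,\phi_{norm}\), with
   \(\phi_{norm} = \mathrm{clamp}(\phi/C_0, 0, 1)\).

The scales are joined by a *quasi-parallel* driver: because the
characteristic diffusion time \(t_m = x_0^2/(4D) \approx 0.2\) day is
shorter than the one-day cell cycle, each day is split into `Np` (default
50) sub-steps; the PDE advances by `1/Np` of a day, then the cohort of
proliferative cells randomly assigned to that sub-step divides at the
current local concentration, and the occupancy and diffusivity fields seen
by the PDE are refreshed. Cells in different cohorts therefore divide at
different phases of the dosing cycle, which is what produces the scatter of
division-reduction factors across the rim under periodic dosing.

# Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `a`, `b` | 0.12, 0.08 | mm^(1/3) | necrotic / proliferative rim scalings |
| `p0` | 0.192 | – | base division probability per day |
| `gamma` | 0.05 | – | mutation rate to the invasive phenotype |
| `Ai` | 2 | – | adhesion threshold of the mutation rule |
| `chi` | 0.15 (growth presets: 0.4) | – | per-attempt ECM degradation |
| `mu` | 3 | – | invasive attempts per day |
| `Pgamma` | 0.05 | – | division-reduction floor at full drug |
| `D0` | 1.3e-6 | cm^2/s | reference drug diffusivity |
| `Kmet` | 2.0e-4 | min^-1 | chemical decomposition rate |
| `lambda14` | 2.5e-4 or 2.5e-5 | s^-1 | per-cell uptake coefficient |
| `phi0` | 0.5 C0 | ug/ml | Michaelis constant (not reported upstream) |
| `eta` | 0.75 | – | intratumoral diffusivity factor |
| `rho_res` | 0.1 | – | residual density of degraded matrix |
| `tau_cycle`, `tau_decay` | 1440, 600/1800 | min | dosing period / decay time |

Time units are mixed deliberately to match field conventions (`Kmet` in
min^-1, `lambda14` in s^-1, dosing times in minutes, the cell cycle in
days); everything is converted to seconds once, at construction.

# Design choices where the design was open

**Division-rule combination.** The additive combination
\(p_0 P_{\gamma,\phi}(1-r/L_{max}) + (1-\rho_{ECM})^2\) makes the division
probability at the study's homogeneous matrix density (\(\rho = 0.3\)) at
least 0.49 regardless of drug, so *no* chemotherapy scenario could suppress
growth and a free tumor would cross the whole domain within weeks. The
package therefore defaults to the multiplicative combination
\(p_0 P_{\gamma,\phi}(1-r/L_{max})(1-\rho_{ECM})^2\), which reproduces the
reported growth scales; the additive form remains available as
`division_rule = "additive"` and is reported in run manifests.

**Occupancy, not cell count.** In the uptake term \(\lambda_0 =
\lambda_{14} n\), a dimensional reading of \(n\) as cells/cm^3 produces
uptake rates of order 10 s^-1 that would annihilate the drug within a
second, contradicting the finite intratumoral concentrations the model is
supposed to produce; since \(\lambda_{14}\) carries s^-1, \(n\) must be
dimensionless. The solver therefore uses the occupancy *fraction* (living
tumor cells / sites per voxel; the Fermi value itself for ideal-tumor
runs). `cell_density_field()` still exposes the per-volume density for
analysis.

**Mutation-rule neighbor count.** A daughter mutates only when its
"neighbor count" is below `Ai = 2`. On a 3D Voronoi lattice (mean degree
~15) every daughter has at least its parent plus several rim cells as tumor
neighbors, so counting *tumor* neighbors would make invasion essentially
impossible, while \(\gamma \times\) (division count) matches the reported
invasive-cell numbers. The default therefore counts *invasive* neighbors
(weakly adhesive phenotype among its own kind); set
`adhesion_neighbors = "tumor"` for the strict reading.

**Invasive migration direction.** The migration target "maximizing the
nutrient concentration" is undefined here because no nutrient field is
simulated; the standard surrogate — the adjacent matrix site farthest from
the tumor centroid (outward motion) — is the default, with
`migration = "random"` as the alternative.

**Stability gate vs production step.** `check_stability()` implements the
classical gate \(D\,\Delta t/\Delta x^2 < 1/2\). That is the
one-dimensional bound; the 3D 7-point explicit scheme is only stable and
positivity-preserving for \(D\,\Delta t/\Delta x^2 \le 1/6\), which the
solver's defaults respect (\(\Delta t = 0.95\,\Delta x^2/(6 D_{max})\)).
Validation-style runs can still request the upstream step of 0.1 s, which
satisfies both bounds comfortably.

**`L_max` and the domain.** The growth-permitting region is a sphere
(radius 0.4 cm in the default presets) masked over the cubic lattice;
`L_max` is the distance from the tumor centroid to that sphere along the
ray through the dividing cell. Daughters are placed uniformly at random
among adjacent matrix/degraded sites (the source model states no placement
rule). The tumor surface is the set of noninvasive tumor cells with at
least one matrix/degraded neighbor, and `L_t` for a given cell uses the
surface cell nearest to it.

**Update order.** Within a day: division (sub-stepped in cohorts), then
necrosis, quiescence, and invasive degradation/migration at the day
boundary; mutation is decided at birth using the neighbor configuration at
that moment. All stochastic draws flow through R's RNG, so
(configuration, seed) determines a run bit-for-bit.

**Adjacency.** Voronoi face-sharing is decided exactly per candidate pair
by a small linear-program feasibility test on the pair's bisector plane
(a face exists iff some plane point is at least as close to the pair as to
every other site). Candidates and constraints come from a cell-list cutoff
of 2.5 mean nearest-neighbor distances; on instances small enough to use
every site as a constraint the result matches a brute-force voxelized
Voronoi construction, and at production settings the cutoff sacrifices
well under 1% of faces (the largest-distance sliver faces). The cruder
distance-cutoff surrogate (`adjacency = "surrogate"`, 2.2 mean-NN
distances) is retained for very large lattices.

# What the generator emulates — and what it does not

The synthetic environment reproduces the study conditions: a 0.8 cm cubic
tissue block tessellated by ~37,000 automaton cells (hard-sphere radius
0.01 cm, packing fraction 0.3), homogeneous matrix (\(\rho = 0.3\)) or the
sinusoidal / two-region heterogeneous fields, a seeded tumor of linear size
0.06 cm, and 120 simulated days. Passing tests show the model's internal
consistency (conservation laws, closed forms, orderings, reproducibility)
and agreement with the study's reported growth scales; they do not show
that real tumors behave this way: the model has no nutrient field (nutrient
limitation enters only through the geometric rim rules), no cell mechanics
or pushing, no vasculature, no drug-induced death (drug only slows
division), and a single idealized cell cycle of one day.

# Numerical choices and problem sizes

Simulations in the test-suite and the acceptance script use, as this
package's own scaling choices: the full 0.8 cm / ~37k-site lattice with a
21^3 transport grid (\(\Delta x = 0.04\) cm) for coupled 120-day growth
runs (10–20 seeds per scenario); the study's own 81^3 grid
(\(\Delta x \approx 0.01\) cm) for the ideal steady-tumor transport
validations; and 0.2–0.4 cm lattices for unit-level properties. The
coupled grid is coarser than the validation grid because the growth
observables are radii averaged over thousands of cells, which are
insensitive to transport-grid resolution well before \(\Delta x = 0.04\)
cm; transport-level claims are always checked at 81^3.

Degenerate inputs are refused loudly: non-positive volumes/rates in the
PBPK system, unstable steps, out-of-range sinusoidal matrix parameters,
co-located packing points, a dosing shell smaller than the interior. The
logistic boundary value is applied per cycle phase; its printed form lacks
a closing bracket upstream and is implemented as
\(C_0/(1+\exp[(t-\tau_{decay})/(\tau_{decay}/10)])\). \(\tau_{infusion}\)
is carried as metadata only — the boundary model is fully specified by
\(\tau_{cycle}\) and \(\tau_{decay}\).

# Known limitations

* The invasive front advances ~0.017 cm/day under the default mobility
  parameters and reaches the 0.4 cm domain mask well before day 120, so
  late-time invasive *extents* are mask-limited; invasive *counts* are not.
* Table-level growth anchors upstream are single stochastic realizations at
  an unreported lattice resolution; multi-seed means here can sit outside
  narrow bands around them even when every ordering and mechanism agrees.
* The ideal steady-tumor profile keeps relaxing slightly beyond 5 h (the
  slowest diffusive mode of the 0.4 cm domain has a ~1–3.5 h time
  constant, depending on uptake); "steady by 5 h" holds only to a few
  percent.
* Voronoi cell volumes are approximated by the domain mean where needed;
  per-cell polyhedron volumes are not computed.
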