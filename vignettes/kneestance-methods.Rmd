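---
title: "Models and methods behind kneestance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kneestance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kneestance)
```

`kneestance` simulates tibiofemoral joint mechanics over one stance phase
of walking at reduced order: rigid femur and tibia, spring-bundle
ligaments, one-dimensional poroelastic cartilage columns under each
plateau cell, and per-frame static optimization of muscle forces. This
vignette explains the models, the choices that were genuinely open, and
what the package's tests do and do not demonstrate.

## Coordinate conventions and units

All quantities live in a right-handed frame fixed to the proximal tibia
of a right knee: x anterior, y superior, z lateral. Lengths are mm,
forces N, moments N·mm internally (N·m at the user interface for joint
moments), stresses MPa, ligament stiffnesses kN, angles degrees. The
femoral reference point — where muscle vectors, the residual force and
the external moments act — is the midpoint between the condyle centers,
and the femur pose is its 3 translations plus a
flexion → abduction → internal Cardan rotation sequence. Flexion is the
prescribed primary degree of freedom; the other five are solved from
equilibrium ("secondary kinematics").

## Muscle model

Muscle-tendon units are quasi-static, rigid-tendon Hill actuators:
`F = f_max (a · fl(l̄) · fv + fp(l̄))` with a Gaussian active
force-length curve (width 0.4), an exponential-toe passive curve, and
`fv ≡ 1` by default. A closed-loop tracking controller with activation
dynamics and elastic tendons is the full-order alternative; at walking
cadence the per-frame static approximation is the established reduced
form, and the force-velocity factor is available as an optional
multiplier for users who want rate effects.

Each frame solves

minimize `Σ aᵢ²` subject to `Σ rᵢ Fᵢ(aᵢ) = M_ext`, `aᵢ ∈ [lᵢ, uᵢ]`,

where `M_ext` is the external flexion-extension moment demand and `rᵢ`
the signed flexion moment arms. For muscles with an EMG envelope `eᵢ`
the box is `[max(0.02, eᵢ−0.1), min(1, eᵢ+0.1)]`; otherwise
`[0.02, 1]`, with 0.02 treated as zero excitation. Because the
stationarity map `aᵢ(λ) = clip(λ cᵢ/2, lᵢ, uᵢ)` is monotone in the
multiplier λ, the box-constrained QP is solved exactly by bisection — no
iterative NLP, no tolerance tuning. When the bounds make the moment
unattainable, moment matching degrades to a quadratic penalty (weight
1000, config-exposed) and the solution is flagged `infeasible-relaxed`.
Only the flexion-extension moment is muscle-balanced; frontal and
transverse moments are applied to the joint directly, because assigning
them to muscles is known to inflate muscle-force estimates.

EMG envelopes are computed by the standard gait pipeline: zero-phase
20–450 Hz band-pass, full-wave rectification, zero-phase 6 Hz low-pass,
normalization to the trial maximum (an MVC-style supplied maximum is
also available). All four settings are config-exposed; they are
conventional defaults, not values fitted to any dataset.

## Ligament bundles

The four main ligaments are bundles of parallel tension-only spring
elements (ACL 60, PCL 100, LCL 15, MCL 20 — about 1 mm² of insertion
area per element) with the piecewise law

* `f = 0` for `ε < 0` (slack),
* `f = K ε² / (4 εₗ)` for `0 ≤ ε ≤ 2εₗ` (toe),
* `f = K (ε − εₗ)` beyond (linear),

with `εₗ = 0.03`. The law is C1-continuous at `ε = 2εₗ` (both value
`K εₗ` and slope `K`), which the tests check to machine precision. `K`
is interpreted as the *total bundle* stiffness, split equally across
elements: per-element stiffnesses of 10–18 kN times 60–100 elements
would give whole-ligament stiffnesses two orders of magnitude above
experimental values, so the bundle reading is the physically consistent
one. Reference pre-strains at full extension are ACL +8 %, PCL −13.5 %,
LCL −7.33 %, MCL +3.66 %: each element's slack length is set to
`L₀ = L_ref/(1+ε_r)` at the reference pose, so the strain recovered
there equals `ε_r` exactly, for any offset. A single average pre-strain
per ligament is used — no anteromedial/posterolateral sub-bundles —
and element strain is the straight-line attachment distance (no
wrapping). Viscoelasticity is deliberately folded into the spring law,
whose parameters derive from high-rate loading appropriate for gait.

Attachment sites are parametric stand-ins for subject-specific anatomy
(ACL femoral attachment slightly lateral of the notch, MCL/LCL on the
epicondyles, PCL posterior-central), config-exposed. Element footprints
are discs filled by a deterministic mirrored-sunflower layout, chosen
symmetric in the footprint plane so that mirroring the whole joint in
the sagittal plane mirrors every element exactly.

## Fibril-reinforced poroelastic columns

The full-order reference is a 3-D fibril-reinforced poro(visco)elastic
continuum with depth-dependent arcade-like collagen architecture. The
reduced form here is one homogeneous 1-D column per plateau cell:

* a linear non-fibrillar matrix (E_m = 0.5 MPa, ν = 0.15),
* Darcy flow with `k = k₀((1+e)/(1+e₀))^{M_k}` (k₀ = 2·10⁻¹⁵ m⁴/(N·s),
  M_k = 5, e₀ = 4),
* a tension-only fibril network `σ_f = (E₀ + E_ε ε_f) ε_f`
  (E₀ = 2 MPa, E_ε = 500 MPa), with an optional dashpot
  (`eta` MPa·s) for the viscoelastic fibril variant — `eta = 0`
  reduces exactly to the elastic branch.

These material values are literature-typical for articular cartilage
and are labeled as such in the shipped config; they are not
subject-specific measurements.

The axial consolidation PDE `∂ε_v/∂t = −∂/∂z(k ∂p/∂z)` is advanced by
backward Euler on a uniform mesh, drained at the articular surface
(`p = 0`) and impermeable at the bone interface. Volumetric strain
couples the axial field to a single column-level lateral stretch:
in-plane equilibrium balances matrix stress, fibril tension and a
confinement restraint χ against the mean pore pressure. χ ∈ [0, 1]
emulates the surrounding tissue: χ = 1 is fully confined (no lateral
stretch, no fibril strain — a test case), χ = 0 laterally free; the
benchmark uses χ = 0.9. This is what preserves the two signature
behaviors of the full model at desk scale: under rapid loading the
column is nearly incompressible, so load is carried by fluid pressure
and the stiffness comes from fibrils stretched by lateral bulging;
under sustained loading the pressure dissipates toward the drained
matrix response.

Numerically, for a fixed secant modulus and a permeability field lagged
one step, the discrete system is linear, so the mean pore pressure is
affine in the lateral stretch; the in-plane equilibrium then reduces to
one scalar monotone equation per column, solved exactly by a vectorized
Newton, with an outer loop on the secant modulus (relative tolerance
1e-9, typically 3–5 passes). The whole plateau is stepped as a batch —
tridiagonal solves vectorized across columns — which is what keeps a
101-frame stance run near half a minute.

Two discretization facts matter for interpretation. First, the drained
surface node gives the column an immediate surface compliance that
scales with the mesh; the benchmark fixes 8 axial nodes per column, so
results are well-defined but the undrained contact stiffness is partly
a resolution choice. Second, the solver is validated in the regime
where the analytic answer is known: with fibrils off and χ = 1 the
column reproduces the Terzaghi degree-of-consolidation series within
0.5 % at Tv ∈ {0.1, 0.2, 0.5, 1} (≥ 50 nodes), the undrained step
pressurizes the fluid to the applied stress within 2 %, and the held
column relaxes monotonically to the elastic drained solution within
1 %. Mixture consistency — total traction equals effective stress plus
pore pressure at every node — holds by construction and is asserted in
the tests.

The reported "maximum principal stress" is the in-plane *effective*
stress including fibril tension. The total in-plane stress would
subtract the pore pressure and is compressive almost everywhere; the
tensile, fibril-dominated quantity is the one of biological interest,
and the effective reading is what makes it so.

## Joint geometry and contact

The knee is a parametric stand-in for segmented imaging geometry: two
femoral condyle ellipsoids (semi-axes 28/24/18 mm, centers ±22 mm from
the midline) over a 45 × 80 mm plateau of 2-mm cells, each compartment
dished with an 80 mm radius so the condyles rest at the compartment
centers at full extension. Contact is detected per cell along the
vertical (the lower ellipsoid surface has a closed form over each
cell), and tractions act along the dished-surface normals — the small
tangential components are what give the joint translational and
rotational restoring stiffness from contact; a config switch reverts to
purely vertical normals. Penetrations are capped below the column
thickness so solver excursions stay defined.

The menisci are annular foundations: vertical squeeze of the wedge
(tangent 0.5) extrudes the ring radially against hoop stiffness
(150 N/mm) plus two horn springs (200 N/mm each); the resulting
vertical support spreads over the covered cells as an added elastic
foundation, in parallel with the cartilage column there. With hoop and
horn stiffness zero the meniscus transmits nothing. Cells under the
ring are labeled cartilage-meniscus, and "contact area" metrics follow
the cartilage-to-cartilage filter, excluding them. In this geometry a
pure lateral translation of the rigid femur digs both condyles into
their compartment walls symmetrically; frontal-plane load
redistribution happens through the abduction tilt, which is how the
adduction moment loads the medial compartment.

## Equilibrium over stance

Each frame prescribes flexion from the gait input and solves the five
remaining DOFs so that the net force and the abduction/internal moments
vanish: Levenberg–Marquardt on the scaled residual followed by damped
Newton polishing (central-difference Jacobian), to a scaled residual
below 1e-9. The contact columns are advanced *inside* the residual
evaluation with the frame time step, so the converged pose and the
reported tractions are one consistent state; this embeds the
pose/consolidation coupling exactly rather than through a fixed-point
relay between separate solves, and it is why vertical conservation
(applied = contact + ligament) holds to 1e-12–1e-14 relative in
practice. After convergence the column states are committed; cells
whose displacement-driven step would go into suction are released
(zero-load recovery), as are previously loaded cells that lost contact
— the tissue keeps its unrecovered strain and pressure memory across
frames. Frames are warm-started from the previous pose; the first frame
brackets the vertical translation by bisection. The frame step is the
stance duration (0.6 s, config-exposed) divided by the grid intervals.

## Synthetic gait inputs

The generator stands in for an instrumented walking trial and defines
the benchmark conditions: bodyweight 765 N (a ~78 kg adult); a flexion
curve with an early-stance peak and a pre-toe-off rise, maximum 22°; a
double-bump vertical residual force peaking at 0.95 BW with a
midstance valley; an anterior-posterior shear of ±0.1 BW; an external
adduction moment peaking at 12 N·m (within the normal-walking range
and small enough that the frontal balance stays inside the ligaments'
working range) and a transverse moment of 1.5 N·m; and a
flexion-extension moment demand of −40 N·m (extensor, early stance) to
+30 N·m (flexor, late stance), sized so that quadriceps and
gastrocnemius forces produce a peak JCF near 2.7 BW. Muscle envelopes
for the measured muscles are generated *consistently* with that demand
— the unbounded optimization solution plus Gaussian noise (σ = 0.02,
clipped to [0, 1]) — mirroring a protocol in which measured EMG and
the estimated forces share the same pattern. With zero noise the trial
is seed-invariant; with noise it is byte-reproducible for a fixed seed.

What the generator does not emulate: measurement artifacts (soft-tissue
marker motion, EMG crosstalk), inter-subject geometry variation,
cadence variability, and any coupling from joint deformation back into
the gait inputs (the loading is applied in series, not co-simulated).
Passing tests therefore show that the pipeline reproduces the expected
mechanics under clean, self-consistent inputs — not that it would
reproduce any particular subject's measurements.

## Sensitivity analysis design

One sweep varies one ligament's pre-strain by
{−10, −5, 0, +5, +10} percentage points added to its reference value
(absolute shifts: the ACL row runs −2 % … +18 %), the other three held
at reference — five stance runs per ligament, twenty in total. Sweep
runs share no mutable state, so the offset-0 run is bit-identical
whether executed standalone or inside any sweep. On the benchmark knee
the package reproduces the directional findings: peak JCF is
non-decreasing in every ligament's offset; MCL tightening raises the
medial:lateral JCF ratio while ACL tightening lowers it; and
slackening below −5 % changes the JCF far less than tightening by the
same amount — asserted as an asymmetry of the mean absolute JCF change
over the stance curve, because the PCL and LCL are slack at the
peak-load frame in this geometry and express their influence in early
and late stance instead. The acceptance checks run the sweep on a
five-fold-thinned stance grid (21 frames), which leaves every one of
these orderings unchanged relative to the full grid.

## Numerical choices and degenerate inputs

* Activation bisection: 200 iterations, resolves the multiplier to
  ~1e-15; bounds with `e − 0.1 > 1` or `e + 0.1 < 0.02` collapse to the
  clipped envelope value.
* Column step: outer secant-modulus loop to 1e-9 relative with a smooth
  modulus floor (no branch switching near zero axial strain); lateral
  Newton clamped to stretch ∈ [−0.45, 0.9].
* Pose solve: residuals scaled by the applied load (forces) and load ×
  10 mm (moments); LM `ftol` 1e-15 then Newton polish; non-convergent
  frames raise an error naming the frame, and sweeps record the failure
  and continue.
* Zero-denominator metrics (no lateral load, empty contact) are
  reported as NA with a defined-ness flag, never as zero.
* Problem sizes in the shipped tests: 101-frame stance on the 2-mm
  plateau grid (920 columns, 8 nodes each) for the conservation run;
  21-frame runs for the twenty-run sweep; 50–60-node single columns for
  the consolidation validation. These sizes were chosen so the whole
  pipeline stays interactive on one CPU.

## Known limitations

* The patellofemoral joint, muscle wrapping, activation dynamics and
  tendon compliance are out of scope; muscle fiber lengths default to
  optimal, so the force-length curves act only if the user supplies
  normalized lengths.
* Cartilage columns do not exchange fluid or shear laterally; depth
  -varying collagen architecture and osmotic swelling are not modeled.
* Contact is frictionless and compartment surfaces are smooth
  paraboloids; femoral rollback arises only weakly from ellipsoid
  flexion geometry, so PCL engagement during midstance is smaller than
  in subject-specific models.
* Ligament insertions are points on rigid bones; insertion-site stress
  and within-bundle property variation are not represented.
* Absolute tissue-response magnitudes (fibril strain, stress, fluid
  pressure) depend on the placeholder material values and the column
  discretization; the package's claims are about orderings,
  conservation laws and validated limits, not about absolute
  subject-specific predictions.
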