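---
title: "Methods: tissue units, vascular routes, and flow-coupled drug transport"
author: "circuitboard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue units, vascular routes, and flow-coupled drug transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitboard)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices behind each solver,
and what the synthetic fixtures do and do not demonstrate about real
data.

## The two-scale picture

Molecular fate in tissue is governed by two transport regimes. Within a
*diffusive field* — a parcel of tissue in which any two points are within
diffusion distance — co-location is driven by Brownian motion, and the
legitimacy of combining cell-level models rests on the cells actually
sharing such a field. Between organs, molecules move by *advection*:
bulk blood flow along a topologically explicit route of vessel
segments. The package represents both: pFTUs (primary functional tissue
units) for the diffusive scale, and a vascular knowledgebase plus 1D
flow/transport solvers for the advective scale. The transition point
between the regimes is the pFTU's central advective channel.

## pFTU geometry and parcellation

A pFTU is a cylindrical diffusive field of **80 µm diameter and 60 µm
length** cuffing a central advective vessel (capillary, epithelial
crypt/duct, or unicellular conduit). The three template parameters are
exposed by `pftu_template()` and used as defaults throughout:

* `dilation_radius_um = 40` — half the diffusive-field diameter; the
  channel is dilated by a 40 µm sphere to produce the field;
* `seg_length_um = 60` — the spacing of the cutting planes set
  perpendicular to the channel;
* `diameter_um = 80` — nominal field diameter (recorded on every pFTU).

The dilation is *true Euclidean*: `euclidean_dilate()` thresholds an
exact anisotropic squared distance transform (a three-pass
lower-envelope algorithm over voxel-centre positions scaled by the
physical voxel size, implemented in C++). This is mathematically
identical to morphological dilation with a sphere structuring element
scaled to the sampling, but exact — iterating a discrete unit ball on an
anisotropic grid does not give the Euclidean ball, which is why the
distance-transform route is the primitive here. Distances are measured
voxel centre to voxel centre, with an inclusive (`<=`) radius threshold.
The test suite and acceptance script verify *exact set equality* against
a brute-force all-pairs oracle on random anisotropic volumes.

Cutting uses a channel centerline. Channels delineated manually come
with their own axis (`centerline_from_points()`, which densifies the
polyline to 1 µm so nearest-point queries resolve positions along the
axis); otherwise `centerline_of()` extracts one: the two geodesically
most distant channel voxels (double breadth-first sweep) are joined by a
shortest path whose edge weights penalise voxels close to the channel
surface (pulling the path onto the medial axis), each path point is
re-centred to the centroid of its perpendicular slab, and the result is
smoothed. Every dilated voxel is then assigned to the arclength bin
`[kL, (k+1)L)` of its *nearest* centerline point; the bin boundaries are
the perpendicular cut planes. Two consequences are load-bearing:

* the segments **partition** the dilated domain (disjoint, union equals
  the whole), a property the suite checks exactly; and
* a remainder shorter than `L` is retained and flagged `partial` rather
  than dropped — the partition stays lossless and the caller decides.

Whether overlapping dilated regions of *adjacent* segments should be
split exactly at nearest-arclength bins is a modelling choice (the
geometry admits others, e.g. splitting by the perpendicular plane of the
mid-point); the bin rule is one consistent realisation and is what the
partition property tests pin down.

## Cell marks, PTMs, and the compatibility gate

Cell annotations are nucleus-centroid marks (`x_um, y_um, z_um,
ct_term`). Membership is by centroid containment: a cell belongs to
every pFTU whose voxel set contains its centroid's voxel. Because
neighbouring diffusive fields overlap (the suite builds two parallel
tubes 60 µm apart whose 40 µm dilations share a slab), cells are in
general members of several pFTUs; a cell whose nucleus straddles a cut
plane is resolved by its centroid. Whole-cell-extent membership is out
of scope.

The primary tissue motif of a pFTU is its anatomy term plus the
*non-redundant* set of cell-type terms of its members — derivation is
idempotent and order-independent by construction (set semantics).
`ptm_compatible()` is the gate that makes model composition honest: a
cell model annotated with an anatomy term and required cell types may be
coupled to a tissue concentration only if the anatomy matches and every
required type is in the PTM — i.e. the modelled cells are provably
within diffusion distance of each other. Term matching is exact-string;
ontology subsumption reasoning is deliberately out of scope, so a model
annotated with a parent class will not match a child term.

## Serial-section registration

Plastic-embedded serial sections deform negligibly, so alignment is
rigid (tx, ty, θ). `align_pair()` minimises the mean squared gray
difference over the overlap region. The objective is normalised *per
overlapping pixel*: normalising over the fixed frame would reward large
shifts that shrink the overlap, so per-overlap normalisation plus a
minimum-overlap constraint (default 50 %) is used instead. The search
is: a coarse rotation grid (±10° in 1° steps) with, per rotation,
integer-shift candidates from FFT cross-correlation of the zero-mean
images (window ±15 px), followed by greedy pattern search at 0.5 then
0.25 px/degree steps. Pattern search only accepts improving moves, so
the attained SSD is non-increasing — the monotone-acceptance property
the suite checks implicitly through the recovery statistics.

Outlier handling follows the difference-profile idea: a pair is flagged
when its residual exceeds the rolling mean of nearby pairs by more than
`k = 3` rolling standard deviations over a ±5 window (conventional
robust defaults; with fewer pairs than the window, global statistics are
used; identical residuals have zero spread and flag nothing under the
strict inequality). Flagged pairs are re-searched with a broadened
window (half the frame) and seeded random restarts — deterministic given
the seed — and a still-flagged pair marks its moving section `removed`.

Recovery tolerance is **0.5 px and 0.5°** on perturbations drawn within
the search bounds; the acceptance sweep demands ≥ 95 % of 50 seeded
trials (the 0.25-px/degree final step leaves headroom of about half the
tolerance). Axial geometry is bookkeeping: section *i* (0-based) sits at
`i × thickness`, and a stack of n sections spans `n × thickness` — 270
sections at 2 µm give 540 µm.

## The vascular knowledgebase

The VKB replaces a logic/reasoner representation with an explicit typed
directed graph: the same queries (routes, supplies/drains, branch
order), desk-scale, no reasoner dependency. Invariants enforced by
`validate_network()`:

* positive length and radius, exactly one anatomy term per segment;
* microcirculations wired serially arteriole → capillary → venule, with
  kinds matching positions — the only legal order;
* branch lists duplicate-free and resolvable;
* weak connectivity of the whole graph (the cardiovascular system is one
  connected series of segments); and
* every microcirculation's region present in at least one `supplies` and
  one `drains` relation. Relations written against the region *term*
  are normalised to the component at construction.

Branch order is encoded as origin fraction along the parent in `[0, 1]`,
ties broken by declaration order, and survives JSON round-trips. Routes
are simple directed paths in flow direction, shortest first; a route
into a region term ends at that region's arteriole aggregate (where
blood enters the exchange bed) and a route out of one starts at its
venule aggregate — the spec of the query leaves this endpoint choice
open, and this convention makes "heart → kidney" read as heart, aorta,
renal artery, arterioles. Any microcirculation traversed en route is
visited a → c → v in order (checked by `validate_route()`).
`entities_en_route()` intersects tissue-specific expression with the
ligand's interactor set, segment by segment, reporting only segments
with at least one encounter.

Full-ontology content is deliberately not bundled; fixture vocabularies
of 10–100 segments stand in, and term ids are opaque strings.

## 1D haemodynamics

Per segment, mass and momentum with the nonlinear tube law:

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t u + u\,\partial_x u =
  -\tfrac{1}{\rho}\partial_x p - \frac{8\pi\mu u}{\rho A}, \qquad
  p = p_{ext} + \beta(\sqrt{A} - \sqrt{A_0}),$$

with linearised wave speed $c = \sqrt{\beta\sqrt{A_0}/(2\rho)}$ and
Poiseuille wall friction. In conservative variables $(A, Q)$ the
momentum flux is $Q^2/A + \beta A^{3/2}/(3\rho)$ (exact for constant
$\beta$ per segment), which the solver exploits:

* **Scheme.** Richtmyer two-step Lax–Wendroff in finite-volume form —
  second order in the interior, with well-defined interface fluxes.
  Friction enters the half-step predictor and is applied
  *semi-implicitly* in the corrector (`Q/(1 + h·8πμ/(ρA))`), so the
  discrete steady state balances flux divergence against friction
  exactly and the update is unconditionally stable in the stiff-friction
  limit.
* **Boundaries and junctions.** Outgoing Riemann invariants
  $W_{1,2} = u \pm 4c$ are extrapolated linearly from the last two cell
  centres to the face. Each node solves a small Newton system (damped,
  numerical Jacobian with per-variable scales): inflow nodes match the
  prescribed $Q(t)$; junctions impose one invariant per attached end,
  static-pressure continuity, and exact mass balance (a total-pressure
  variant is a documented alternative; static continuity is the
  default); terminal nodes hold a fixed pressure; bed nodes couple the
  characteristic to the RCR relation $Q = (p(A) - p_c)/R_{prox}$.
* **Beds.** $C\,\dot p_c = Q_{in} - Q_{out}$ with
  $Q_{out} = (p_c - p_{ven})/R_{dist}$. Inside the field solver the
  compliance is advanced explicitly with the same fluxes the ledger
  integrates, so stored volume equals the integral of net flux to
  round-off. The standalone `bed_update()` uses the exact exponential
  solution of the (linear, frozen-pressure) step instead — it reproduces
  the relaxation constant $\tau = C R_1 R_2/(R_1{+}R_2)$ exactly and is
  cross-checked against a generic stiff integrator in the suite.
* **Stability.** `dt` defaults to `0.8 · min(dx)/c0` and sub-steps
  automatically (with a single warning) when `|u| + c` tightens the CFL
  bound. Area collapse (`A ≤ 0`) and NaN states abort with segment and
  location.

Two verification notes worth keeping in mind. First, the steady
pressure drop of a *compliant* tube differs from the rigid Poiseuille
formula by a relative $\Delta p/(\rho c^2)$ — about $4\times10^{-4}$ at
the $c_0 = 12$ m/s used in the stiff-limit check, far inside the 1 %
tolerance but an irreducible floor that no grid refinement removes. The
grid-convergence property is therefore demonstrated by self-convergence
against a fine-grid reference on a high-viscosity case with a resolvable
gradient (observed ratio ≈ 4 per halving of dx, i.e. second order).
Second, global mass balance is exact *by construction* (the ledger uses
the solver's own interface fluxes), so the 10⁻⁶-per-cycle requirement is
met at round-off; the informative checks are the junction Newton
residuals, driven to 10⁻¹² in scaled units.

Units are SI internally (m, s, Pa, m³/s); fixture parameters are
order-of-magnitude physiological (blood ρ = 1050 kg/m³, μ = 3.5 mPa·s,
wave speeds 6–12 m/s, bed resistances 10⁸–10⁹ Pa·s/m³, compliances
~10⁻¹⁰ m³/Pa) and documented as non-canonical: they make the dynamics
realistic in character, not calibrated to a specific organism.

## Drug transport and receptor coupling

$$\partial_t (Ac) + \partial_x (Qc) =
  \partial_x\!\left(A D\, \partial_x c\right) + s(x, t)$$

solved explicitly with first-order upwind advection and central
diffusion on the flow solver's grid (cell *masses* are the state, so
conservation is structural). Choices and their rationale:

* **Upwind + explicit**: positivity-preserving at the combined CFL bound
  `dt (u/dx + 2D/dx²) ≤ 1`, automatically sub-stepped. A caller-chosen
  `dt = dx/u` runs at CFL exactly 1, where upwind advection is the exact
  shift — the advected-pulse check exploits this; away from CFL 1 the
  scheme's numerical diffusion `u dx (1−CFL)/2` is the documented price
  of positivity at desk scale.
* **Junction mixing** is flux-weighted: each node pools the mass flowing
  in and redistributes it to receiving ends in proportion to their
  flows, conserving mass identically even when the discrete cell flows
  on either side differ transiently.
* **Beds** are well-mixed compartments `V dc/dt = Q(c_in − c) − E Q c +
  s` with extraction fraction `E ∈ [0, 1]` removing drug irreversibly;
  the outflow to the venous side carries `(1−E) Q c`. Compartment volume
  is a transport parameter (default 10⁻⁷ m³), not derivable from the RCR
  impedance.
* **Sources**: time-varying point (mol/s at a position), distributed
  along a segment (mol/(m·s)), or into a region's bed compartment —
  matched by the bed's region term.
* **Mass audit**: injected = in transit + in compartments + extracted +
  outflowed, checked to round-off; negative mass beyond 10⁻⁹ of the
  injected total aborts as a scheme violation.
* Taylor dispersion augmentation of `D` is not applied; `D` is plain
  molecular diffusivity and a config input.

`couple_receptor()` integrates mass-action binding
`d[LR]/dt = k_on c (R_tot − [LR]) − k_off [LR]` by the exact exponential
update of the linear ODE over each sample interval (piecewise-constant
c) — unconditionally stable for stiff rate constants and bounded in
[0, 1] by construction. Units of `k_on` must match the concentration
units of the supplied trace (the equilibrium checks use
`Kd = k_off/k_on` in the trace's own units). The call *refuses* (listing
the missing terms) unless the receptor model's annotation passes the PTM
gate — the gate is the point of the PTM machinery, not an optional
check.

## Synthetic fixtures: what they do and do not show

The generators are first-class, seeded, and RNG-state-preserving:

* `make_tube_volume()` rasterises tube channels (voxel centre within the
  radius of a densified axis polyline) and places nuclei by rejection
  sampling within distance bands of the tube wall — emulating epithelial
  and endothelial cuffs. Voxel sizes in the fixtures are quarter-µm
  multiples, which makes every squared-distance comparison exact in
  double precision; the brute-force dilation oracle is then a true
  set-equality check with no tie-breaking ambiguity at the radius
  boundary, while staying in the realistic 1–10 µm microscopy range.
* `make_misaligned_stack()` applies known rigid perturbations
  cumulatively to a band-limited random texture, so registration output
  scores as `recovered ∘ applied ≈ identity`.
* `make_vascular_tree()` builds a symmetric (optionally jittered) binary
  arterial tree of the requested depth — depth 1 is a single root
  artery; 2^(depth−1) leaves — mirrored venously, with one
  microcirculation triplet and one RCR bed per leaf, Murray-type radius
  scaling (`2^{-1/3}` per generation), and supplies/drains/branch-order
  relations. Every generated network passes `validate_network()`.

What passing tests on these fixtures does *not* show: real histology has
staining variation, tissue deformation the rigid model ignores by
design, channels that branch and anastomose (the centerline extractor
takes the longest path and warns), manual delineation error, and cell
marks with observer noise; real vasculature is asymmetric with
parameter heterogeneity far beyond the fixture jitter. The fixtures
validate the *algorithms* — exactness of the dilation, the partition
property, transform recovery, conservation and analytic limits — not
biological calibration.

## Problem sizes and runtimes

The suite and acceptance script run on deliberately modest sizes chosen
as the smallest that make each property measurable: 64³ volumes for the
dilation oracle, 48–96 px sections and 50 trials for registration
recovery, 12–200 cells per vessel segment, trees of depth ≤ 3
(≤ 30 segments, where exhaustive route enumeration stays cheap), and
0.8–1.2 s of simulated flow (enough to pass the slowest transient, whose
decay is set by friction and bed RC constants). The whole suite runs in
about two minutes; the acceptance script in about half a minute.

## Known limitations

* Rigid 2D registration only; no deformable model, shade correction or
  patch stitching.
* Centerlines assume tube-like channels; branched channels reduce to
  their longest path with a warning.
* Exact-string term matching; no ontology reasoning or subsumption.
* 1D flow with Poiseuille friction: no wall viscoelasticity, no 3D
  effects, no vessel-geometry extraction from images.
* Transport is first-order upwind: sharp fronts smear away from CFL 1;
  no Taylor dispersion model.
* Bed parameters, compartment volumes and extraction fractions are
  inputs, not predictions; permeability-limited exchange between the
  channel and its pFTU cuff is not modelled.
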