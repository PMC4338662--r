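# circuitboard

A desk-scale R toolkit for multiscale computational physiology: it turns
3D histology into annotated **primary functional tissue units (pFTUs)**,
represents long-range vascular routes as a queryable **vascular
knowledgebase (VKB)**, and simulates **pulsatile blood flow and drug
advection–diffusion** over that network, coupled to receptor-binding
cell models that are gated by tissue-motif annotations.

It is aimed at physiology and PBPK/PD modellers who need the bridge
between *diffusive* tissue compartments (where molecules co-locate by
Brownian motion) and *advective* vascular routes (where blood carries
them between organs), with every piece annotated by opaque
anatomy/cell-type ontology terms so that tissue data and cell models can
be combined only when that combination is provably legitimate.

## What it computes

**Tissue parcellation.** A labeled voxel volume is split into connected
advective channels (26-adjacency). Each channel is dilated by a
true-Euclidean **40 µm** sphere — computed as an exact anisotropic
Euclidean distance transform, so non-isotropic voxel sampling is honoured
rather than approximated by iterated unit dilations — and the resulting
diffusive field is cut into **60 µm** segments by planes perpendicular to
the channel centerline. Each segment is one pFTU: a cylindrical diffusive
field of nominal **80 µm** diameter and 60 µm length cuffing the vessel.
Marked cell nuclei are assigned to every pFTU whose field contains them
(fields overlap, so multi-membership is expected), and each pFTU yields
its **primary tissue motif (PTM)**: the anatomy term plus the
non-redundant set of cell-type terms within one diffusion distance.

**Serial-section registration.** Adjacent 2D sections are aligned by
minimising the mean squared gray-value difference over their overlap
(rotation grid + FFT translation candidates + sub-pixel pattern search).
Poor matches are detected against a rolling difference profile of nearby
pairs (flag when residual > mean + 3 sd over a ±5 window) and rescued by
a broader seeded multi-start search; unrescuable sections are marked for
removal. Cumulative transforms place n sections of thickness t on an
axial span of n·t (e.g. 270 × 2 µm = 540 µm).

**Vascular knowledgebase.** Vessel segments (with explicit flow
direction and one anatomy term each), ordered branching (origin fraction
along the parent), and microcirculation components — a serial
arteriole→capillary→venule triplet supplying/draining one organ region.
Route queries answer "via which compartments must a ligand released at A
transit to reach B?" by shortest-first simple-path enumeration in flow
direction, and `entities_en_route()` lists the (off-)target interactors
expressed along the way.

**Haemodynamics.** 1D time-varying Navier–Stokes per segment with the
nonlinear pressure–area tube law `p = p_ext + β(√A − √A0)`
(pulse-wave speed `c = sqrt(β√A0/(2ρ))`), solved by a conservative
Richtmyer two-step Lax–Wendroff finite-volume scheme; junctions couple
through Riemann invariants with static-pressure continuity and exact
mass balance; RCR (Windkessel) beds close the arterial side onto the
venous side. The mass ledger uses the solver's own interface fluxes, so
global volume balance holds to round-off.

**Drug transport.** `∂(Ac)/∂t + ∂(Qc)/∂x = ∂x(AD ∂x c) + s` with
upwind advection (exact at CFL 1), flux-weighted junction mixing,
well-mixed bed compartments with extraction fraction E, and a
mole-by-mole mass audit. Tissue concentrations drive receptor occupancy
`d[LR]/dt = k_on c (R_tot − [LR]) − k_off [LR]` — but only after the
receptor model's annotation passes the PTM compatibility gate.

Seeded synthetic generators (`make_tube_volume`, `make_misaligned_stack`,
`make_vascular_tree`) produce every input with known ground truth.

## Worked example

```r
library(circuitboard)

## a synthetic crypt-like channel with typed nuclei
fix <- make_tube_volume(
  dims = c(120, 30, 14), voxel_size_um = c(4, 4, 8),
  tubes = list(list(start = c(20, 60, 56), end = c(440, 60, 56),
                    radius_um = 8, label = 1L)),
  nuclei = list(list(ct_term = "CT:enterocyte", n = 15, band = c(0, 20)),
                list(ct_term = "CT:goblet-cell", n = 5, band = c(0, 20))),
  seed = 1)
fix$volume
#> labeled volume 120 x 30 x 14, voxel 4 x 4 x 8 um, 1 labels

## parcellate into pFTUs (40 um dilation, 60 um perpendicular cuts)
par <- parcellate(fix$volume, term_map = list("1" = "FMA:colonic-crypt"))
par$pftus[[2]]
#> pFTU ch001_pftu001 (channel ch001, segment 1): 3240 voxels, term FMA:colonic-crypt

## cells -> PTM -> model gate
mem <- assign_cells(fix$marks, par$pftus, fix$volume)
ptm <- derive_ptm(par$pftus[[2]], mem, fix$marks)
ptm
#> PTM [FMA:colonic-crypt]: {CT:enterocyte}
ptm_compatible(ptm, list(anatomy_term = "FMA:colonic-crypt",
                         cell_types = "CT:enterocyte"))$compatible
#> [1] TRUE

## a vascular tree, a route query, and pulsatile flow
tree <- make_vascular_tree(depth = 2, seed = 1)
find_routes(tree$network, "FMA:artery-1", "FMA:region-11")[[1]]
#> route FMA:artery-1 -> FMA:region-11 (3 segments):
#>   art_1 -> art_11 -> mc_a_11

fs <- solve_flow(tree$flow, sine_inflow(8e-7, 3e-7, period_s = 0.25),
                 t_end = 0.5, save_every = 10L)
flow_mass_balance(fs)$relative_error
#> [1] 4.43e-15
```

The pFTU print shows one 60 µm slice of the dilated channel (3240
voxels) carrying its anatomy term; the PTM is that slice's anatomy term
paired with the deduplicated cell types found inside its diffusive
field; the gate passes because the modelled cell type is provably within
diffusion distance there. The route lists the ordered vessel segments a
blood-borne ligand traverses from the root artery into the region's
exchange bed, and the flow solver's volume ledger closes at machine
precision.

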