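---
title: "Methods: quantifying inter-domain motion with interdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying inter-domain motion with interdom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model of motion

`interdom` treats a multi-domain protein as a small set of rigid bodies
connected by flexible hinges. The object of study is never the internal
geometry of a domain — that is assumed (and verified, via rigid-core RMSD
series) to be stable — but the *relative* placement of the domains: how far
apart their centres are, how the hinge angles open and close, and how
specific side-chain contacts form and break as the molecule compacts.

For hPDI the rigid cores are `a` Glu22–Thr133, `b` Thr138–Gln233, `b′`
Ile238–Gly349 and `a′` Lys370–Glu471 (mature-protein numbering), with
Glu359 of the x-linker between `b′` and `a′` registered as its own
single-residue unit. Domain boundaries are excluded from the cores because
terminal residues are the flexible ones; all defaults are plain data
(`hpdi_segmentation()`, `hpdi_active_sites()`) and any other segmentation
passes through the same validity checks.

## Metrics and conventions

* **Domain centre**: unweighted mean of the rigid-core **Cα** coordinates.
  Whether centres should use Cα, backbone or all heavy atoms is a genuine
  free choice; Cα is the default because it is insensitive to missing
  side-chain atoms, and the filter is a config switch (`center_atoms`)
  recorded in every output manifest.
* **Angles**: the angle among three domains is measured at the centre of
  the *middle listed* domain, in degrees within [0°, 180°]. The phrase
  "angle among domains a, b and b′" is otherwise ambiguous; the vertex
  convention is stated in the manifest.
* **Dihedral**: the signed IUPAC torsion of the four centres in sequence
  order, range (−180°, 180°]. The canonical point set (0,0,0), (1,0,0),
  (1,1,0), (1,1,1) gives **+90°**; mirror reflection flips the sign. Values
  near 0° or ±180° mean near-coplanar centres.
* **Superposition**: Kabsch via SVD with the smallest singular value's sign
  corrected so the rotation is always proper (det = +1), even for
  mirror-image inputs. Fewer than three point pairs, or a collinear
  reference, is a degeneracy error rather than a silent answer.
* **Salt bridge**: a (positive, negative) residue pair whose closest
  distance between catalogued charged atoms (Arg NE/NH1/NH2, Lys NZ; Asp
  OD1/OD2, Glu OE1/OE2) is **strictly** below the 3.0 Å threshold.
  Bridges are counted per residue pair, not per atom pair, so a bidentate
  arrangement is one bridge. The criterion is symmetric in the two atom
  sets and needs no hydrogen positions. Histidine and chain termini are
  excluded by default; the catalogue is an argument, not a constant.
  An inclusive (≤) mode exists but is off by default.
* **Cation–π**: no universally agreed criterion exists, so the package
  states one: ring-centroid distance ≤ 6.0 Å *and* angle between the ring
  plane normal and the centroid→cation vector ≤ 45°, with the Trp
  six-membered ring (CD2, CE2, CE3, CZ2, CZ3, CH2) or the Tyr/Phe ring,
  and Arg CZ or Lys NZ as the cation point. Both cutoffs are arguments.
* **Active-site proximity**: the minimum SG–SG distance across sites
  (site-internal pairs excluded). The same nearest-SG convention is applied
  to crystal structures, which is the only self-consistent reading when a
  single "distance between the active sites" is quoted.
* **Frames are 0-based** everywhere, including file outputs.

## RMSD series with separate align and measure selections

`rmsd_series(traj, align, measure, reference)` superposes each frame onto
the reference using the *align* selection and reports RMSD over the
*measure* selection. Three uses cover the standard analyses: align =
measure = one rigid core (internal stability of a domain); align = whole
molecule (global drift against the first or last snapshot); align = domain
`b`, measure = domain `b′` (the displacement of one domain in the frame of
another, which is how a "b′ rotates ~20° with respect to b" statement is
quantified — see `rotation_angle_between()` for the axis–angle version).

One caveat carried as a config decision rather than hard-coded: the a′
core contains the mobile Thr428–Phe440 loop. It is *retained* in all fits
by default, since excluding it would silently change the reported RMSD;
callers can mask residue windows through the selection arguments.

## The synthetic generator and what it does (not) show

The generator builds four random rigid point clouds of
`atoms_per_domain = 30` Cα pseudo-residues each (radius 8 Å), numbered
inside the hPDI core ranges, with optional charged side-chain atoms at the
curated bridge-pair positions, SG atoms at 53/56/397/400, and a planar Trp
ring. Pose construction per frame is exact:

* `b` is fixed at the origin and `b′` at distance `dist_b_bp` (default
  30 Å) along x — the b–b′ separation is the one adjacent-domain distance
  that stays put while the molecule compacts.
* `a` is placed in the z = 0 plane from the prescribed a-b-b′ angle θ and
  a–b′ distance; the law of cosines then *determines* the a–b distance, so
  those three quantities cannot be prescribed independently (an infeasible
  combination is rejected before generation, naming the first violating
  frame).
* `a′` is placed in the half-plane through the b–b′ axis rotated by the
  prescribed dihedral φ, at fixed perpendicular offset (25 Å), with its
  axial position solved from the a–a′ distance. The construction's
  half-plane parameter equals the IUPAC torsion of the four centres
  exactly (the sign works out because `a` sits at positive y and the
  offset is positive).

Because each local cloud is recentred to have *exactly* zero mean, the Cα
centre of every placed domain equals the constructed centre to machine
precision, and all prescribed metrics are recovered from coordinates at
~1e-14. Scheduled sulfur distances and contact events override designated
flexible atoms: the pair is laid out along a fixed coordinate axis around
a midpoint snapped to the 0.001 Å grid, so the pair distance is exact in
memory and perturbed by at most 2×0.0005 Å after PDB serialisation.
Optional Gaussian jitter (`internal_noise_sd`, default 0) touches only
non-core, non-scheduled atoms, so rigid-core invariants stay exact.

Default schedules are the study conditions the package is built around:
201 frames with a–b′ relaxing 45 → 32 Å, a–a′ 55 → 35 Å, the a-b-b′ angle
110° → 70°, the dihedral 60° → 5° (toward coplanarity), the active-site
sulfurs 40 → 5.4 Å, and the Lys326–Glu431 / Lys308–Glu359 bridges forming
in the second half at 2.8 Å.

What passing these tests shows: the *analysis* layer measures exactly what
it claims on geometry it fully understands, including after file round
trips. What it does not show: anything about force fields, solvent,
kinetics or the realism of any particular trajectory — the toy is rigid
geometry plus scheduled events, not physics. Conclusions about a real
protein still require real ensembles.

## Numerical choices and edge cases

* Distances are Å, angles degrees, throughout; `frame_interval` is
  metadata only and never enters a computation.
* Coincident centres (angle), collinear consecutive centres (dihedral) and
  rank-deficient superposition references raise classed geometry errors.
* PDB serialisation quantises coordinates to 0.001 Å. After a round trip,
  centre distances are reproduced to ~1e-4 Å (averaging over 30 Cαs) and
  scheduled atom-pair distances to ≤ 1e-3 Å by construction. The
  four-centre dihedral, being a degree-valued quantity accumulating the
  error of four centres, lands at the same order (worst case ~1e-3 over
  random schedules) — the property suite runs at a fixed seed and the
  acceptance script reports the measured worst case.
* DCD I/O is single-precision by format (~1e-5 Å at typical magnitudes);
  the reader autodetects endianness, validates the atom count against the
  topology, and distinguishes an empty from a truncated file (reporting
  the last complete frame).
* Alternate locations collapse to the highest-occupancy conformer (ties by
  altloc letter); insertion codes are rejected outright because every
  interface here keys residues by plain integers.
* Waters and monatomic ions are dropped on reading by default; the first
  protein chain is used unless a chain is named.
* The analysis pipeline is deterministic: identical config and inputs give
  byte-identical TSVs, and the compactness summary is a pure function of
  the emitted series (`recompute_report()` proves it by recomputation).

## Design decisions that were genuinely open

* **Auto-scan vs curated pairs.** Published analyses trace a curated list
  of bridge pairs; `run_full_analysis()` generalises this by discovering
  every pair bridged in *any* frame and then tracing all of them, while
  the curated hPDI list ships as `hpdi_bridge_pairs()`. One wrinkle in the
  curated list: residue 181 of domain `b` appears in the literature both
  as Asp and as Glu; the packaged table uses Asp181, following the
  figure-level annotations over a single prose mention.
* **Problem sizes in the checks.** The property suites run 100 random
  charged frames (≤ 50 residues) against an exhaustive atom-pair
  enumeration, 100 random motion schedules with a PDB round trip each, and
  1000 random point sets against a quaternion-method superposition oracle
  — sizes chosen so the whole suite completes in about two minutes while
  still exercising every code path many times over.
* **No hard compactness cutoff.** The compactness report flags a metric as
  `compacted` purely by direction (final < initial). Inventing a threshold
  would imply a physical claim the geometry alone cannot support.

## Known limitations

Single-chain analysis (no inter-copy contacts); no mmCIF/XTC readers; no
SASA, so "buried salt bridge" claims are out of scope; no PCA/NMA or
per-residue fluctuation analysis; the cation–π criterion is geometric
only. The synthetic generator fixes `b` and `b′` in the laboratory frame —
rigid-body invariance of the metrics is exercised by applying random
global transforms in the tests rather than inside the generator.
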