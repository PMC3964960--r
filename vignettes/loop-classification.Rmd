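---
title: "Classifying protein loops by flanking-SSE geometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein loops by flanking-SSE geometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looparch)
```

`looparch` classifies the loops of protein structures by the geometry of
their bracketing secondary structure elements (SSEs) and the backbone
conformation of the loop itself. This vignette is the package's account of
the method: the model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where more than one convention was defensible.

## The pipeline

1. **Input.** PDB structures (backbone N, CA, C, O required). Waters are
   dropped; other HETATM groups are kept for contact annotation. Alternate
   locations resolve to the highest occupancy (ties: first in file); only
   the first MODEL of multi-model files is read. Two consecutive residues
   are *bonded* when their C–N distance is at most 1.9 Å, a standard
   peptide-bond tolerance.
2. **Chain selection.** Chains with resolution worse than 2.5 Å are
   removed; the rest are scanned longest-first and discarded at ≥ 40 %
   global sequence identity with any kept chain (Needleman–Wunsch, match 1,
   mismatch 0, linear gap −1; identity = matches / alignment length). The
   exact alignment is affordable at desk scale and avoids the word-size
   heuristics of the usual clustering tools.
3. **Secondary structure.** DSSP output files are consumed when available
   (letters H, G, E kept; I, T, S, B and blanks become coil). Otherwise an
   internal assigner imputes the amide hydrogen from the previous carbonyl
   and declares a hydrogen bond when the electrostatic energy
   27.888 · (1/r~ON~ + 1/r~CH~ − 1/r~OH~ − 1/r~CN~) < −0.5 kcal/mol.
   Two consecutive *n*→*n*+4 turns make H, two *n*→*n*+3 turns make G, and
   bridge pairs (parallel or antiparallel) make E, with priority H > E > G.
   Bridge pairs are retained: they later split β–β loops into hairpins and
   links.
4. **Smoothing.** Maximal runs of one letter over bonded residues become
   SSEs only at minimum lengths E: 2, G: 3, H: 4 residues; shorter runs are
   relabelled coil.
5. **Loops.** One loop per pair of consecutive same-chain SSEs without an
   intervening break; zero-length loops (adjacent SSEs) are legitimate and
   kept. Types: positional flank-letter pairs, with E–E split into `BN`
   (≥ 1 bridge between the two strands) and `BK` (none). Only direct
   bridges count; a bulge-interrupted ladder does not make a hairpin here.
6. **Geometry and conformation.** See below.
7. **Clustering, hierarchy, reports.** See below.

## Geometry

Each SSE axis is the screw axis of the least-squares rigid transform mapping
CA(1..n−1) onto CA(2..n). For an ideal helix this is exactly the helix axis
— every CA equidistant from it — and for strands it degenerates to the
strand direction. A plain total-least-squares line through the raw CA cloud
was considered first but rejected: for helices sampled over a non-integer
number of turns the principal component is tilted a fraction of a degree
off the true axis (enough to move CA–axis distances by ~0.5 Å), and the
bias decays only slowly with helix length. The TLS line is kept as the
fallback when the inter-residue rotation is under 5° (near-straight
segments) or the screw fit is degenerate; 2–3 residue SSEs use the line
through their terminal CAs. Axis endpoints are the projections of the first
and last CA onto the axis, so the axis is oriented N→C.

With **u₁**, **u₂** the two axis directions and **D** the vector from the
C-terminal end of axis 1 to the N-terminal start of axis 2:
*distance* = |**D**|, *hoist* = ∠(**u₁**, **D**),
*packing* = ∠(**u₁**, **u₂**), and *meridian* = the signed dihedral from
plane(**u₁**, **D**) to plane(**u₁**, **u₂**), right-handed about **u₁**,
in (−180°, 180°]. When **D** vanishes or is parallel to **u₁**, or the axes
are parallel, the meridian is 0 by convention — the quantity is genuinely
undefined there and a fixed value keeps the pipeline deterministic. Angles
are degrees at every API surface (radians internally); outputs print angles
to one decimal.

All four parameters are rigid-motion invariant; the test suite drives this
to < 1e−9 over 100 random rotations and translations.

## Conformation strings

Every (φ, ψ) maps to one letter of an ordered rectangle partition of the
Ramachandran torus; the first matching rectangle wins and `x` is the
fallback. The default 8-letter partition (`a` right-handed helical, `b`
extended, `l` left-handed helical, `e`, `p`, `g`, `t` tiling the rest) is a
documented stand-in: the historical region boundaries this echoes are not
available, so the rectangles are *configuration*, shipped in
`inst/extdata/default_config.yaml`, not constants in code. A loop's string
covers the loop plus the first two residues of each bracing SSE
(`n_flank = 2`), so a length-ℓ loop yields ℓ + 4 letters; loops with an
undefined dihedral anywhere in that window (termini, chain breaks) are
excluded from clustering but stay in the extraction reports.

## Clustering

Both routes share one neighborhood notion: two loops are geometric
neighbors when all four parameter differences are within the cutoffs
(defaults Δdistance ≤ 2 Å, Δhoist and Δpacking ≤ 30°, Δmeridian ≤ 45°,
circular). These defaults, and the Gaussian kernel widths σ = cutoff/2 used
for edge weights, are configuration values: the original calibration is not
in the available text, and the package treats them as the experiment's
tunable conditions.

**Density search (DS)** runs per (type, length): repeatedly take the
unassigned loop with the most unassigned neighbors and emit its
neighborhood as a cluster while it has at least `min_cluster_size` (3)
members. Ties break by the smallest mean cutoff-normalized 4-D distance to
the neighbors, then by lexicographic loop id — the greedy loop is fully
deterministic. The historical variant allowing ±1–2 residue length
deviation is deliberately out of scope.

**Markov Clustering (MCL)** runs per (type, length category). Categories
default to S = [0, 4], M = [4, 9], L = [9, 19], XL = [19, ∞); every
boundary length belongs to *both* neighbors (a length-4 loop is short *and*
medium), mirroring how boundary subclasses are labelled (`4S`, `4M`), so a
boundary loop may legitimately appear in two subclasses. Edges require the
geometry gate *and* conformation-string compatibility: the shorter string
must embed in the longer as an ordered alignment with exactly
(length difference) insertions, where any aligned pair touching a flank
position (first or last two characters of either string) must match, while
loop-interior mismatches are tolerated. The embedding — rather than a
rigid flanks-only comparison — matters precisely in the case cross-length
clustering exists for: when an assigner places an SSE boundary one residue
differently between two otherwise identical structures, the displaced
residue's code slides from the loop window into the flank window, and only
an alignment with a gap can see that the two strings describe the same
conformation. Weights are ∏ exp(−(Δ/σ)²) ∈ (0, 1].

MCL itself: add unit self-loops, column-normalize, then iterate expansion
(matrix squaring), inflation (entrywise power 2.0 plus renormalization) and
pruning (entries < 1e−5 zeroed, renormalized) until the maximum entry
change is < 1e−8 or 100 iterations. Clusters are read as the connected
components induced by the rows of attractor nodes (positive diagonal); a
node claimed by several clusters joins the largest, ties going to the
cluster containing the lexicographically smallest attractor. Column sums
are asserted to stay within 1e−12 of 1 after every normalization. One
practical consequence of the unit self-loop worth knowing: very small blobs
(3–4 members) whose mutual edge weights are far below 1 can decay into
singletons, because each node's self-loop outweighs its neighbors. With
realistic blob sizes (the recovery tests use 10 members) this does not
occur.

## Hierarchy, consensus and quality

Clusters land under (method, type, length), the length level being the
*shortest* member (MCL clusters may span lengths); at category-boundary
lengths the MCL label carries the category suffix (`4S`, `4M`). Within a
(type, length), clusters sharing a Ramachandran consensus merge into one
class. The consensus aligns members anchored at both flanks with gaps
centered in the loop region (the extra gap of an odd split goes after the
left half); at each position the code supported by more than 50 % of the
voting members wins (gaps do not vote), otherwise `x`. The threshold is
configurable: whether the original classification used plurality, majority
or exact matching is not stated anywhere available, and 0.5 is the weakest
rule that still yields a unique code.

Classes are numbered 1..n by descending total membership (ties:
lexicographic consensus string), subclasses within a class by descending
size (ties: smallest member id) — codes like `DS.HH.1.1.1` are therefore
reproducible. Consensus geometry is the component-wise median, with a
circular median for the meridian (candidate minimizing summed circular
distance; ties resolved toward the circular mean).

Subclass quality uses Kabsch superposition (SVD with determinant
correction; reflections excluded; < 3 points or collinear sets are errors)
over the N/CA/C atoms of the aligned positions (gap positions skipped).
The reference is the medoid — the member minimizing summed pairwise RMSD —
and the reported statistics are member-vs-medoid means and maxima: bounded
cost and robust to outliers compared with all-pairs means, and the
per-pair table is retained for anyone who wants the full distribution.
Percentages in the per-type report round half-up to one decimal.

## The synthetic generator

`generate_synthetic_structure()` builds backbones by sequential placement
from ideal internal coordinates (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
trans ω = 180°) and per-residue dihedrals, with canonical defaults of
(−57, −47) for α-helices, (−49, −26) for 3₁₀ helices and (−120, 120) for
strands. Identical specs and seeds give bit-identical coordinates.
`generate_antiparallel_sheet()` places a second strand by least-squares
fitting canonical inter-strand hydrogen-bond distances, providing a
fixture for bridge detection.

`jitter_structure()` implements coordinate noise as a smooth low-frequency
displacement field along the chain, scaled to a given per-coordinate RMS
(0.3 Å in the recovery experiments). Independent per-atom Gaussian noise of
that size routinely stretches C–N distances past the bonding tolerance and
destroys the hydrogen-bond network — real coordinate variation between
related structures is spatially correlated, which the smooth field
reproduces while leaving covalent geometry intact.

`generate_loop_family()` stacks these into planted helix–loop–helix
families: ten jittered copies of one ideal backbone form one geometric
blob. The recovery experiments use three families with loop dihedrals
placed firmly inside Ramachandran basins and away from helix-compatible
values at the SSE junctions — a loop residue that can be absorbed into a
flanking helix under jitter changes the loop's *length*, which the
same-length DS route by design treats as a different bucket (that ambiguity
is exactly what the cross-length MCL route exists to absorb, and the
string-embedding edge rule handles it). Family loop lengths (3, 2, 5)
avoid category boundaries so "one family, one subclass" is well defined
for MCL counting.

What the generator does **not** emulate: side chains (and hence packing
constraints), sequence-dependent dihedral preferences, missing atoms and
density-poor regions, crystallographic contacts, β-sheets inside a single
chain, and real (φ, ψ) dispersion within SSEs. Passing the planted-recovery
tests therefore demonstrates the correctness and determinism of the
machinery — extraction, geometry, both clusterings, hierarchy and
statistics — under controlled conditions, not classification performance
on real PDB data, whose cluster structure is far less separable.

## Problem sizes and defaults

The shipped tests and the acceptance script run on three 10-member
families (30 structures, 27–29 residues each), the property suites on 100
random transforms / 100 random clustering instances of ≤ 12 loops, and the
determinism check on two 6-structure pipeline runs — sizes chosen so the
whole suite exercises every code path in about a minute while the planted
blobs remain statistically unambiguous. Every threshold lives in one config
(`default_config()` / `read_config()`, YAML mirror in `inst/extdata/`);
unknown keys are rejected rather than ignored. The chain-redundancy filter
requires a numeric resolution — entries without one (e.g. NMR) are
excluded rather than special-cased.

## Known limitations

- The Ramachandran partition is a stand-in tiling; boundaries are data and
  can be replaced wholesale through the config without touching code.
- The meridian sign convention (right-handed about the first axis) and the
  endpoint-to-endpoint distance are package conventions; other conventions
  exist, so compare absolute geometry values across tools with care.
- The internal secondary-structure assigner is a faithful
  hydrogen-bond-energy implementation but is not DSSP; on real structures
  the two can disagree at SSE termini. Supply DSSP files when fidelity to
  DSSP matters.
- MCL is dense-matrix: fine for thousands of loops per (type, category)
  bucket, not for full-PDB scale out-of-core runs.
- π-helices, bulge-tolerant hairpin detection, mmCIF input and NMR
  ensembles are out of scope.
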