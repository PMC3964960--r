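# looparch

Structural classification of protein loops by the geometry of their
flanking secondary structure elements.

Most of a protein's fold is regular — α-helices, 3₁₀ helices and β-strands —
but the loops connecting those elements carry much of the functional
variation, and classifying them is the basis for loop modelling, structure
prediction and function annotation. `looparch` implements a complete
loop-classification engine for structural bioinformaticians: it extracts
every loop bracketed by two secondary structure elements (SSEs), describes it
by a four-parameter supersecondary geometry and a Ramachandran-alphabet
conformation string, clusters the loops with two independent algorithms, and
assembles the clusters into a four-level hierarchy with quality statistics.

## The method

**Loop types.** Each loop is typed by its bracketing SSEs (H = α-helix,
G = 3₁₀ helix, E = β-strand), with β–β loops split by strand pairing into
hairpins (paired, `BN`) and links (unpaired, `BK`), giving ten codes:
`HH, HE, EH, BN, BK, EG, GE, GH, HG, GG`.

**Geometry.** Each flank gets an axis (the screw axis of the least-squares
transform between consecutive CA windows — exactly the helix axis for ideal
helices). With **u₁**, **u₂** the axis directions and **D** the vector from
the end of the first axis to the start of the second:

- *distance* = |**D**|
- *hoist* = ∠(**u₁**, **D**)
- *packing* = ∠(**u₁**, **u₂**)
- *meridian* = signed dihedral from plane(**u₁**, **D**) to
  plane(**u₁**, **u₂**), right-handed about **u₁**

All four are invariant under rigid motion of the structure.

**Conformation.** Every residue's (φ, ψ) is coded with a letter from a
rectangular Ramachandran partition (8 letters; `a` helical, `b` extended,
`l` left-handed, …). A loop's conformation string covers the loop plus the
two residues entering each flanking SSE.

**Clustering, two routes.**

- *DS (density search)* — greedy extraction of the densest geometric
  neighborhoods among loops of one type and one length (all four geometry
  differences within configurable cutoffs).
- *MCL (Markov Clustering)* — loops of one type and one length *category*
  (short/medium/long/extra-long) are joined in a similarity graph (geometry
  gate plus flank-anchored conformation compatibility, Gaussian-kernel
  weights) and clustered by alternating expansion and inflation of the
  column-stochastic matrix. MCL can join loops of slightly different
  lengths, absorbing the uncertainty in SSE boundary placement.

**Hierarchy.** Each method's clusters are placed under
type → length (shortest member) → class (shared Ramachandran consensus) →
subclass (one cluster), with codes assigned by size, e.g. `DS.HH.1.1.1`.
Every subclass carries a consensus geometry (medians, circular median for
the meridian) and RMSD statistics from Kabsch superposition of members onto
the cluster medoid.

A synthetic-backbone generator (ideal-geometry chains built from φ/ψ
specifications, plus smooth coordinate jitter) makes the entire pipeline
testable without downloading a single structure.

## Worked example

Two planted families of helix–loop–helix structures (10 members each,
0.3 Å coordinate jitter), classified end to end:

```r
library(looparch)
library(dplyr)

structs <- c(
  generate_loop_family(c(-80, -90, -70), c(80, 0, 120), 10,
                       amplitude = 0.3, seed = 1, id_prefix = "fa"),
  generate_loop_family(c(60, 75), c(40, 25), 10,
                       amplitude = 0.3, seed = 101, id_prefix = "fb")
)

loops <- bind_rows(lapply(structs, function(s) {
  ss <- assign_secondary_structure(s)
  sses <- smooth_assignment(ss, s)
  annotate_loops(extract_loops(s, sses, attr(ss, "bridges")), s, sses)
}))

hierarchy <- build_hierarchy(cluster_loops(loops), loops)
tidy(hierarchy) %>%
  select(code, n, consensus_conformation, distance, hoist, packing,
         meridian, rmsd_mean)
#> # A tibble: 4 × 8
#>   code            n consensus_conformation distance hoist packing meridian rmsd_mean
#>   <chr>       <int> <chr>                     <dbl> <dbl>   <dbl>    <dbl>     <dbl>
#> 1 DS.HH.2.1.1    10 aallaa                     6.91  68.6    43.9   -10.8      0.292
#> 2 DS.HH.3.1.1    10 aababaa                    9.50  43.1   132.     -6.62     0.289
#> 3 MCL.HH.2.1.1   10 aallaa                     6.91  68.6    43.9   -10.8      0.292
#> 4 MCL.HH.3.1.1   10 aababaa                    9.50  43.1   132.     -6.62     0.289
```

Both routes recover exactly the two planted families: one subclass per
family per method, with the loop-3 family (`aababaa` conformation) and the
loop-2 family (`aallaa`) cleanly separated in geometry space, and mean
member-to-medoid RMSD around 0.3 Å — the jitter amplitude, as expected.
`classification_report(hierarchy, loops)` tabulates per-type totals and
percentages classified; `run_pipeline()` drives the same stages from PDB
files to tab-separated outputs, and `exec/looparch` wraps it for the
shell (`synth`, `extract`, `cluster`, `classify`, `report`, `run`).

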