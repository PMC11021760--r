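---
title: "Fragment growth in protein pockets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment growth in protein pockets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fraggrow is an automated fragment-based structure generator: starting from
probe fragments placed at pharmacophore hotspots of a protein binding
pocket, it grows small molecules by graph-level linking rules, scores the
grown structures against an empirical interaction field, and selects the
best candidates per iteration, optionally diversified by
interaction-fingerprint clustering. This vignette is the package's own
account of the models inside it: what is computed, which knobs matter, and
what the synthetic fixtures do and do not demonstrate.

## The pipeline

A run has a non-iterative stage and an iterative one.

1. **Pocket and hotspots.** The binding site is every residue with a heavy
   atom within 5 Å (`pocket_cutoff`) of the reference ligand. Typed
   hotspots are read off the pocket residues: hydrogen-bond donors (N/O/S
   with hydrogen; direction along the H when present, otherwise away from
   the bonded heavy atoms), acceptors (carbonyl, hydroxyl, carboxylate
   oxygens, pyridine-type nitrogens; lone-pair bisector direction),
   aromatic rings (centroid and normal of His/Phe/Tyr/Trp rings), and
   hydrophobic patches (complete-linkage clusters of three or more
   mutually close apolar carbons). The typing table is configuration
   (`inst/extdata/hotspot_rules.yaml`), not code, and it is this package's
   own convention.
2. **Probe placement.** For each probe conformer and each complementary
   (feature, hotspot) pair, a pose is constructed at ideal pairing
   geometry and spun about the pairing axis on a fixed angular grid (ring
   features enumerate both faces, since a ring normal has no intrinsic
   sign; the spin phase is anchored to the pocket centroid so the grid is
   equivariant under rigid motion of the complex); poses
   with hard steric clashes (closer than 0.7 of the summed van der Waals
   radii to the protein) are discarded, the rest are refined by rigid-body
   local optimization and ranked by pharmacophore score minus a small
   multiple of the binding energy. The refiner is a contract: the default
   is the internal rigid optimizer, and an external program (for instance
   a semiempirical quantum code) can be plugged in through
   `xtb_refiner()`, which truncates the pocket around the probe, shells
   out, and accepts the returned pose only if it does not worsen the
   internal energy.
3. **Growth loop.** Each iteration links every selected parent with every
   library fragment under the enabled rules (below), filters the products
   with the core medicinal-chemistry rules, generates 3D poses, docks them
   rigidly, scores them, and keeps the top `k` by docking energy or PLI
   score, either plainly or as per-cluster best after
   interaction-fingerprint clustering. Growth stops at `max_iterations` or
   when no parent remains below the molecular-weight ceiling.
4. **Final pass.** Structures from all iterations (probes included) are
   re-filtered with the enhanced rules (terminal functional groups plus
   user property bounds), deduplicated by canonical SMILES keeping the
   best-scoring pose, and annotated with binding energy, PLI score and
   shape similarity to the reference ligand.

## Linking rules

Four graph-level couplings generate offspring, all operating on
hydrogen-complete molecular graphs with the product re-perceived
(kekulization, aromaticity, hydrogens) by Open Babel; an offspring that
cannot be sanitized is silently rejected and tallied:

* **direct**: a single bond between two hydrogen-bearing atoms;
* **linker**: two placed probes bridged through a two-point linker
  fragment (both orientations of an asymmetric linker are enumerated);
* **fusion**: two ring bonds identified atom-for-atom, giving condensed
  systems; both mappings are tried, identical elements are required at
  identified positions, and an aromatic bond fused onto an aliphatic ring
  keeps its aromatic character (benzene + cyclopentane gives the indane
  skeleton);
* **spiro**: two saturated ring atoms identified into one spiro center;
  aromatic atoms are refused.

Attachment sites are any hydrogen-bearing heavy atom (amide nitrogens are
excluded by default), reduced to one representative per graph-automorphism
orbit to tame combinatorics; explicit `[*]` markers in a library file
override the implicit sites. Products carry a complete lineage record
(rule, parents, fragment, sites) and replaying the record reproduces the
canonical SMILES exactly — this is tested property-style, against an
independent brute-force enumerator.

## Geometry

**Conformers.** Coordinates are generated by a deterministic multi-start
distance-restraint embedder: ideal bond lengths from covalent radii,
1-3 distances from hybridization or ring interior angles, regular-polygon
restraints over aromatic rings, planarity (improper) terms at sp2
centers, and soft lower bounds between nonbonded atoms, minimized with
BFGS from classical-MDS starting points plus seeded jitter. Every
coordinate is a pure function of the R random seed, which the pipeline
depends on for reproducibility. The price is crude torsional sampling and
no stereochemistry; the gain is bitwise-reproducible geometry everywhere.

**Grown-candidate poses.** A child produced by direct linkage, fusion or
spiro junction inherits its parent atoms' coordinates from the parent
pose; the fragment is attached rigidly from a cached conformer at ideal
bond geometry, with the junction torsion sampled coarsely and hydrogens
rebuilt on the assembled skeleton. Because the same probe is usually
placed at several sites, assembly is tried on every recorded placement of
the parent molecule and the full-molecule energy decides which placement
carries the child. Linker children, whose two parents are both fixed in
space, instead go through full embedding followed by least-squares
alignment of the inherited atoms onto both parent poses.

**Docking.** Rigid-body docking is derivative-free (Nelder-Mead) local
search over the 6 rigid degrees of freedom with seeded perturbation
restarts; for direct-linkage children the junction torsion joins the
search as a seventh degree of freedom. Docking is two-tier: every
candidate gets a quick local search, then each iteration's best few
(`polish_top`) are re-docked from more starts with a larger iteration
budget, so a tight first-pass budget cannot cost a near-native pose its
rank. Docked energy never exceeds the starting energy.

**RMSD conventions.** The benchmark RMSD is computed in the pocket frame
without re-superposition — it measures pose reproduction, not shape — and
is minimized over graph automorphisms (a benzene rotated by 60° in place
scores zero). The alignment RMSD inside the growth loop is the usual
post-superposition residual. When the regrown copy and the reference are
separate molecule objects, the correspondence is the set of
color-respecting graph isomorphisms (igraph VF2 on order-subdivided
graphs), which subsumes the automorphism minimization.

## The interaction field

The scoring function is an explicit, documented surrogate on a
kcal/mol-like scale:

$$E = \sum_{\text{pairs}} \varepsilon\left[\left(\tfrac{r_0}{r}\right)^8 -
2\left(\tfrac{r_0}{r}\right)^4\right] \;-\; w_{hb}\sum_{\text{donors}} g_{hb}
\;-\; w_{ar}\sum_{\text{rings}} g_{ar} \;-\; w_{hp}\sum g_{hp} \;+\;
E_{\text{clash}}$$

with a soft 8-4 steric well over heavy-atom pairs within 6 Å
(\(r_0\) = summed van der Waals radii, \(\varepsilon = 0.02\): a
near-repulsive soft core, so untyped burial cannot outweigh the typed
terms), linear
geometric switch functions \(g\) (1 at ideal geometry, 0 at the window
edge) for hydrogen bonds (heavy-atom distance 2.6-3.4 Å, ideal 2.9;
donor-axis alignment within 60°, acceptor within 90°), aromatic pairing
(centroid distance 3.5-5.0 Å, stacked or T-shaped normal windows) and
hydrophobic contacts (3.0-5.5 Å), plus a quadratic penalty below 0.6 of
the van der Waals sum. Two choices deserve emphasis:

* every donor hydrogen — pocket or ligand side — counts only its
  best-matched partner, so a single well-placed acceptor cannot be
  scored against several donors at once;
* a hydrogen bond (weight 3.0) is deliberately worth far more than any
  single dispersion pair, mirroring the usual balance in empirical
  scoring functions.

The same switch functions back the pharmacophore score (sum over hotspots
of kind-weight times best switch value), the PLI score (the same sum
normalized by the total hotspot weight, so 0 means no contact and 1 means
every hotspot ideally satisfied), and the interaction fingerprint (one
bit per residue × contact kind, set when the corresponding window is
satisfied; the ionic bit requires opposite formal charges within 4.5 Å).
There is a single geometric definition of a contact in the package. The
field scores only intermolecular terms; ligand strain is not estimated.

Selection with fingerprint clustering uses deterministic leader
clustering at Tanimoto 0.6, processing candidates in descending score
order so cluster leaders are strong poses; the per-cluster best is kept.

## Filters

The shipped medicinal-chemistry rule set (`inst/extdata/mcf_rules.yaml`)
is an explicit list of reactive/unstable groups (acyl halides, peroxides,
geminal diols, aliphatic aldehydes, azo chains, extreme Michael
acceptors, isocyanates, hemiaminals), an element whitelist (C, H, N, O,
S, F, Cl, Br) and ring-size bounds (3-8). The enhanced pass additionally
matches terminal-group alerts against acyclic peripheral substituents and
enforces user property bounds (molecular weight 550 Da by default, heavy
atoms, rotatable bonds, ring count). Carbonyl-hydration liability
(geminal diols) is included although some generators tolerate it. SMARTS
matching uses an internal matcher for a documented subset of SMARTS
(element lists, aromaticity, X/H/charge/ring primitives) so violations
can report matched atoms; patterns outside the subset fall back to Open
Babel match counting. The rotatable-bond count is any single non-ring
bond between two non-terminal heavy atoms excluding amide C-N bonds.

## The benchmark and its fixtures

`run_benchmark()` implements regrow-and-reproduce: the reference ligand is
fragmented by breaking acyclic single bonds with a ring-atom endpoint
(amide bonds and terminal single-atom decorations are exempt; an acyclic
piece isolated between two cuts becomes a linker fragment); fragments
whose crystal geometry forms at least one hydrogen bond with the protein
become probes; all fragments become building blocks; a generation run
then tries to rebuild the ligand in its own pocket, and the minimum
pocket-frame symmetry RMSD of any regrown copy against the crystal pose
is classified as reproduced (< 2 Å), almost (2-4.5 Å) or failed
(> 4.5 Å). Regrowth defaults to the direct and linker rules — the inverse
of the fragmentation operator — because fusion and spiro products can
never reproduce a target obtained by cleaving acyclic bonds.

`make_toy_complex()` builds the synthetic complexes the tests run on: the
ligand is embedded and surrounded by minimal real residues placed at
ideal interaction geometry — a tyrosine hydroxyl donating to each ligand
acceptor, an aspartate carboxylate accepting from each ligand donor, a
phenylalanine ring stacked on each ligand ring — plus glycine shell
residues for steric body, oriented with their backbone polar groups
outward. Side-chain-anchored partners are used deliberately: they keep
backbone donors/acceptors away from the interaction sites, so the planted
pose is a clear optimum of the field rather than one of several
degenerate minima. The default study conditions for the regrow check are
ligands of 2-3 fragments, a library of the true fragments plus 10 decoy
fragments with one designated attachment point each, probes kept at 4
placements per molecule, 2 growth iterations of width `k = 2`, one docked
pose per candidate with a polishing re-dock of each iteration's leaders,
and a 260 Da ceiling (the planted targets span 171-233 Da); these sizes keep a five-complex
benchmark at desk scale (minutes, one CPU).

What passing these fixtures shows: the engine recovers a known answer
end-to-end — fragmentation, placement, growth, filtering, docking,
selection and symmetry-aware evaluation compose correctly, and the
surrogate field's optimum coincides with an ideal-geometry pose it was
never told about. What it does not show: performance on real proteins,
with crystallographic noise, waters, flexible side chains, or scoring
functions fitted to affinity data. The toy pocket is rigid, sparse and
built from the same residue templates the hotspot typing expects.

## Numerical choices and degenerate inputs

* All stochastic steps (embedding, docking restarts, decoy shuffles,
  shell placement) draw from R's RNG through seeds derived
  deterministically from one master seed; identical seeds give
  byte-identical SDF output.
* Conformers are deduplicated at 0.5 Å heavy-atom RMSD after optimal
  superposition; probe poses at 1.0 Å without re-superposition.
* Kabsch superposition never returns reflections; with three collinear
  atoms the rotation about the common axis is whatever the SVD yields,
  which is deterministic.
* Ties in candidate selection break on the canonical SMILES string.
* An empty hotspot list, an unplaceable probe, or a probe pool smaller
  than `k_probes` abort or warn early with a diagnostic rather than
  producing silent empties; a molecule 50 Å from the pocket scores
  exactly zero.
* PDB altlocs keep the highest occupancy (ties prefer altloc A); waters
  are dropped; insertion codes are part of the residue key.

## Known limitations

* No stereochemistry: the embedder samples both enantiomeric geometries
  indifferently and SMILES chirality flags are ignored.
* The energy model is a surrogate; its parameterization is configuration,
  not a fitted claim, and absolute energies have no thermodynamic
  meaning.
* Conformer quality is adequate for rigid and moderately flexible
  molecules; macrocycles and long chains get coarse geometry.
* Protonation states are taken as given; no tautomer or pKa handling.
* The synthetic-accessibility hook is deliberately empty, and de novo
  (reference-free) site detection is out of scope.
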