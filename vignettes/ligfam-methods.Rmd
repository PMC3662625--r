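---
title: "Ligand-centric analysis of SAM/SAH-binding proteins: methods and design"
author: "ligfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-centric analysis of SAM/SAH-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligfam)
```

# The problem

S-adenosyl-L-methionine (SAM) is, after ATP, the most versatile small-molecule
ligand in biology: best known as the universal methyl donor of the
methyltransferases (MTases), it also serves radical chemistry, aminopropyl and
ribosyl transfer, and more. Bound SAM — and its demethylated product
S-adenosyl-L-homocysteine (SAH) — appears across many unrelated protein folds,
and the residues that bind it are poorly conserved at the sequence level. A
*ligand-centric* annotation strategy therefore works outward from the bound
ligand itself: its conformation (ribose pucker, glycosidic and arm dihedrals),
its hydrogen-bond contacts, the strand topology of the sheet that cradles it,
and the family-level conservation of the contacting residues. `ligfam`
implements that strategy as a tested R library with a thin command-line
wrapper, together with a deterministic synthetic-structure generator that
serves as its download-free test surface.

# Ribose pucker: pseudorotation analysis

A five-membered ring is never planar; its out-of-plane pucker is summarised by
two numbers, the pseudorotation phase angle $P$ and the puckering amplitude
$V_{max}$. `ligfam` follows the classical reference-torsion convention: with
endocyclic torsions $\nu_0 \dots \nu_4$ taken around the ring
C1'–C2'–C3'–C4'–O4' (and $\nu_2$ as reference),

$$\tan P = \frac{(\nu_4 + \nu_1) - (\nu_3 + \nu_0)}
  {2\,\nu_2\,(\sin 36^\circ + \sin 72^\circ)}, \qquad
  V_{max} = \nu_2 / \cos P ,$$

with the quadrant of $P$ resolved by `atan2` so that $V_{max} \ge 0$; the
implementation evaluates $V_{max}$ as $\sqrt{s^2 + \nu_2^2}$ (where $s$ is the
numerator rescaled), which equals $\nu_2/\cos P$ identically but stays finite
as $P$ approaches $\pm 90^\circ$. Every defined result satisfies
$\nu_2 = V_{max}\cos P$ exactly.

Conformer names are read off the pseudorotation wheel. Envelope forms sit at
the odd multiples of $18^\circ$ ($18^\circ =$ C3'-endo, $126^\circ =$ C1'-exo,
$162^\circ =$ C2'-endo, ...); the `conformer` field reports the nearest
envelope midpoint, which is the vocabulary used in structural surveys of
bound SAM, while `wheelSector()` additionally exposes the full 20-sector
label including the twist forms between envelopes. Near-planar rings
($\max_j |\nu_j| < 1^\circ$) are reported as undefined rather than dividing
by a vanishing $\cos P$ — with amplitudes this small the phase is numerically
meaningless.

Both $P$ conventions are emitted: $[0^\circ, 360^\circ)$ and the signed
$(-180^\circ, 180^\circ]$ alias, because surveys that report "negative phase
angles" implicitly use the signed form.

A useful check worth recording: mirroring a ring negates every endocyclic
torsion, and since $-\cos x = \cos(x + 180^\circ)$ this maps
$P \mapsto P + 180^\circ$ (C3'-endo $\leftrightarrow$ C3'-exo) with $V_{max}$
unchanged. The test suite asserts exactly this map.

## Ligand dihedrals

Three dihedrals describe whether the bound ligand is extended or folded:
*chi* = C4–N9–C1'–O4' (glycosidic orientation of the adenine),
*gamma* = O3'–C4'–C5'–SD and *delta* = C4'–C5'–SD–CG (the methionine arm; for
SAH the CG of the homocysteine arm). Gamma is a pseudo-torsion — O3' is not
bonded to C4' — but it is well defined on coordinates and is computed as
such. No extended/folded cut-off is imposed: the three angles are reported
descriptively, because any threshold would be arbitrary.

## B-factor reliability

Crystallographic temperature factors measure atomic mobility; a ligand whose
atoms average above $80\ \mathring{A}^2$ is too mobile for its modelled
conformation to be trusted. `ligandReliability()` flags ligands with mean B
**strictly** greater than 80 (a mean of exactly 80.0 is not flagged), and
flagged ligands are excluded from conformation typing by default while still
appearing, marked, in every report.

# Ligand superposition and conformation Types

Pairs of ligands are superposed by least squares over either the five ribose
ring atoms (`"ribose"`) or the intersection of shared heavy atoms (`"all"`;
a SAM–SAH pair automatically drops the S-methyl CE). The fit is the Kabsch
SVD solution restricted to proper rotations — reflections are chemically
meaningless and forbidden — and the implementation is cross-checked in the
tests against an independent quaternion-eigenvalue (Horn) oracle to
$10^{-6}\ \mathring{A}$.

Conformation *Types* are obtained by complete-linkage agglomerative
clustering of the all-vs-all RMSD matrix, cut at a threshold (default
1.0 Å). The matrix itself is computed with the ribose moiety as the common
fitting frame and the RMSD measured over all shared atoms: the ribose is the
part of the ligand that superposes almost perfectly across folds, so
differences in the measured RMSD then reflect genuine divergence of the
adenine and methionine arms. Both the atom sets and the threshold are
configurable, and a target-based mode (`rmsdToTarget()`) reproduces the
protocol of comparing every ligand to one high-resolution reference
structure. Complete linkage was chosen because its cut height bounds the
intra-cluster diameter, making the threshold directly interpretable in
Ångström; no published algorithm or cut-off exists for the original Type
assignments, so these are package design choices. Type labels are
deterministic: clusters are numbered by decreasing size with ties broken by
the lexicographically smallest member identifier.

# Hydrogen-bond contacts

Hydrogen-bond identification is geometric and heavy-atom only: most X-ray
entries lack hydrogens, so no angle term is defensible. A contact is a
(ligand N/O/S, protein N/O/S) pair within 3.35 Å (configurable) in which one
partner can donate and the other accept, per fixed donor/acceptor tables:
the adenine ring nitrogens N1/N3/N7 accept, the exocyclic N6 donates, the
ribose hydroxyls O2'/O3' do both, the ring ether O4' and the carboxylate
O/OXT accept, and the terminal amine N donates. The thioether/sulfonium SD
is excluded — it essentially never hydrogen-bonds in these complexes.
Carbon atoms never participate. The 3.35 Å default approximates the
donor–acceptor distance criterion of the classical H-bond assignment
programs while staying parameter-light and reproducible. Water-mediated
bridges are out of scope; only direct contacts are counted.

`interactionProfile()` aggregates contacts over family representatives into
per-ligand-atom residue-type counts and charged/hydrophobic/polar fractions
(charged = D,E,K,R,H; hydrophobic = A,V,L,I,M,F,W,C; polar = S,T,N,Q,Y,G).

# Sheet topology and the LigFold catalog

Within the Rossmann-fold MTases, the spatial left-to-right order of the
β-strands (numbered 1..n from the N terminus) distinguishes topological
sub-classes. `buildSheet()` takes secondary structure as *input* — a strand
table plus ladder (strand-pairing) table, or a classic DSSP file — builds
the ladder graph, rejects barrels (cycles) and branched sheets, reduces a
disconnected graph to its largest sheet with a warning, and linearises the
path into an order string such as `"3214567"`.

A linearised sheet can be read in two directions, and the catalog contains
entries that are each other's reversals, so the reading direction matters
and no convention is published. The package's rule: compute both readings;
if exactly one matches the packaged catalog, use it; otherwise (both or
neither match) use the reading whose first strand has the lower N-to-C
number, and set the `ambiguous` flag so the choice is auditable.

The packaged `ligFoldCatalog()` holds the 14 observed fold-type-I strand
arrangements with their LigFold identifiers (SAM_DM_Ia ... SAM_DM_In),
including the dual-domain Ia+Ib combination (SAM_DM_Il) which
`dualDomainScan()` resolves by joining per-domain order strings. Unmatched
topologies are flagged NOVEL with the nearest catalog entries by string
edit distance. `foldRegistry()` enumerates the 18 fold types to which bound
SAM has been observed — 9 MTase folds and 9 non-MTase folds. The registry's
first five MTase entries carry the classical class names (Rossmann fold,
protein MTases, tetrapyrrole methylases, RNA methylases, SET-domain histone
MTases) and the Helical bundle is among the non-MTases; the remaining
entries are reconstructed placeholders that preserve the counts, which is
all downstream code relies on.

# Family site rules

A site rule records, for one family with a structure-bearing representative,
the ligand-contacting residues that are conserved across *all* aligned
members. Two conservation modes exist: `strict` (every row identical, no
gaps — gaps disqualify a column) and `conservative` (all rows within one
substitution group: {D,E}, {K,R}, {S,T}, {N,Q}, {I,L,V,M}, {F,Y,W}, {A,G};
residues outside every group match only themselves). Rule positions are the
intersection of contacting and conserved columns; contacts that cannot be
mapped to an alignment column are reported as unmapped, and an empty rule
is legal (with a warning) — positions binding through backbone O/OXT, for
example, are typically not conserved and drop out.

Propagation to a structure-less query sequence uses global pairwise
alignment of the query against the representative (BLOSUM62, affine gaps:
open 10, extend 1), maps each rule position through the alignment and
checks the query residue against the allowed set. The match is positive
only if *every* position matches — the same strictness that makes the
original annotations high-confidence — and per-position diagnostics are
always produced. Profile HMMs would be the heavier-weight alternative for
this decision; at the scale of a single family with a designated
representative, a pairwise global alignment makes the same accept/reject
decisions and keeps the package self-contained.

## Conserved MTase motifs

`detectMotifs()` recognises the classical fold-type-I motifs: Motif I is the
glycine-rich loop `[GA]x[GA]x[GA]` preceded by an invariant acidic residue
at −2 and hydrophobic residues at −3/−4 (relative to the first glycine);
Motifs II (mid-strand-II acidic with hydrophobic −3/−4), III (hydrophilic
strand-III N-terminus, optional C-terminal glycine), IV (acidic near the
strand-IV N-terminus with V/I at +2) and VI (glycine at the strand-V start
with hydrophobic +2/+3) require strand annotations and are skipped with a
notice when none are supplied. Motif V — the helix after strand IV — has no
conserved residues and is only ever reported as a region, never as a
sequence match.

# The synthetic generator

Real surveys of SAM-binding structures rest on hundreds of PDB entries; the
package instead tests every analysis path against synthetic inputs whose
ground truth is known exactly.

**Rings** (`makeRibose`): a planar regular pentagon is displaced out of
plane with the wave $z_k \propto V_{max} \cos(P + 144^\circ k + 54^\circ)$
(the $54^\circ$ offset aligns the displacement wave with the torsion
convention), then refined by constrained least squares — in a rigid-body-free
9-parameter frame — against the target torsions
$\nu_j = V_{max}\cos(P + 144^\circ (j-2))$ plus idealized bond lengths.
An exactly-cosine torsion set with exactly-fixed bond lengths over-determines
a closed five-ring by one degree of freedom, so the refinement balances the
two: with the packaged weights the torsion residual stays below
$0.4^\circ$ (tolerance 0.5°, else a generation error) while bonds stay
within about 0.04 Å of their 1.45–1.53 Å targets. Recovery of $(P, V_{max})$
through the analysis module is better than $0.4^\circ$ over the full
$80$-point grid ($P$ every $18^\circ$; $V_{max} \in \{10, 25, 40, 55\}$,
matching the amplitude range seen in real SAM complexes).

**Conformers** (`makeConformer`): full heavy-atom SAM (27 atoms) or SAH
(26; no CE) built from internal coordinates — ribose from `makeRibose`, the
planar adenine attached rigidly through chi, the arm through gamma (set by
rotation about C4'–C5' so the pseudo-torsion lands exactly) and delta.
Idealized bond lengths and angles are standard small-molecule values
embedded in the source; the adenine plate is a planar template with
idealized purine geometry. Non-bonded pairs (bond-graph distance ≥ 3)
closer than 1.8 Å raise a generation error with a clash report; the default
dihedrals (chi = −60°, gamma = −60°, delta = 180°) build clash-free across
the entire pseudorotation wheel. Coordinates are fully deterministic; the
`seed` argument exists for interface symmetry and affects nothing.

**Pockets** (`makePocket`): each specification row places a one-atom
protein residue at *exactly* the requested distance from the named ligand
atom, along an outward direction chosen (from a small deterministic
candidate fan) so that no other polar ligand atom falls within
hydrogen-bonding range of it — the designed contact set is therefore the
exact expected answer. Decoy carbon atoms (which cannot hydrogen-bond) are
seeded at ≥ 5 Å from every ligand atom.

**Families** (`makeFamily`): gapless toy alignments with specified strict /
conservative / non-conserved columns at specified representative positions
(conservative columns cycle through the substitution group so they are
never accidentally strict; non-conserved columns draw from a different
group so they can never pass either mode), reproducible per seed.

What passing these tests shows — and does not. The generators exercise the
complete analysis logic on inputs with exact ground truth, which is the
right standard for the geometry, clustering, graph and conservation
machinery. They do not emulate crystallographic noise, alternate
conformations beyond the altloc policy, water networks, gapped family
alignments or genuinely ambiguous sheet graphs; conclusions about real PDB
entries inherit the usual caveats of the input coordinates, and the
packaged H-bond criterion is a distance-only approximation of the
angle-aware programs used in curation pipelines.

# Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties go to the first altloc
  identifier — one deterministic conformer per atom.
* Multi-model files: model 1 only (crystal structures are the use case).
* Hydrogens are ignored everywhere.
* Atom-name dialects: `O2*`-style names are normalized to `O2'` at parse
  time; all code speaks primed names.
* Planarity cut-off $\max|\nu_j| < 1^\circ$; degenerate torsions (collinear
  triples) raise errors rather than returning garbage.
* Kabsch requires ≥ 3 non-collinear pairs; masked RMSD cells (pairing
  failures) propagate as NA and block typing with an instructive error.
* Report JSON is bit-stable: fixed key order, no timestamps — identical
  inputs and configuration give byte-identical reports.

# Problem sizes used by the packaged checks

The test suite and the acceptance script regenerate everything they assert:
an 80-point pucker grid, 100 random 10-atom clouds for the superposition
oracle, 200 random strand permutations (n = 5–8), multi-site pockets with
20 decoys, and 100 seeded toy families for the conservation audit. These
sizes keep the full suite around half a minute on one CPU while covering
the full pseudorotation wheel and every catalog entry.

# Known limitations

* Secondary structure is ingested, never computed; the DSSP reader covers
  the classic fixed-column format only.
* β-barrels and branched sheets are rejected by design.
* The H-bond model has no angle term and no water-mediated bridges.
* Site rules seed exclusively from hydrogen-bond contacts; hydrophobic
  packing positions are not considered.
* The reading-direction convention for strand-order strings is a package
  decision (catalog-guided, lower-first-strand fallback) — sheets whose two
  readings both match the catalog are flagged ambiguous rather than
  silently resolved.
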