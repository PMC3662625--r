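Package: ligfam
Title: Ligand-Centric Annotation of SAM/SAH-Binding Protein Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A ligand-centric toolkit for the structural annotation of
    S-adenosyl-L-methionine (SAM) and S-adenosyl-L-homocysteine (SAH)
    binding proteins. Extracts bound ligands from PDB files, computes
    ribose pseudorotation parameters (phase angle P, amplitude Vmax,
    envelope conformer names) and the chi/gamma/delta ligand dihedrals,
    flags high-B-factor ligands, superposes ligands (ribose moiety or
    all atoms) with Kabsch least-squares fitting and clusters the
    resulting RMSD matrices into conformation Types, profiles
    ligand-protein hydrogen bonds, classifies beta-sheet strand-order
    topologies against a packaged LigFold catalog of Rossmann-fold
    methyltransferase sub-classes, and generates family site rules
    (conserved SAM-binding residues anchored to a representative
    structure) that can be propagated to structure-less sequences.
    Includes a deterministic synthetic-structure generator (ribose
    rings at prescribed pucker, full SAM/SAH conformers, toy binding
    pockets and toy family alignments) used as the package's
    download-free test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: StructuralBioinformatics, Proteomics, Annotation, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structio.R'
    'contacts.R'
    'geometry.R'
    'ligfam-package.R'
    'siterules.R'
    'topology.R'
    'superpose.R'
    'pipeline.R'
    'synthconf.R'
    'utils.R'
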