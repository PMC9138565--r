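---
title: "SASA fingerprints and clustering: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SASA fingerprints and clustering: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrsasa)
```

This vignette is the package's own account of the science it implements:
the accessibility model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The accessibility model

The solvent-accessible surface of a protein is the surface traced by the
center of a spherical probe (water, radius 1.4 Å) rolling over the van der
Waals envelope of its heavy atoms. `atom_sasa()` estimates it by
Shrake–Rupley sampling: each atom's radius is expanded by the probe radius,
`n_points` quasi-uniform directions are placed on the expanded sphere with
a golden-spiral (Fibonacci) lattice, and the accessible area is

$$A_i \;=\; 4\pi (r_i + r_p)^2 \; \frac{\#\{\text{points outside every
neighboring expanded sphere}\}}{n},$$

with points exactly on a neighbor sphere counted as buried, which makes
the estimate deterministic. Only atoms within $R_i + R_j$ of expanded
radii can occlude each other; candidates are found through a uniform
spatial grid whose cell size equals the largest expanded diameter, so a
27-cell lookup provably contains every possible neighbor (the test suite
checks the grid path against a plain all-pairs loop).

Two details deserve emphasis:

- **Orientation canonicalization.** A fixed sampling lattice is not
  rotation-invariant: rotating the molecule changes which lattice points
  are buried, perturbing areas at the percent level. `atom_sasa()`
  therefore expresses the lattice in a molecule-fixed frame — the
  principal axes of the atom coordinates, with eigenvector signs fixed by
  the skew of the coordinate projections and a right-handed third axis —
  so areas are invariant under rigid motion to floating-point precision.
  The limitation is inherited from the frame: for molecules whose
  principal axes are degenerate (exactly symmetric bodies), the frame is
  arbitrary, though still deterministic. `orient = "fixed"` retains the
  laboratory-frame lattice, under which removing an atom can only free
  sample points, making occlusion monotonicity exact; with the principal
  frame the same property holds only up to the sampling resolution,
  because deleting an atom also perturbs the frame.
- **Accuracy vs `n_points`.** The default n = 960 reproduces the
  closed-form area of an isolated sphere essentially exactly and the
  two-sphere spherical-cap complement to ~0.3%; doubling n moves no atom
  of an ideal-helix fixture by more than 2% *of its expanded-sphere area*.
  The fraction-of-sphere yardstick is the meaningful one: deeply buried
  atoms have areas near zero, where relative change is ill-conditioned.
  An independent Monte-Carlo estimator (random directions, same burial
  rule) agrees within 1% of the sphere area on small random fixtures.

Radii default to the Chothia united-atom set (C 1.87, N 1.65, O 1.40,
S 1.85 Å) with hydrogens ignored — appropriate for backbone-plus-heavy-atom
models — and are fully configurable through `radii_table()` /
`read_radii()`. Polarity follows the element: N and O polar, C and S
apolar; the polar/apolar and backbone/side-chain decompositions are exact
partitions of each residue's total, and their whole-protein aggregates
(TSA = TPS + TAS = SCS + BBS) hold to machine precision by construction.

## Burial classification against a Gly-X-Gly reference

A residue's burial is judged by its *relative* accessibility: side-chain
SASA divided by the mean side-chain SASA of the same residue type in an
unconstrained tripeptide context. The reference ensemble places residue X
between two glycines and samples 30 random conformers per type: φ uniform
on (−180°, 0°), ψ uniform on (−180°, 180°), side-chain χ uniform, ω fixed
at trans, with conformers rejected when any non-bonded atom pair falls
below 0.6 of the summed van der Waals radii. Uniform sampling over the
sterically allowed backbone region is a deliberate choice: the ensemble is
meant to represent an average unfolded context, not a rotamer-library
equilibrium, and clash rejection merely removes unphysical conformers.
Glycine, having no side chain, is referenced (and classified) by its
all-atom accessibility.

Ratios strictly above 0.5 are *surface*, strictly below 0.2 *nucleus*,
everything else — including the exact boundary values — *intermediate*.
Classification is scale-free (multiplying all areas and references by one
constant changes nothing) and monotone in exposure.

The packaged reference (`default_reference()`) was generated once by
`build_reference(n = 30, seed = 20220424)` under the default radii and is
shipped as TSV with a provenance header; regenerating with the same seed
reproduces it bit-identically, and users with different radii or probe
conventions should regenerate rather than reuse it.

The per-protein environment summary reports an *average total SASA*,
(nucleus + surface area) / denominator. Published tables of this quantity
are arithmetically ambiguous about the denominator — dividing by the full
protein length does not reproduce typical printed magnitudes — so both
readings are implemented: the default divides by the number of classified
(nucleus + surface) residues, `denominator = "length"` by the full length.
Neither is asserted against any published value.

## Sequence-level descriptors

`descriptors()` follows the ProtParam conventions exactly: average (not
monoisotopic) residue masses with one water per peptide bond; pI by
bisection on the Bjellqvist charge model (C-terminus 3.55,
residue-specific N-terminal pKa, D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0,
K 10.0, R 12.0) to |charge| < 1e-4; Ikai aliphatic index
100(f_A + 2.9 f_V + 3.9(f_I + f_L)); Kyte–Doolittle GRAVY. Every one of
these is a pure function of the amino-acid composition (plus the identity
of the first residue, for the N-terminal pKa term). That observation
carries the package's worked examples: for the eight lipases of the
motivating family only the per-residue compositions are shipped
(`lipase_compositions()`), and `lipase_sequences()` reconstructs synthetic
Met-initiated sequences realizing those exact counts — every
composition-level descriptor of the reconstruction equals that of the real
protein, while the residue *order* is explicitly synthetic and unsuitable
for order-sensitive analyses (secondary structure, structure building).

`cf_predict()` implements the classic Chou–Fasman procedure with the 1978
propensity tables: helix nucleation in hexapeptides with ≥ 4 residues of
Pα ≥ 1.00, sheet nucleation in pentapeptides with ≥ 3 of Pβ ≥ 1.00, both
extended while the trailing tetrapeptide keeps a mean propensity ≥ 1.00,
and turns where the bend-frequency product exceeds 7.5e-5 with the mean
turn propensity above 1.00 and above both competing means. Helix, sheet
and turn masks may overlap — the reporting convention of the classic
servers, whose percentage columns can sum past 100 — and a resolved
single-label track is provided secondarily (larger mean propensity wins,
turns always win). Predictions on real sequences should be read as
indicative only; the method is of historical accuracy (~50–60%).

## SCRs, fingerprints and clustering

Structurally conserved regions are defined on a user-supplied multiple
alignment: a column is conserved when gap-free in every sequence with
majority-residue frequency ≥ `min_conservation` (default 0.5), and maximal
conserved runs of ≥ `min_len` columns (default 5) become regions.
This column criterion replaces interactive structure-superposition tools
as a reproducible, printable rule; explicit intervals in a BED-like TSV
are accepted as an override, and the fingerprint itself — the ordered
vector of residue SASA values over SCR columns — is unchanged either way.
Fingerprint values use residue total SASA by default (side-chain-only is a
config alternative), and fingerprints across proteins of one SCR set
always have equal length, making them valid clustering observations.

Whole proteins of unequal length are instead represented by a
9-component summary vector (TPS, TAS, TSA, SCS, BBS, nucleus total,
surface total, average total SASA, residue count); z-scoring is optional
and off by default, since the components are all in comparable area units
except the count.

Clustering is agglomerative Ward on Euclidean distances, implemented via
the Lance–Williams recurrence on squared distances with merge heights
equal to √(2 × increase in within-cluster sum of squares) — the common
"ward.D2" dendrogram convention, pinned by tests against both an
exhaustive raw-point reference and `stats::hclust`. Ties are broken
toward the smallest cluster-index pair in creation order, making results
deterministic and input-order invariant up to that rule. Ward linkage is
reducible, so merge heights are provably non-decreasing; cophenetic
distances are ultrametric. Dendrograms serialize to Newick with midpoint
depths (node depth = height/2, as in standard hclust-to-phylo
conversion). Cophenetic similarity percentages use the transform
100(1 − h/h_root); published "overall similarity" percentages for such
dendrograms rarely state their transform, so this default is explicitly a
choice and is never compared against any published number.

## The synthetic-data generator

`build_peptide()` constructs peptides from internal coordinates with
standard backbone geometry (N–CA 1.458, CA–C 1.525, C–N 1.329 Å,
tetrahedral/trigonal angles, trans ω unless overridden) and idealized
side-chain templates for all 20 residues (fixed bond lengths/angles, χ
torsions settable, sampled, or defaulting to extended with aromatic χ2 at
90°). There is no rotamer library and no force-field relaxation: the
geometry is ideal, which is exactly what makes closed-form checks (helix
CA(i, i+3) spacing, Gly side-chain absence, clash-freedom) possible.

`make_family()` plants recoverable group structure: all groups share one
backbone template; groups differ by a ψ-shift (default 60° per group step)
and a handful of residue substitutions; members within a group differ only
by isotropic Gaussian coordinate jitter (default σ = 0.2 Å). Substitutions
(never indels) keep the ground-truth alignment trivially exact. Default
problem sizes — 3 groups × 3 members × 30 residues — keep a full pipeline
run in seconds while leaving the between-group SASA separation far above
the within-group jitter.

What passing tests on these families shows: the pipeline's stages compose
correctly, preserve the partition identities, and recover a planted
3-group structure exactly (adjusted Rand index 1.0) from both summary
vectors and SCR fingerprints. What it does not show: performance on real
homology models, whose errors are systematic (loop placement, side-chain
packing) rather than isotropic jitter, and whose conserved regions are
defined by structural superposition rather than by construction.

## Numerical choices and degenerate inputs

- Bisection for pI runs on [0, 14] to charge tolerance 1e-4 (reported to
  2 decimals); ties in Ward merging and points exactly on neighbor spheres
  are resolved deterministically as documented above.
- Coincident atoms are a hard error (naming both atoms); empty structures,
  ragged alignments, zero-variance fingerprints, unknown residue codes and
  multi-chain files without a chain selection all fail fast with the
  offending identifier.
- Gly-X-Gly conformer sampling retries clash-rejected conformers up to a
  bounded budget (200) before erroring; with the default thresholds the
  budget is never approached in practice.
- The whole-protein observation vector intentionally excludes per-residue
  detail so that proteins of different lengths remain comparable;
  fingerprints carry the per-residue signal where equal length is
  guaranteed.

## Known limitations

- Sampled SASA is an approximation; exact analytic surfaces
  (Gauss–Bonnet/power-diagram methods) are out of scope, and absolute
  areas depend on the radii set, which published tables rarely state.
- The Chou–Fasman tables and rules are reproduced faithfully but are not a
  modern secondary-structure predictor.
- Side-chain geometry is idealized; SASA references built from it are
  internally consistent but not interchangeable with references built from
  rotamer-library ensembles.
- Single chain per structure; mmCIF, NMR multi-model files and ligands are
  not handled.
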