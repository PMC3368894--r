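---
title: "Predicting protein-protein interaction sites from 3D probability density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interaction sites from 3D probability density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Protein-protein interfaces are physicochemically complementary: the core of
a binding patch is packed like a protein interior, hydrophobic and tight,
while its rim resembles the general polar surface.  `pdmppi` turns that
observation into a predictor.  The partner protein is unknown at prediction
time, so its contribution is *simulated*: contact statistics harvested from
the interiors of known structures are projected around the query protein as
three-dimensional probability density maps (PDMs), one per interacting atom
type.  Where a surface region looks like one side of a well-packed
interaction, the maps light up with plausible partner atoms.

The pipeline has five stages:

1. **Atom typing and SASA.**  Heavy atoms are grouped into 30 protein
   chemical types plus crystal-water oxygen (type 31), each with a van der
   Waals radius.  Solvent-accessible surface area is computed with a
   Shrake-Rupley spherical quadrature (960 deterministic Fibonacci points
   per atom, 1.4 Å probe).  Surface atoms are those with SASA > 0.  Ground
   truth for training compares the unbound and complexed forms:
   dSASA = (SASA_u − SASA_c)/SASA_u in [0, 1], and an atom is a PPI-site
   atom when dSASA > 0 (strictly; no minimum-area epsilon).

2. **Knowledge base.**  Non-covalent contacts (distance ≤ r_i + r_j + 1.4 Å;
   same-residue and 1-2/1-3/1-4 pairs excluded; type pairs screened by a
   31×31 interaction filter with admission rule value < −0.1) are expressed
   in a canonical local frame anchored on each atom's covalent neighbours
   and binned into per-(center type, partner type) histograms (1 Å cells,
   ±8 Å).  The local frames make the statistics exactly pose-invariant.

3. **PDM projection.**  Around a query, every surface atom's normalized
   canonical histograms are rigid-transformed by its frame and splatted
   (trilinear, mass-conserving) into global 1 Å grids; the accumulated maps
   are averaged over contributing atoms and zeroed inside the protein's van
   der Waals volume.

4. **32 attributes and classifiers.**  For each predictable surface atom
   (surface, types 1-30, complete phi/psi), attribute j ≤ 31 is the
   distance-weighted patch average (10 Å radius, linear taper) of 5 Å local
   sums of map j; attribute 32 is the unoccupied-space fraction of the
   10 Å sphere (local surface geometry).  Attributes are scaled to [0, 1]
   with dataset-level constants: the medians over training proteins of the
   per-protein extrema.  One bagged classifier is trained per protein atom
   type: 10 bags, each holding all positives plus 1.5× randomly drawn
   negatives (without replacement), each bag training either a 32-15-1
   sigmoid network (full-batch iRprop−, 1000 iterations, snapshot at the
   best validation MCC checked every 10 iterations) or an RBF SVM with
   cost/gamma grid search; member outputs are averaged with equal weight.

5. **Calibration, patches, residues.**  Validation activities are sorted
   into ten bins of width 0.1; each bin's confidence is its true-positive
   fraction (the conservation identity Σ confidence·count = positives holds
   exactly; empty bins are filled by linear interpolation, with linear
   extrapolation clipped to [0, 1] at the edges).  Atoms above the seed
   confidence cut act as cluster centres, collect surface atoms within
   11 Å above the member cut, and patches whose seeds come within 10 Å
   merge transitively.  A residue is called positive when strictly more
   than the conversion fraction of its surface atoms belong to a patch;
   actual sites apply the same rule to dSASA > 0 atoms.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| probe radius | 1.4 Å | water-sized SASA probe |
| contact tolerance | 1.4 Å | slack over the vdW sum in the contact rule |
| KB grid | 1 Å cells, ±8 Å | canonical histogram geometry |
| map grid | 1 Å cells, 10 Å margin | global PDM geometry (margin covers both feature spheres) |
| density radius | 5 Å | local sum of map values |
| patch radius | 10 Å | attribute aggregation and geometry sphere |
| bags / ratio | 10 / 1.5 | bagging against class imbalance |
| ANN | 32-15-1, 1000 iterations | fixed architecture, iRprop− (η+ 1.2, η− 0.5, Δ0 0.1, Δmax 50) |
| seed / member cut | 0.6 / 0.2 | patch seeding and growth confidence cuts |
| grow / merge radius | 11 Å / 10 Å | patch growth and seed merging |
| residue fraction | 30% | atom-to-residue conversion |

The seed cut, member cut and conversion fraction are *calibrated on the
validation proteins* (grid search maximizing validation residue MCC), which
is part of the training protocol: these published values are the defaults
and the starting point of the search, and exact ties keep them.  The growth
and merge radii stay fixed.

## Design choices where the method description is open

- **Contact rule.**  The knowledge-base contact criterion follows a simple
  distance rule, d ≤ r_i + r_j + 1.4 Å, with the rule recorded in the KB
  metadata so alternatives can be swapped in.
- **Eq-style feature forms.**  The local density sum is unweighted over
  cells within 5 Å; the patch weight is the linear taper w(d) = 1 − d/10
  normalized to a weighted mean.  Both are reconstructions of incompletely
  specified forms; quadratic and exponential tapers are available through
  the configuration and change desk-scale results by at most a few
  hundredths of MCC.
- **Local frames.**  Right-handed orthonormal frames from the sorted
  covalent neighbours; terminal atoms borrow their neighbour's second
  neighbour.  Determinism and exact pose-invariance of the histograms are
  tested properties.
- **Interaction filter.**  The published 31×31 filter is supplementary
  data that is not redistributed here; the package ships a clearly-labelled
  synthetic stand-in (`synthetic_filter_matrix()`,
  `inst/extdata/filter_matrix_synthetic.tsv`) built from chemistry rules
  in the spirit of the filter's purpose - keeping the maps low in noise
  from irrelevant interactions.  Side-chain carbon/sulfur packing,
  donor-acceptor hydrogen bonds and water-polar contacts are admitted;
  like-polarity and polar-apolar pairs are rejected; backbone carbons are
  treated as carriers of the flanking amide dipoles rather than as
  hydrophobic interactors.  Users with the published table can load it
  with `load_filter_matrix()`.
- **Ties and degeneracies.**  Threshold optimization breaks ties to the
  lowest threshold; SVM grid ties to the smallest cost then gamma;
  "greater than" cuts are strict; a single-class validation set falls back
  to the final ANN iteration (with a warning) and a 0.5 decision threshold;
  MCC with a zero denominator is 0.

## The synthetic world

Everything is testable offline through deterministic generators
(`generate_reference_set()`, `generate_toy_complex()`), which emulate the
aspects of real structures the pipeline actually consumes:

- chains are confined self-avoiding CA walks with idealized backbone
  geometry and two-sphere side chains (CB at 1.55 Å plus a distal
  representative atom at 3.1 Å, bent 25° like a side-chain chi angle), so
  typing, SASA, covalent topology, local frames and side-chain packing
  contacts all exercise the production code paths;
- reference globules carry spatially clustered hydrophobicity (a random
  hemisphere at 0.85 versus 0.15, with a buried-core bias), reproducing the
  hydrophobic-with-hydrophobic contact enrichment that knowledge-based
  statistics rely on;
- toy complexes dock two hemispherical "domes" face to face (closest
  clash-free pose over a small lateral-offset search, so the side-chain
  brushes interdigitate); the slab under the contact face draws hydrophobic
  residues at 0.95 versus 0.15 elsewhere - a strong planted signal with
  interface cores that resemble interiors, as in real complexes.

What the toys do *not* emulate: real rotamer chemistry, backbone hydrogen
bonding geometry, waters, crystallographic noise, evolutionary signal, or
the scale of curated training sets (hundreds of proteins).  Passing the
desk-scale tests therefore demonstrates that the pipeline's machinery is
correct and that a strong planted physicochemical signal is recoverable
end-to-end; it does not re-establish the published benchmarks on real
complexes.

## The end-to-end experiment

`end_to_end_scenario()` runs the complete study at desk scale: a knowledge
base from 48 reference globules (56 residues each), 20 training complexes
and 6 held-out test complexes (48 residues per chain), a train/validation
split that keeps whole complexes intact (30% of complexes held out for
thresholds, confidence tables and patch calibration), and pooled
residue-level benchmarking on the held-out complexes; `null_control = TRUE` retrains on label-shuffled data to verify
the result collapses to chance.  These sizes were chosen as the smallest
world in which every atom type common in the toys has hundreds of training
examples and the validation folds are large enough to calibrate confidence
tables; a run takes a few minutes on one CPU.  At this scale the residue
MCC against the pipeline's own dSASA truth lands near the published
residue-level performance of the method on real data (≈ 0.45-0.5 across
seeds and draws), with the label-shuffled null at ≈ 0.  Five-fold
cross-validation of the classifiers (and selection of the best-performing
fold) is available through `make_cv_folds()` and explicit validation
groups in `train_from_preps()`, but at desk scale shrinking the training
folds costs more than fold selection gains, so the scenario uses the
single complex-level split.

## Known limitations

- The filter matrix is a synthetic stand-in; absolute map values (and
  anything downstream of the exact admitted-pair set) will differ from the
  published pipeline.
- Per-protein baseline shifts of the attribute scales limit cross-protein
  transfer at desk scale; with hundreds of training proteins (as in the
  real study conditions) the classifiers average over these shifts.
- SVM ensembles keep LIBSVM state in-session (JSON persistence covers ANN
  bundles only), and the published cost/gamma grid is computationally heavy
  at full size; desk-scale work passes reduced grids.
- The mmCIF dialect, biological-unit reassembly and modified residues are
  out of scope; the user supplies the complexed form for labelling.
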