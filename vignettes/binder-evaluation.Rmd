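---
title: "Evaluating designed peptide binders: geometry, bind score, and campaign analytics"
author: "binderscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating designed peptide binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderscore)
```

## The problem

Modern binder-design pipelines generate candidate peptide or miniprotein
sequences against a chosen receptor interface (typically with an
inverse-folding model seeded by a backbone fragment), then predict each
candidate in complex with the receptor using an AlphaFold2-style
predictor. The design problem thereby becomes a *selection* problem:
out of thousands of predicted complexes, which designs are confidently
and correctly placed at the intended interface? `binderscore`
implements the evaluation layer of such a pipeline — interface
geometry, a composite bind score, backbone seed cropping, sequence-level
recovery metrics, and campaign-level selection statistics — together
with a synthetic complex generator so that every metric can be
exercised and verified without any structure downloads.

## Interface definition and geometry

Two residues on opposite chains are in contact when their *effective
beta carbons* — the CB atom, or CA for glycine, which has none — lie
within **8 Å** of each other; the comparison is inclusive (`<= 8`).
The interface of a complex is the projection of these contact pairs
onto each chain. The **contact density** of a binder (or of a seed
fragment) is the number of cross-chain contacts divided by the binder
length, in contacts per residue.

All comparative geometry is computed in the receptor frame: the
predicted receptor is superposed onto the reference receptor by a
least-squares (Kabsch) fit of CA atoms paired by residue number, with
reflections disallowed (the rotation determinant is constrained to +1,
so a mirror-image receptor fits poorly instead of silently inverting
chirality). Two quantities are then measured:

* **Interface RMSD** — the RMSD over the effective beta carbons of the
  binder residues belonging to the *native* interface, with native and
  predicted binder residues paired by sequence position (1..N within
  the chain). Designed sequences carry no meaningful author numbering,
  so positional pairing is the only consistent choice. A design is
  called **successful** when this RMSD is at most 2 Å. Only the
  binder's interface atoms enter the deviation set; the receptor
  enters through the superposition alone. (An alternative reading
  would include receptor interface CBs in the deviation set; since the
  quantity of interest is the *binder's* placement and the receptor is
  already the alignment frame, we measure the binder only.)
* **ΔCOM** — the distance between the CA centroids of the predicted
  binder and a reference binder (the seed where one exists, otherwise
  the native binder) in the receptor-aligned frame. We compute an
  unweighted CA centroid: the available descriptions of this term mix
  "centre of mass" with CA-only language, and the unweighted CA
  centroid is the minimal consistent reading. The choice is isolated
  in one function (`delta_com`) should a mass-weighted variant ever be
  needed.

## The bind score

Candidate designs are ranked by a single composite loss,

$$
\mathrm{Loss} \;=\; \mathrm{plDDT}_b^{-1}\cdot
\left(\frac{1}{m}\sum_{i=1}^{m} d_i \;+\;
\frac{1}{n}\sum_{j=1}^{n} d_j \cdot \tfrac{1}{2}\cdot \Delta COM\right)
$$

where $\mathrm{plDDT}_b$ is the mean per-residue predicted confidence
of the binder on the 0–100 scale, $d_i$ is the shortest distance from
each of the $m$ heavy atoms of the chosen receptor *target residues*
to any binder heavy atom, $d_j$ is the shortest distance from each of
the $n$ binder heavy atoms to any target heavy atom, and $\Delta COM$
is the displacement defined above. Hydrogens are excluded throughout.
Confident, tightly packed, on-target placements give a low loss; the
ΔCOM factor anchors the score to the intended side of the receptor,
since a binder on the mirror-image face can reproduce the distance
terms but not the centroid.

Two interpretive points deserve a note:

* **Grouping.** As printed, the ΔCOM·½ factor multiplies only the
  second (binder-to-target) mean, and that is how `compute_loss`
  assembles the score; the assembly lives in one internal function so
  the alternative grouping (ΔCOM scaling the whole parenthesis) would
  be a one-line change. With ΔCOM = 0 the two readings coincide.
* **Scale.** The selection cutoffs shipped as defaults (loss ≤ 0.11
  for one-shot selection at low false-positive rates; loss ≤ 1
  combined with binder plDDT ≥ 80 for convergence campaigns; success
  at interface RMSD ≤ 2 Å) assume plDDT on 0–100. For that reason the
  PDB reader *rejects* B-factor columns that look like 0–1 confidences
  rather than rescaling them: silent rescaling would shift every loss
  by two orders of magnitude.

When no reference binder exists at all (scoring a lone predicted
complex), the ΔCOM term cannot be formed; `compute_loss` then zeroes
the term and flags the breakdown with `delta_com = NA`. All threshold
comparisons in `select_binders` are inclusive.

## Seed cropping

Given a scaffold hit (e.g. from a Foldseek search, whose tabular output
`read_foldseek_hits` ingests) and a set of receptor target residues,
`best_crop` scans every contiguous window of length L ∈
{10, 20, 30, 40, 50} and keeps the window with the most CB contacts to
the target interface; ties break to the smallest start, and scaffolds
shorter than L are used whole. `rank_crops` orders crops across hits
and lengths by contact count, then contact density, then hit id (the
tie policy is ours; nothing in the workflow depends on it). Crops are
ranked per requested length; pooling across lengths is left to the
caller, since campaigns typically budget designs per length.
`build_design_input` assembles the inverse-folding input with the
receptor backbone first, a 10-position masked spacer, then the seed —
binder-first concatenation is avoided deliberately, because sequence
generators trained on single chains strongly prefer methionine at
position 1 of the leading block.

## Recovery metrics

Sequence identity is a poor measure of binder quality: a one-position
register shift can zero the identity while preserving every
interaction. Two metrics address this:

* **Contact recovery** groups amino acids into five physicochemical
  categories — Hydrophobic (A, F, I, L, M, P, V, W, Y), Small (G),
  Polar (N, C, Q, S, T), Positive (R, H, K), Negative (D, E) — and
  asks, for each receptor residue of the native interface, which
  categories of binder residue it contacts. Repeat contacts within a
  category collapse: a receptor position contacting A, F and R is
  annotated {Hydrophobic, Positive}. The recovery is the fraction of
  native annotations preserved at the same receptor position by the
  design. It is a recall: categories the design adds beyond the native
  set do not penalise it, because the metric measures preservation of
  native interactions, not parsimony. Non-standard residues ("X") are
  excluded from the annotation sets.
* **Interface sequence recovery** is plain positional identity
  restricted to the native binder interface positions.

`mutation_scan` generates the probe set used to test whether a
structure evaluator notices interface corruption: for each k in 1..L
(L = number of contact positions) it emits `per_count` (default 10)
sequences mutated at exactly k randomly chosen contact positions, each
substitution drawn uniformly from the 19 non-identical standard amino
acids. The scan is deterministic given its seed and leaves the
caller's RNG state untouched.

## Campaign analytics

`roc_auc` sweeps unique score values as thresholds (one curve vertex
per unique score, so tied scores are handled by the 0.5-credit
Mann–Whitney convention; the trapezoidal area equals the pairwise
formulation to machine precision). For loss-based selection, lower is
positive. `success_curve` reports, for each n, the fraction of targets
whose first n designs contain at least one success — non-decreasing in
n by construction. `density_success_profile` sorts designs by seed
contact density, splits them into 30 near-equal contiguous partitions
(remainder records are spread one-per-block over the leading blocks —
the exact remainder policy is unstated in the workflows this mirrors,
and no conclusion depends on it), and correlates per-block mean
density with per-block success rate by Spearman rank correlation
(mid-ranks for ties, via `stats::cor`). `interface_ss_fractions`
consumes precomputed secondary-structure labels (e.g. a DSSP run
reduced with `reduce_dssp`: H/G/I → Helix, E/B → Sheet, rest → Loop)
and tallies interface composition.

## The synthetic generator

`make_ideal_complex` builds a receptor and a binder as ideal
poly-alanine helices (1.5 Å rise, 100° twist per residue, CA radius
2.3 Å, CB pointing radially outward, plus plausible N/C/O backbone
records). The binder helix faces the receptor, and their separation is
tuned — coarse-to-fine scan over the separation, then over a small
axial shift — until the complex has *exactly* the requested number of
CB contacts at 8 Å. Counts that no separation can realise (contacts
appear in symmetric pairs at some geometries, so a few counts, e.g. 4
for the default lengths, are skipped over) raise an error rather than
an approximation. The "predicted" complex is the native one with the
binder rigidly displaced by a chosen vector and the whole complex
optionally rotated, so the fixture carries planted analytic truth:
interface RMSD and ΔCOM both equal the displacement magnitude, and
receptor superposition must absorb the rotation exactly. These planted
identities, together with brute-force oracles (exhaustive contact
enumeration, all-atom-pair loss evaluation, window scans), form the
backbone of the test suite.

`make_design_table` simulates a campaign result table: per-design
success is Bernoulli with probability proportional to seed contact
density (mean equal to `success_prob`), successful designs draw
interface RMSD uniformly in [0.2, 2] Å and failures in [2.3, 20] Å,
the loss is `0.05 * rmsd * exp(noise)` with log-normal noise
(`noise_sd`, default 0.1), and plDDT declines linearly with RMSD plus
Gaussian noise. With `noise_sd = 0` loss ordering equals RMSD ordering
and loss-based ROC selection is perfect — a useful degenerate check.

What the generator does **not** emulate: real side-chain packing,
loop/sheet binders (fixtures are helical), receptor flexibility,
predictor failure modes (plDDT values are assigned, not predicted),
and the heavy right tail of real RMSD distributions. Passing tests on
these fixtures therefore demonstrate that the *metrics and statistics
are computed correctly*, not that any design pipeline will reach a
particular success rate on real targets.

## Numerical choices and degenerate inputs

* Contact cutoff comparisons are inclusive at exactly 8 Å; selection
  thresholds are inclusive too (ties are selected).
* Glycine uses CA as its effective CB. No virtual CB is constructed:
  the same convention applies to native and designed structures, so
  the approximation cancels in every comparison.
* Alternate locations resolve to the highest-occupancy conformer, ties
  to the first encountered; hydrogens are kept in the atom table but
  excluded from every distance computation; residues missing all of
  N/CA/C are flagged in a per-structure report rather than dropped.
* Superposition requires at least 3 pairable CA atoms; `spearman_rho`
  refuses constant vectors and fewer than 3 points; ROC construction
  refuses single-class labels (the campaign driver downgrades this to
  a warning and skips the ROC step).
* Crop-window ties break to the smallest start index.

## Problem sizes used in the shipped analyses

The bundled acceptance analysis (`scripts/acceptance.R`) uses a
12-contact helix fixture for the geometry identities, a 2000-target
zero-shot campaign (one design per target, 1.9% mean success), and a
500-target convergence campaign (100 designs per target, per-design
success probability 6.7e-4 so that roughly 5–7% of targets reach a
success within 100 designs). These sizes give stable summary
statistics while keeping the whole analysis in well under a minute of
CPU; the statistics they feed are scale-free (AUCs, rates,
correlations), so larger tables change only the noise, not the
expected values.

## A worked run

```{r example, eval = FALSE}
fx <- make_ideal_complex(fixture_spec(n_contacts = 12,
                                      displacement = c(3, 4, 0)))
ifc <- contact_pairs(fx$native)
tr <- superpose_receptor(fx$native, fx$predicted)
compute_loss(fx$predicted, ifc$receptor_interface,
             reference_binder = binder_atoms(fx$native), frame = tr)
interface_rmsd(fx$native, fx$predicted, ifc)   # 5: the planted (3,4,0)

tab <- make_design_table(200, 25, 0.05, rng_seed = 42)
cmd_evaluate(tab)
```

## Limitations

The package evaluates and selects designs; it does not run structure
prediction, inverse folding, scaffold search or DSSP — it consumes
their outputs (PDB files with plDDT in the B-factor column, tabular
hit lists, precomputed secondary-structure labels). mmCIF input,
multi-model handling beyond model 1, hydrogen placement,
solvent-accessibility interface definitions and binding free-energy
estimation are out of scope.
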