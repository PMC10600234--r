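# binderscore

Evaluation and selection of designed peptide and miniprotein binders
from predicted receptor–binder complexes.

## What problem this solves

Binder-design pipelines produce thousands of candidate sequences per
receptor interface; each candidate is folded in complex with its
receptor by an AlphaFold2-style predictor, which stores a per-residue
confidence (plDDT, 0–100) in the B-factor column of its PDB output.
The bottleneck is selection: deciding which predicted complexes are
confidently and *correctly* placed at the intended interface.
`binderscore` provides that evaluation layer for structural
bioinformaticians running such campaigns:

- **Interface geometry** — contacts between effective beta carbons
  (CB, or CA for glycine) at an inclusive 8 Å cutoff; contact density;
  Kabsch superposition of receptors on CA atoms (proper rotations
  only); binder interface RMSD in the receptor frame; CA-centroid
  displacement (ΔCOM) against a seed or native reference.
- **The bind score** — the composite loss used to rank designs:

  ```
  Loss = plDDT_b^-1 * ( (1/m) Σ d_i  +  (1/n) Σ d_j * (1/2) * ΔCOM )
  ```

  with `d_i` the shortest distance from each heavy atom of the
  receptor target residues to any binder heavy atom (m atoms), `d_j`
  the reverse direction (n binder atoms), and `plDDT_b` the mean
  binder confidence. Low loss = confident, packed, on-target.
- **Seed search** — maximal-contact contiguous crops (lengths
  10–50) from scaffold hits, and assembly of the inverse-folding
  input in receptor → 10-residue mask → seed order.
- **Recovery metrics** — amino-acid-category contact recovery
  (Hydrophobic/Small/Polar/Positive/Negative), interface sequence
  recovery, and randomized mutation scans of interface positions.
- **Campaign analytics** — ROC/AUC selection of successful designs
  (success = interface RMSD ≤ 2 Å), success-rate convergence curves,
  on/off-target specificity summaries, contact-density success
  profiles, Spearman correlations, interface secondary-structure
  fractions.
- **Synthetic fixtures** — ideal-helix receptor–binder complexes with
  an exact requested contact count and planted displacement, plus
  simulated campaign tables, so the entire stack is testable offline.

## Worked example

```r
library(binderscore)

# a synthetic native complex with exactly 12 CB contacts, and a
# "predicted" complex whose binder is displaced by (3, 4, 0) A
fx  <- make_ideal_complex(fixture_spec(n_contacts = 12,
                                       displacement = c(3, 4, 0)))
ifc <- contact_pairs(fx$native)
ifc
#> interface (Cb cutoff 8.0 A): 12 contact pairs, 7 receptor / 6 binder residues

tr <- superpose_receptor(fx$native, fx$predicted)
compute_loss(fx$predicted, ifc$receptor_interface,
             reference_binder = binder_atoms(fx$native), frame = tr)
#> bind score: 0.4805
#>   binder plDDT            85.00
#>   target->binder distance 10.345 A (m = 35 atoms)
#>   binder->target distance 12.200 A (n = 75 atoms)
#>   delta-COM               5.000 A

interface_rmsd(fx$native, fx$predicted, ifc)
#> [1] 5
```

The interface RMSD and ΔCOM both recover the planted 5 Å displacement
(3-4-5 triangle); the bind score of 0.4805 decomposes into the mean
directed interface distances, the displacement penalty, and the
inverse-plDDT weight shown in the breakdown.

Campaign-level analysis of a simulated design table:

```r
tab <- make_design_table(200, 25, 0.05, rng_seed = 42)
cmd_evaluate(tab)
#> campaign: 5000 designs over 200 targets
#>   loss ROC AUC          0.9999
#>   loss-RMSD Spearman    0.981
#>   success rate (all n)  0.7750
#>   density-success rho   0.875
#>   selected designs      836
```

Here 5000 simulated designs are ranked by loss: the AUC near 1 says
the loss almost perfectly separates successful (≤ 2 Å) from failed
designs under the simulation's low-noise loss–RMSD coupling; 77.5% of
targets reach at least one success within their 25 designs; and 836
designs pass the default selection thresholds (loss ≤ 1, plDDT ≥ 80).

A thin command-line dispatcher over the same functions ships as
`inst/exec/binderscore` (subcommands `score`, `evaluate`, `roc`,
`specificity`, `recovery`, `mutate-scan`, `crop`, `simulate`).

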