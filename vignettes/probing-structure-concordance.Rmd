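---
title: "Quantifying concordance between DMS probing and 3D structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying concordance between DMS probing and 3D structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeconcord)
```

## The problem

Dimethyl sulfate (DMS) methylates the N1 of adenine and the N3 of
cytosine when the Watson-Crick-Franklin (WCF) face of the base is not
protected by pairing, hydrogen bonding or burial.  A per-nucleotide DMS
reactivity track measured *in vivo* is therefore an indirect readout of
the structure the RNA adopts in the cell.  Given an atomic coordinate
model of the same RNA — for instance a cryo-EM reconstruction of a
ribosomal subunit — one can ask how well the model explains the in-cell
reactivities: reactive positions should be solvent-accessible and free
of WCF-face hydrogen bonds, unreactive ones buried or paired.

`probeconcord` implements that comparison end to end:

1. per-atom solvent-accessible surface area (SASA) by the
   Shrake–Rupley method, reduced to the DMS-reactive nitrogen of every
   A and C;
2. hydrogen-bond detection on hydrogen-free models via a heteroatom
   (N/O) distance criterion, with counts per nucleotide both over all
   atoms and restricted to the WCF face (N6/N1/N3 of A, N4/N3/O2 of C
   — the sugar-edge N3 of adenosine is counted deliberately, since
   occupancy there also protects the base);
3. canonical WCF base-pair annotation and per-nucleotide
   paired/unpaired flags;
4. protein–RNA atom-contact counting at a distance cutoff;
5. ingestion of StructureFold-style `.react` tracks, averaging of
   replicate rRNA gene copies, between-condition differential
   reactivity, and a sequence-alignment-based map between probing
   coordinates and model numbering;
6. Pearson correlations and ROC/AUC analysis of reactivity against
   single and Boolean-combined structural binaries.

A seeded synthetic-data generator replaces the deposited structures and
tracks during testing, so every stage is verifiable against exactly
known ground truth without downloads.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | solvent probe for SASA |
| `n_points` | 400 | – | sphere samples per atom |
| vdW radii | C 1.70, N 1.55, O 1.52, P 1.80, S 1.80 | Å | single-radius element table; fallback 1.80 |
| H-bond window | 2.0–3.5 | Å | heteroatom (N/O) distance band |
| contact cutoff | 4.0 | Å | protein–RNA atom contacts |
| `sasa_cutoff` | 1.4 | Å² | "buried" boundary; strict (`< 1.4` is protected, equality accessible) |
| reactivity filter | 0.2 | – | low-reactivity filter, applied to base-pairing ROCs only |
| differential threshold | 0.5 | – | `|Δreactivity| ≥ 0.5` marks highly differential positions (inclusive) |

The vdW table is a configuration knob (`sasa_params()`): published
radius sets differ at the 0.01–0.1 Å level and shift absolute SASA
values slightly, which is why analyses should state the table used.
All of these constants are centralized in the pipeline run
configuration (`validate_config()`), which injects exactly the
defaults above when a field is omitted.

## Statistical model of the ROC analysis

Each nucleotide receives a binary structural label — *accessible*
(positive) or *protected* (negative) — from one of the rules

* `unpaired`: not a member of any canonical WCF pair;
* `sasa`: protected iff reactive-atom SASA `< 1.4` Å²;
* `hb (k)`: protected iff at least `k` WCF-face hydrogen bonds
  (`k` = 1, 2, 3);
* `combo OR/AND (k)`: the Boolean combination of the two.

Reactivity is swept as a decision threshold (a position is called
reactive when its score is at or above the threshold; tied scores are
grouped).  The area under the TPR-vs-FPR curve is computed by the
trapezoidal rule and equals the tie-corrected Mann–Whitney probability
`P(score_pos > score_neg) + P(tie)/2`, which the implementation also
returns and the tests verify to 1e-12 against an exhaustive pairwise
count.  An AUC of 1 means the structural binary orders reactivities
perfectly; 0.5 means it carries no information.  Because normalized
reactivity tracks contain many exact zeros, the base-pairing ROC
optionally discards scores below 0.2 first — many unreactive-but-
unpaired positions otherwise flood the false negatives; the filter is
not applied to SASA or H-bond rules by default.

A grid cell whose labelling is one-class under a rule (for instance no
adenosine reaching three face bonds) has no defined AUC; the grid
reports `NA` there while the single-curve constructor treats it as an
error.

## The synthetic generator

`build_aform_model()` constructs idealized helical RNA from fixed
constants: rise 2.81 Å and twist 32.7° per step, the standard values
for A-form RNA.  Base geometry is schematic — regular-polygon rings
with exocyclic heteroatoms at canonical bond lengths — arranged so the
WCF chemistry is exact: every A–U pair contributes precisely its two
canonical hydrogen bonds (N1···N3, N6···O4), every G–C pair its three,
all within the 2.0–3.5 Å window, with C1'–C1' distances inside the
10.4 ± 1.5 Å pairing window.

Two deliberate departures from physical helices keep the ground truth
exact:

* **The helix axis is displaced away from the pair.**  A flat-base
  helix with 2.81 Å rise places stacked heteroatoms of consecutive
  steps within the hydrogen-bond window no matter how the axis is
  chosen near the pair (we verified this by exhaustive search), which
  would contaminate the face-bond counts.  With the axis displaced,
  the minimum inter-residue non-bonded N/O distance in any generated
  model is 3.75 Å, so the detected bond set equals the designed one
  atom for atom.
* **The sugar is a carbon cage, with no phosphodiester backbone.**
  Because the displaced axis removes stacking occlusion, each
  nucleotide carries two "cap" carbons sandwiching its base face;
  they bury the reactive nitrogen of paired bases (SASA 0 Å², well
  below the 1.4 Å² cutoff) while unpaired bases expose it at 4–9 Å².
  Phosphate oxygens are omitted entirely: at this geometry they would
  sit within the H-bond window of neighbouring base faces and break
  the exact inventory.

Unpaired positions inside a duplex are produced by *omitting the
partner nucleotide* (a bulge).  This achieves everything a flipped-out
base provides for the analysis — unpaired status, zero face bonds,
solvent exposure — without introducing clashes.  Hairpin loops and
decoy protein chains (compact alanine-like clusters placed at a
controlled distance from a chosen nucleotide, from the locally most
open direction) complete the fixture vocabulary.

Reactivity is simulated per A/C nucleotide as

```
mu    = max(0, baseline + sasa_coeff * SASA - face_hb_coeff * n_face_hbonds)
value = mu * exp(eps),   eps ~ Normal(0, noise_sd^2)
```

with replicate gene-copy tracks sharing `mu` and drawing independent
noise, values dropped to missing with probability `missing_rate`, and
G/U positions always missing.  The multiplicative log-normal noise
reflects that probing reactivities are non-negative and right-skewed
and that upstream normalization operates on a log scale.  The default
study conditions are a 540-bp duplex with 80 bulges (1000 nucleotides),
`baseline` 0.1, `sasa_coeff` 0.05 Å⁻², `face_hb_coeff` 0.3 per bond,
`noise_sd` 0.5, `missing_rate` 0.05, three gene copies, seed 7.

Under those coefficients every protected base hits the `max(0, ·)`
floor exactly (0.1 − 2·0.3 < 0), so the synthetic score distributions
of accessible and protected classes separate completely and every
well-defined rule attains AUC 1.0 — which the analytically expected
AUC of the generative model also gives, so the acceptance comparison
is exact but saturated.  A non-saturated regime (baseline 0.3, H-bond
coefficient 0.05, expected AUCs ≈ 0.93–0.97) is exercised separately
in the test suite to confirm the empirical AUC tracks the analytic
value away from the boundary.

What passing on synthetic data does **not** show: the generator has no
sequence-context biases, no tertiary contacts (so no adenosine ever
carries three face bonds), no partially-buried intermediates, no
correlated noise between copies, and its geometry is schematic.
Agreement on real deposited models and tracks depends additionally on
the vdW radius table and on how the pairing annotation approximates a
full-featured annotator; the published correlations for the archaeal
ribosome this kind of analysis targets are of the order r ≈ 0.4 (SASA)
and r ≈ −0.2 (H-bonds) with maximal combinatorial AUCs ≈ 0.75, far
from the clean-separation regime.

## Numerical choices

* **Sphere sampling** uses a deterministic Fibonacci (golden-spiral)
  lattice — no RNG, so areas are bit-stable across runs.  Coordinates
  are first expressed in the molecule's principal-axes frame with a
  deterministic sign convention; the lattice therefore co-rotates with
  the molecule and areas are invariant under rigid motion of the
  input, not merely under translation.
* **Neighbour search** for SASA, hydrogen bonds and contacts uses a
  uniform spatial grid with cell size at least the query cutoff; the
  tests assert exact agreement with all-pairs scans.
* **Superposition** is the standard SVD construction with a
  determinant guard against reflections; collinear or short (< 3 atom
  pairs) selections are errors.
* **Alignment** for the numbering map is global Needleman–Wunsch
  (match +1, mismatch −1, gap −2; T ≡ U) via Biostrings; mappings
  below 80% identity are refused since they almost always indicate
  the wrong chain was selected.
* **Averaging across gene copies** takes the mean of present values
  and yields missing only where every copy is missing, keeping
  coverage high.
* **Differential sign convention**: `delta = condition_a −
  condition_b` (first listed condition minus second, e.g. methanol −
  acetate); only `|delta|` feeds the selection rule, and the
  inclusive `≥ 0.5` reading is used.
* **Altloc resolution** keeps the highest-occupancy conformer (ties:
  altloc identifier order); hydrogens are dropped on load; multi-model
  files contribute model 1.
* **Waters and free ions** neither occlude solvent accessibility nor
  donate hydrogen bonds by default; both choices are toggleable.

## Problem sizes

The shipped tests run the full stack on duplexes of 8–540 base pairs
(up to 1000 nucleotides, ~13k atoms) and exercise the SASA kernel once
on a ~150k-atom model — the size of a complete large ribosomal
subunit — which completes in well under a minute on a single CPU.

## Known limitations

* The hydrogen-bond criterion is purely distance-based; no
  donor/acceptor chemistry or angular term is applied by default, so
  close N/O vdW contacts count as bonds.  This approximates, but does
  not reproduce, annotators that drop "questionable" bonds.
* Base pairs are classified canonical only for A–U and G–C; G·U
  wobbles are reported as class `other` and count as unpaired in the
  derived flags.
* No SES (molecular surface), no per-residue relative accessibility,
  no Leontis–Westhof edge taxonomy, no stacking annotation.
* AUCs carry no confidence intervals; the package reports the point
  estimates the analysis calls for.

## A worked run

```{r example, eval = FALSE}
spec  <- synthetic_spec(duplex_length = 60, n_bulges = 10, seed = 7)
model <- synthetic_model(spec)
sasa  <- shrake_rupley(model)
bonds <- detect_hbonds(model)
pairs <- annotate_base_pairs(model, bonds)
sim   <- simulate_reactivity(model, "A", sasa, bonds, spec)
avg   <- average_gene_copies(sim$tracks, names(sim$tracks))
cs    <- chain_sequence(model, "A")
map   <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
ft    <- build_feature_table(model, sasa, bonds, pairs, map, avg)
probe_concordance(ft, filter_below = NULL)
```

For file-based work, `write_fixtures()` emits the same study as PDB +
`.react` + truth TSV, and `run_pipeline()` drives everything from a
JSON configuration, writing feature tables, the ROC grid (TSV + JSON
curves), correlations, differential records and contact tables, each
with a provenance header.
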