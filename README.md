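# probeconcord

Quantifying how well a 3D coordinate model of an RNA–protein complex
explains *in vivo* chemical probing data.

Dimethyl sulfate (DMS) methylates N1 of adenine and N3 of cytosine
when the Watson–Crick–Franklin (WCF) face of the base is unprotected,
so a per-nucleotide DMS reactivity track is an in-cell readout of base
accessibility.  Given an atomic model of the same RNA — e.g. a cryo-EM
reconstruction of a ribosomal subunit — `probeconcord` extracts the
structural features that should govern protection and measures their
agreement with the measured reactivities.  It is aimed at structural
biologists and RNA biochemists who have both a deposited model and
StructureFold-style `.react` probing tracks for the same molecule.

## What it computes

For every A and C nucleotide:

* **SASA** of the DMS-reactive nitrogen (N1/N3) by the Shrake–Rupley
  rolling-ball method (probe 1.4 Å, 400 deterministic lattice points
  per atom, single-radius vdW table C 1.70 / N 1.55 / O 1.52 / P 1.80 /
  S 1.80 Å);
* **hydrogen bonds** on hydrogen-free models as N/O heteroatom pairs at
  2.0–3.5 Å, counted over all atoms and restricted to the WCF face
  (N6, N1, N3 of A; N4, N3, O2 of C);
* **canonical base pairing** (A–U, G–C with ≥ 2 WCF-edge bonds and
  C1′–C1′ within 10.4 ± 1.5 Å) and the derived paired/unpaired flag;
* **protein–RNA contacts**: atom pairs within 4.0 Å per protein chain;
* **reactivity**: gene-copy-averaged tracks, between-condition
  differential reactivity with the |Δ| ≥ 0.5 selection rule, and an
  alignment-based map between probing coordinates and model numbering.

Agreement is quantified by Pearson correlations (reactivity vs SASA,
reactivity vs H-bond count) and by ROC/AUC of reactivity against
structural binaries — unpaired, SASA < 1.4 Å², ≥ k face H-bonds, and
their OR/AND combinations — where AUC is the probability that a random
accessible nucleotide out-reacts a random protected one (trapezoidal
area; identical to the tie-corrected Mann–Whitney statistic).

A seeded synthetic-data generator (`synthetic_spec()`,
`build_aform_model()`, `simulate_reactivity()`, `write_fixtures()`)
builds idealized A-form duplexes/hairpins with exactly known ground
truth plus simulated tracks, so the entire pipeline is testable with
no downloads.  `run_pipeline()` drives everything from a JSON
configuration and writes a reproducible artifact bundle.

## Worked example

```r
library(probeconcord)
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

```
probe_concordance over 24 nucleotides with reactivity
  r(reactivity, SASA)      = +0.981
  r(reactivity, H-bonds)   = -0.896
  AUC grid:
    unpaired               A  AUC 1.000  (1+/8-)
    sasa<1.4               A  AUC 1.000  (1+/8-)
    hb>=1                  A  AUC 1.000  (1+/8-)
    ...
```

The correlations say what the generative model built in: reactivity
rises with solvent accessibility and falls with hydrogen bonding.  The
AUC grid scores each structural binary as a classifier of reactivity;
on this idealized geometry accessible and protected bases separate
completely, so every well-defined rule reaches 1.0 (cells whose
labelling is one-class report `NA`).  On real deposited models the
same grid lands well below 1 — that distance from perfection is the
biological signal the analysis is after.  Bulged positions simulate
unpaired, exposed bases; `n_bulges = 10` of the 60 stem positions are
unpaired here, and the positive/negative counts per base reflect the
A/C content among them.

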