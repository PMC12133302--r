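---
title: "Structure-based beta-sheet preference profiles and predictor agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based beta-sheet preference profiles and predictor agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilbeta)
```

## The problem

Amyloid fibrils are polymorphic: the same polypeptide — the amyloid-beta
peptide, alpha-synuclein, a tau isoform — deposits in the PDB as dozens of
distinct fibril structures whose cross-beta cores recruit different
stretches of the sequence. Any single structure therefore under-determines
which residues "prefer" the beta core. `fibrilbeta` treats the ensemble of
deposited polymorphs as the object of study. For every residue $n$ it
computes

$$F_\beta(n) = 100 \times
  \frac{\sum_{\text{entries covering } n} f_e(n)}{\#\{\text{entries
  covering } n\}},$$

where $f_e(n)$ is the fraction of the molecules of entry $e$ that place
residue $n$ in a beta strand. Two normalisations matter and both are
implemented exactly as stated by their worked examples:

* **molecule weighting** — an entry whose two conformers disagree at a
  residue contributes 0.5, not 1 or 0 (`entry_fraction()`);
* **coverage weighting** — a residue absent from an entry's construct
  (e.g. residues 41–42 of a 40-residue construct) is excluded from that
  residue's denominator, not scored 0 (`compute_profile()`).

The profile is smoothed over a sliding window (default 7 residues, the
conventional width for aggregation-propensity profiles), high-preference
segments are read off at a percent threshold, and the agreement between
those segments and sequence-based aggregation hot spots is quantified with
a contingency table, Cohen's kappa and a one-tail Fisher's exact test.

## From structures to annotations

Two ingestion routes produce the same per-molecule binary annotation
(`beta_annotation`):

1. **Curated intervals** (`load_strand_annotation()`): a TSV of 1-based
   inclusive strand intervals per molecule. This is the authoritative,
   data-driven route for reproducing published analyses, because published
   strand boundaries are curated calls, not raw dihedral output.
2. **Coordinates** (`parse_structure()` → `compute_dihedrals()` →
   `assign_beta()`): backbone-only parsing of PDB/mmCIF (first model),
   $\phi,\psi$ from the standard four-atom torsions, and a purely
   dihedral-based call — a residue is beta when both angles are defined
   and fall in the configured Ramachandran beta region. No
   hydrogen-bonding (DSSP-style) criterion is used, by design.

The default beta region is the extended basin
$\phi \in [-180°, -45°]$, $\psi \in [45°, 180°] \cup [-180°, -150°]$,
the second psi range wrapping the upper-left basin across $\psi = 180°$.
Published strand boundaries were curated against rendered Ramachandran
plots whose exact polygon is not stated; the rectangle set is therefore
fully configurable, and the interval-ingestion route bypasses it entirely.
Residues present in the construct but unresolved count as non-beta and
stay in the coverage range (the disordered fuzzy coat is part of the
molecule); whether they should instead leave the denominator is an open
question of the source analysis — we chose the reading consistent with
its only worked normalisation.

Two post-processing rules mirror the curation conventions:

* **Bridging** (`apply_bridging_rule()`): glycine-rich positions with
  high backbone freedom (Aβ Gly37–Gly38; αS Gly67–Gly68, Gly84–Ala85–
  Gly86) are promoted to beta exactly when the next residue is beta.
  Promotion cascades right-to-left, so Gly37 can be promoted through an
  already-promoted Gly38 — "aligned with the strand that starts at
  Val39" implies contiguity with the downstream strand.
* **Strand-length filtering** (`filter_strand_length()`): maximal beta
  runs shorter than $L_\beta^{min}$ are erased; the analysis is run at
  $L_\beta \ge 1$ and $L_\beta \ge 4$.

The order is fixed as assign → bridge → filter: a bridged residue must be
able to rescue a 3-residue run to the length-4 threshold.

## Agreement statistics

For masks $t$ (theory/prediction) and $e$ (experiment) over $l$ residues,
the four-class counts $\beta_{te}, \beta_{t\varnothing},
\beta_{\varnothing e}, \beta_{\varnothing\varnothing}$ sum to $l$, and

$$\kappa = \frac{2(\beta_{te}\beta_{\varnothing\varnothing} -
  \beta_{t\varnothing}\beta_{\varnothing e})}
  {(\beta_{te}+\beta_{t\varnothing})(\beta_{t\varnothing}+
   \beta_{\varnothing\varnothing}) + (\beta_{te}+\beta_{\varnothing e})
   (\beta_{\varnothing e}+\beta_{\varnothing\varnothing})}.$$

Degenerate tables (both masks all-true or all-false) have a vanishing
denominator; kappa is reported `NA`, never coerced to 0. The one-tail
Fisher P sums the hypergeometric point probability of the observed table
with those of every fixed-margin table of higher agreement; with margins
fixed, "larger $\beta_{te}$" and "larger
$\beta_{\varnothing\varnothing}$" coincide, so this is the standard
one-sided tail, computed in log-factorial space (exact to $l$ of a few
thousand; no continuity correction). Labels follow the conventional
bands: significance `*`/`**`/`***` at 0.05/0.01/0.001 and kappa classes
scarce/fair/good/very good/extremely good on right-closed 0.2-wide bins,
with $\kappa \le 0$ labelled `none`.

```{r kappa-example}
l <- 42
pred <- segments_to_mask(builtin_segments("abeta42", "zyggregator"), l)
expe <- segments_to_mask(builtin_segments("abeta42", "experimental_lb4"), l)
agreement(pred, expe)
```

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `lbeta_min` | 1 and 4 | residues | the two published strand-length regimes |
| window `w` | 7 | residues | conventional aggregation-profile window |
| threshold | Aβ 55/40, αS 70/60, tau 70/60 (L≥1 / L≥4) | % | the cut-offs at which the published peaks were read |
| comparison | `>=` | — | the L≥4 thresholds that anchor the kappa targets are printed inclusively; configurable because the source mixes strict and inclusive forms |
| beta region | $\phi\in[-180,-45]$, $\psi\in[45,180]\cup[-180,-150]$ | degrees | canonical extended basin; configurable |
| chain-break tolerance | 2.5 | Å | generous peptide-bond C–N cut-off |

Predictor decision rules are encoded once in `predictor_rule()`:
ZYGGREGATOR $Z^{prof}_{agg} \ge 1$ (the source prints both $\ge$ and $>$;
we use $\ge$), AGGRESCAN runs of $\ge 5$ residues with $a4v \ge 0$ and no
proline, TANGO score $> 0$, WALTZ score $\ge 75$ (high-sensitivity
setting), PASTA $-\Delta G_{agg} > 5$ energy units. The predictors
themselves are never recomputed: their published hot-spot intervals ship
as fixtures (`builtin_segments()`), and arbitrary score tracks can be
thresholded with `load_track()` + `threshold_track()`.

## What the synthetic generator emulates — and what it does not

`generate_ensemble()` produces a database with the statistical shape the
analysis assumes: `n_entries` structures of a length-`l` protein, planted
true-core segments, molecule counts drawn from a 1/2/3 distribution
(default 22:7:1 over 30 entries, the amyloid-beta ensemble's split),
i.i.d. per-residue flip noise (default 0.05), and an optional C-terminal
truncation model emulating 40- vs 42-residue constructs. Expectations are
exact: a planted residue's raw profile value is $100(1-\text{noise})$ in
expectation, a background residue's $100\,\text{noise}$.

It deliberately does **not** model spatially correlated noise, fibril
packing, protofilament symmetry or side chains. A green recovery test
therefore establishes that the pipeline's bookkeeping (fractions,
denominators, thresholds, run filtering) is correct under the stated
noise model — it says nothing about curation quality of real strand
calls, which enter through the annotation fixtures instead.

`build_coordinates()` realises an annotation as an ideal backbone
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, standard angles, trans peptide
bonds) by sequential internal-coordinate placement, choosing $(\phi,\psi)$
per residue from the beta/coil angle map (defaults $(-120°, 135°)$ /
$(-60°, -45°)$), with optional uniform jitter. One numerical subtlety:
terminal residues have an undefined $\phi$ or $\psi$ and by contract can
never be called beta from coordinates, so the builder pads one coil
residue beyond each coverage end by default (`pad_termini`); the leading
pad is skipped when coverage starts at residue 1, making a planted strand
at residue 1 the one case the coordinate route cannot round-trip.

```{r roundtrip}
ann <- beta_annotation("demo", 1L, c(1L, 42L),
                       segments_to_mask(segment_set(c(12, 31), c(21, 42)), 42))
pdb <- tempfile(fileext = ".pdb")
build_coordinates(ann, file = pdb)
annotation_segments(attr(parse_structure(pdb, lbeta_min = 4)[[1]],
                         "beta_annotation"))
```

## Numerical and design choices

* **Window truncation**: terminal windows shrink rather than zero-pad;
  padding would bias terminal residues downward.
* **Segment normalisation**: `segment_set()` sorts and merges overlapping
  *and adjacent* intervals, giving every residue set one canonical
  representation so mask/segment round-trips are exact.
* **Chain collapsing**: without an explicit chain map, chains of one file
  collapse when their final beta annotations are identical (fibril layers
  are stacked copies); distinct patterns become distinct molecules. The
  representative chain is chosen by chain-id order, so results do not
  depend on record order in the file.
* **Per-structure masks**: elements with partial coverage score their
  uncovered residues as non-beta over the full length $l$; restricting
  $l$ to the covered range is a documented alternative reading of the
  source and can be emulated by slicing masks before `agreement()`.
* **Kappa precision**: pipeline reports round kappa to 3 decimals for
  display; the statistics functions themselves never round.
* **Smoothed vs raw extraction**: peaks are read from the smoothed
  profile by default (published peaks were read off plotted,
  window-averaged profiles); synthetic plateau recovery uses the raw
  profile because smoothing a noise-free plateau deliberately blurs its
  edges across any threshold below 100%.

## Known limitations

* The dihedral route assigns no beta state to residues flanking chain
  breaks or termini; curated interval input is authoritative where
  published boundaries disagree with a raw dihedral reading.
* mmCIF support covers the `atom_site` loop with whitespace-delimited
  rows — sufficient for deposited coordinate files, not a general STAR
  parser.
* Tau predictor hot-spot intervals are not bundled (they were never
  published as intervals); the tau path is exercised by property tests
  and its experimental peaks only.
* The one-tail exact test is computed by full-support summation, which is
  exact but not optimised for $l \gg 10^4$.
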