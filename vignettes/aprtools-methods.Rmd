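---
title: "Methods: aggregation prone region analysis with aprtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregation prone region analysis with aprtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aprtools)
```

## The scientific problem

Short sequence stretches able to nucleate cross-β aggregation — aggregation
prone regions (APRs) — are unavoidable in natural proteins because the same
hydrophobic, β-prone residues that drive folding also drive aggregation.
`aprtools` implements a family of statistics used to characterize how
evolution manages this liability: composition-matched and scrambled null
sequence datasets, gate-keeper residue profiling around APRs, conservation of
APRs in homologue families, the association between APRs and structural
order, burial and solvent-isolatedness of APRs in 3D structures, and a
permutation (decoy) test for the structural proximity of catalytic residues
to APRs. Every stage can run on synthetic data with known ground truth, so
the full pipeline is testable without external databases or predictors.

APRs enter the package as interval annotations (`seq_id`, `start`, `end`,
`source`, `score`; 1-based inclusive, minimum length 6). Dedicated predictors
(TANGO, WALTZ) are deliberately out of scope; a transparent surrogate
predictor is provided for synthetic closed-loop tests only.

## Sequence null models

* **Uniform null** — every residue drawn at 5%; the maximally patternless
  reference (`generate_uniform_random()`).
* **Composition-matched null** — residues drawn i.i.d. from a reference
  composition (`reference_composition()` ships the composition of a
  495-protein folded corpus and a 536-protein disordered corpus as printed;
  the disordered set's percentages sum to 100.1 due to rounding, so the
  vectors are renormalized).
* **Scrambled null** — `scramble_sequence()` implements the rejection
  algorithm in which randomly chosen parent residues are assigned to randomly
  chosen unoccupied positions, retrying on collisions. This preserves each
  parent's length and residue multiset exactly while destroying patterning;
  property tests confirm it behaves as a uniform permutation generator.

Compositions are compared with a goodness-of-fit chi-square after converting
both profiles to counts per 1000 residues
(`composition_chi_square()`). This convention is the one under which the
folded-corpus composition against the uniform 5% profile gives 160.84; the
statistic is intentionally asymmetric (the second argument is the reference),
and categories with zero expected and zero observed frequency are dropped.

Two-sample comparisons of aggregation-propensity distributions default to
Welch's unequal-variance t-test; the pooled-variance variant is available via
`var_equal = TRUE` and the choice is part of the recorded output.

## Sequence-level APR statistics

The aggregation propensity of a sequence is its total aggregation score
divided by its length; the APR proportion is the percentage of residues
covered by (non-overlapping) APRs. Gate-keeper residues (Asp, Glu, Lys, Arg,
Pro) are counted at the three positions preceding and succeeding each APR.
Two conventions required a decision where the field's usage is silent:

* the frequency denominator at each flank position counts only APRs for which
  that position exists (termini-truncated flanks are excluded from the
  denominator), and
* a residue flanking two adjacent APRs is counted once per APR
  (independent per-APR counting).

## Conservation in homologue families

Alignments are row sets of equal aligned length with the parent first.
Identity between rows is column identity over mutually non-gap positions —
not an alignment score — and `filter_homologues()` applies the two
conventional cuts (minimum identity to the parent; removal of rows identical
to it). For conservation, each parent APR is projected through the parent's
aligned columns into every row; an APR instance is conserved between two rows
when the extracted subsequences are identical. With `n_total` = #APRs x
#rows and `n_uniq` = the summed number of distinct variants,

conservation % = 100 (n_total − n_uniq) / n_total.

This algebra is an adopted interpretation of the variable definitions (the
original formula block is only available as a figure); it yields 0 when every
row differs at every APR and approaches 100 for large perfectly conserved
families, and `100 (M − 1) / M` for an `M`-row family with identical
variants. Homologue APRs are located positionally via the parent's columns,
never by substring search elsewhere.

## Order/disorder contingency analysis

Residues are classified once each by APR membership and disorder state
(residues not covered by a disorder interval are assumed ordered). The odds
ratio defaults to the ordered orientation,
`(in_ord/out_ord) / (in_dis/out_dis)`, with the reciprocal available.
Independence is tested with Pearson's chi-square plus an exact test; for
tables above 1e5 residues the exact hypergeometric tail is numerically
degenerate and the chi-square p-value is reported with the method named.
Annotations extending beyond a sequence are a hard error (data integrity);
overlapping disorder intervals are merged with a warning.

## Solvent accessible surface area and burial metrics

SASA uses the Shrake–Rupley construction: each atom's solvent-expanded
sphere (Bondi van der Waals radius + probe, default probe 1.4 Å) is sampled
with a deterministic Fibonacci spiral of 960 points; a point is accessible
if outside every other expanded sphere. An isolated atom therefore recovers
4π(r + probe)² exactly, and doubling the point count moves residue ASA by
under 2% on the test structures. Hydrogens are never retained; heteroatoms
are excluded as occluders by default (`include_het = TRUE` to keep them);
unknown elements are an error unless a fallback radius is supplied.

For a segment (an APR mapped onto a chain), `segment_metrics()` reports the
observed in-context SASA, the expected SASA from dataset-average per-type
values, the total surface of the segment's atoms alone in the identical
conformation, and the derived quantities: percent solvent accessibility,
burial preference (observed/expected; < 1 = more buried than composition
predicts), the surface buried by the rest of the protein, and solvent
isolatedness Iso = buried/total. Iso + SolvAcc/100 = 1 holds identically and
is asserted for every segment in the tests. `iso_zscore_riso()` standardizes
a segment's Iso against all equal-length windows of its protein (one-residue
steps, windows restricted to runs of consecutively numbered residues with
coordinates, the segment's own window included — the inclusive convention was
adopted where the source prose is ambiguous).

## Catalytic proximity and the decoy null

The incidence of catalytic residues inside APRs and their 3-residue flanks is
estimated as `n_cata * n_apr_residues / n_total`, with flank residues counted
as a union (no double counting). Structural contact uses a 4.5 Å heavy-atom
cutoff by default (3.5 and 6.0 Å are common alternatives; contact counts are
necessarily monotone in the cutoff). A catalytic residue lying inside an APR
is flagged and excluded from contact counts, and a residue's own atoms never
count as its contact partners.

The decoy null replaces each true site with a residue drawn uniformly from
the standard residues of the same chain — self and other catalytic residues
included, the most literal reading of "any residue within the same
structure"; `exclude_self`, `exclude_catalytic` and `whole_structure` expose
the alternatives. With `asa_match`, candidates are restricted to residues
whose ASA is within the stated fraction of the true site's. The default of
10,000 lists (scaled down from the original million) gives the null mean a
relative Monte-Carlo error well below the effect sizes of interest; on toy
chains the null mean matches exhaustive enumeration, and sites drawn by the
decoy procedure itself give |Z| < 4.

## Disruption ranking

`rank_disruption_candidates()` encodes the four-branch solubility-engineering
rule: a buried APR (Iso above its protein's window mean, i.e. Z > 0 — chosen
because the Z-score is the analysis's own significance device and no numeric
Iso cutoff is published) is never disrupted; an exposed APR with no
functional contact is a priority target when weakly conserved and needs an
allostery check first when strongly conserved; an exposed, weakly conserved
APR in functional contact may be disrupted only with modelling support; and
missing evidence yields `insufficient_evidence`. The verdict is a total
function of the three flags, tested over all eight combinations.

## The synthetic generators: what they emulate, and what they do not

* `make_sequences_with_aprs()` — background from the folded-corpus
  composition; APR windows filled with β-branched/aromatic hydrophobics
  (V/I/L/F); controlled flank positions carry gate-keepers at exactly the
  stated rate. Emulates composition and planted-motif structure, not the
  score distributions of real predictors.
* `make_disorder_corpus()` — per-residue disorder drawn with probabilities
  solved (via `uniroot`) so the expected table attains a target odds ratio at
  a target coverage (default 0.261, the disordered-corpus background). At
  200k residues a planted odds ratio of 3 is recovered within roughly ±6%
  (≈95% of seeds in [2.8, 3.2]). Real disorder is autocorrelated along the
  chain; the generator's independence assumption only affects interval
  lengths, not the expected table.
* `make_toy_structure()` — deterministic analytic geometry (α-helical Cα coil
  + extended tail) so the core-vs-tail isolatedness ordering is a property of
  the construction, not of sampling. Cα-only models understate absolute ASA;
  all assertions on them are ordinal or algebraic.
* `make_alignment_family()` — per-column substitutions at rate `r_in` inside
  and `r_out` outside APR columns, gap-free. Defaults (0.01 / 0.25) emulate
  the distant-homologue regime in which APR columns are under purifying
  constraint, so measured APR conservation exceeds mean identity — the
  signature the conservation analysis is designed to detect. The emitted
  expectation uses the large-alphabet approximation that mutated variants are
  pairwise distinct (exact at `r_in = 0`).
* `make_catalytic_scenario()` — a planar Cα lattice (3.8 Å in-row, 4.0 Å
  between rows) in which the contact-eligible residue set is provable from
  geometry: row-2 residues above the APR and the two in-row flanks are within
  4.5 Å, rows three and beyond are not.

Passing closed-loop tests on these generators demonstrates that the
statistics recover known ground truth under their own assumptions; it does
not validate any external predictor, nor reproduce corpus-scale averages that
depend on real structures.

## Numerical choices and problem sizes

Default probe 1.4 Å and 960 sphere points per atom; unit tests drop to
120–240 points where only ordinal properties are asserted, keeping the full
suite under a minute. The end-to-end `run_pipeline()` defaults (60 sequences
of 150 residues; 100 x 500-residue disorder corpus; 2000 decoy lists; 240
sphere points) are sized so a complete run takes seconds while every stage
still operates in its calibrated regime; the acceptance analyses use 200,000
residues for odds-ratio recovery and 10,000 decoy lists, the package's
standard large-sample settings. Seeds are explicit everywhere; a fixed seed
gives byte-identical output (the RNG state of the calling session is never
disturbed).

## Known limitations

* The surrogate predictor is a hydropathy window; it recovers planted
  hydrophobic APRs but makes no claim about real aggregation scores.
* The exact test is replaced by the chi-square approximation above 1e5
  residues; published "exact" probabilities at that scale are not
  numerically reproducible in any case.
* Identity filtering uses column identity, not alignment scores; the two are
  conflated in common usage but can differ near gaps.
* SASA absolute values depend on the radius set (Bondi) and differ slightly
  from other engines; all downstream metrics are ratios, which are far less
  sensitive to the radius choice.
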