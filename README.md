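# aprtools

Sequence and structure analysis of protein **aggregation prone regions
(APRs)** — the short, β-prone hydrophobic stretches that nucleate cross-β
aggregation. The package is aimed at structural bioinformaticians and protein
engineers who want to quantify how a proteome or a single protein manages its
aggregation liability, and to rank APRs as mutation targets for improving
solubility.

## What it computes

* **Sequence null models** — uniform-composition random sequences,
  composition-matched random sequences, and exact residue-multiset-preserving
  scrambles of natural sequences; pooled amino-acid compositions and a
  counts-per-1000 goodness-of-fit χ² between composition profiles
  (`Σ (Oₖ − Eₖ)² / Eₖ` over the 20 residue types); k-means splitting of a
  corpus by per-sequence composition; Welch/pooled t-tests between
  aggregation-propensity distributions.
* **APR statistics** — length-normalized aggregation propensity
  (score/length), APR residue proportion (Σ APR lengths / seqlen), and
  gate-keeper (D, E, K, R, P) frequencies at the three flank positions on
  each side of every APR.
* **Conservation** — percent identity filtering of homologue alignments and
  the APR conservation score `100 (n_total − n_uniq) / n_total`, where
  `n_uniq` counts distinct APR sequence variants across the family.
* **Order/disorder association** — the 2×2 residue contingency table
  (in/out APR × ordered/disordered), odds ratios
  `(in_ord/out_ord)/(in_dis/out_dis)` with reciprocal orientation,
  χ² and exact tests.
* **Structural burial** — a Shrake–Rupley SASA engine (probe 1.4 Å, 960
  deterministic sphere points, Bondi radii), per-type dataset average ASA,
  and per-segment metrics: observed/expected SASA, isolated-segment total
  surface, percent solvent accessibility, burial preference, and solvent
  isolatedness Iso with its sliding-window Z-score and ratio.
* **Catalytic proximity** — expected incidence of catalytic residues in APRs
  plus 3-residue flanks (`n_cata · n_APR / n_total`), heavy-atom contact
  detection at a 4.5 Å cutoff, and a decoy-list permutation null with
  optional ASA matching, reporting `Z = (observed − null mean)/null sd`.
* **Disruption ranking** — the four-branch rule classifying each APR as
  `do_not_disrupt`, `priority_target`,
  `conditional_disrupt_after_allostery_check` or
  `conditional_disrupt_with_modeling` from its burial, functional-contact and
  conservation flags.
* **Synthetic data** — generators with machine-readable ground truth for
  every stage (planted APRs and gate-keepers, disorder corpora with a target
  odds ratio, deterministic toy structures, alignment families with
  controlled mutation rates, catalytic-proximity scenarios).

See `vignettes/aprtools-methods.Rmd` for the models, conventions and design
decisions.

## Worked example

```r
library(aprtools)

# Odds ratio from a published order/disorder contingency table
t <- contingency_table(1327, 10739, 59311, 160944)
odds_ratio(t)                      # 2.982  (ordered residues ~3x likelier in APRs)
odds_ratio(t, "disordered")        # 0.335  (the reciprocal orientation)

# Composition chi-square: folded-protein corpus vs uniform 5%
composition_chi_square(reference_composition(),
                       setNames(rep(0.05, 20), aa_alphabet()))
#> 160.84

# Expected catalytic residues inside APRs + flanks (961 sites, corpus of 110,334)
estimate_incidence(961, 11414, 110334)$count   # 99   (10.3% of 961)

# Burial of a designated core segment in a deterministic toy structure
toy  <- make_toy_structure()
asa  <- compute_asa(toy$model, points = 240)
core <- iso_zscore_riso(toy$model, "A", toy$core[1], toy$core[2],
                        asa = asa, points = 240)
core$iso; core$z                   # 0.222, 0.88  (above the window mean: buried)

# Decoy permutation null on a planted proximity scenario
sc <- make_catalytic_scenario(n_sites = 10, prop_near = 0.6, seed = 5)
decoy_null(sc$model, sc$sites, sc$aprs, n_lists = 10000, seed = 6)
#> decoy null: observed 6 of 10 sites in APR contact;
#> null 0.67 +/- 0.79 over 10000 lists; Z = 6.78 (cutoff 4.5 A)
```

The observed count (6 planted contacts) sits far above the chain's uniform
background, so the Z-score flags the planted proximity; under a null
placement the same machinery gives |Z| < 4.

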