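# Disruption-candidate ranking and end-to-end pipeline orchestration.

#' Rank APRs as protein-solubility mutation targets
#'
#' Deterministic four-branch decision rule over three per-APR feature flags:
#' \itemize{
#'   \item `buried` — the APR's solvent isolatedness is above its protein's
#'     sliding-window mean (Z > 0), i.e. it likely stabilizes the core;
#'   \item `contact` — the APR contacts functional (e.g. catalytic) residues;
#'   \item `conserved` — the APR is more conserved than the average sequence
#'     identity among homologues.
#' }
#' Verdicts: a buried APR is never disrupted; an exposed APR with no
#' functional contact is a `priority_target` when weakly conserved, or
#' requires an allostery check first when strongly conserved; an exposed APR
#' in functional contact can only be disrupted with molecular modelling
#' support when weakly conserved, and is left alone when also conserved. A
#' missing flag yields `insufficient_evidence`.
#'
#' @param dossiers Data frame with logical columns `buried`, `contact`,
#'   `conserved` (NA = missing evidence); other columns are carried through.
#' @return The input with `verdict` and `rationale` columns appended.
#' @export
rank_disruption_candidates <- function(dossiers) {
  need <- c("buried", "contact", "conserved")
  if (!all(need %in% names(dossiers)))
    stop("dossiers require logical columns: ", paste(need, collapse = ", "))
  decide <- function(buried, contact, conserved) {
    if (is.na(buried) || is.na(contact) || is.na(conserved))
      return(c("insufficient_evidence", "one or more feature flags missing"))
    if (buried)
      return(c("do_not_disrupt",
               "buried in the protein core; likely contributes to stability"))
    if (!contact && !conserved)
      return(c("priority_target",
               "exposed, no functional contact, weakly conserved"))
    if (!contact && conserved)
      return(c("conditional_disrupt_after_allostery_check",
               "exposed and uncontacted but conserved; rule out allostery or other structure-function roles first"))
    if (contact && !conserved)
      return(c("conditional_disrupt_with_modeling",
               "exposed and weakly conserved but contacts functional residues; model mutations that spare contacting residues"))
    c("do_not_disrupt",
      "contacts functional residues and is conserved")
  }
  vr <- t(mapply(decide, dossiers$buried, dossiers$contact, dossiers$conserved))
  dossiers$verdict <- unname(vr[, 1])
  dossiers$rationale <- unname(vr[, 2])
  dossiers
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes every stage on internally generated synthetic data with ground
#' truth: sequence nulls and composition chi-square, surrogate APR prediction
#' with gate-keeper profiling, the disorder contingency analysis, toy-
#' structure burial metrics, alignment-family conservation, the catalytic
#' decoy null, and disruption ranking. All randomness derives from `seed`;
#' re-running with the same config and seed reproduces the reports.
#'
#' @param out_dir Output directory (created if needed); TSV tables plus a
#'   JSON manifest `manifest.json` are written there.
#' @param seed Integer master seed.
#' @param config Optional named list overriding stage parameters
#'   (`n_sequences`, `seq_length`, `n_lists`, `sasa_points`, `or_n`,
#'   `or_length`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = list()) {
  cfg <- utils::modifyList(list(
    n_sequences = 60, seq_length = 150,
    or_n = 100, or_length = 500,
    n_lists = 2000, sasa_points = 240), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  # sequence nulls and composition statistics
  synth <- make_sequences_with_aprs(cfg$n_sequences, cfg$seq_length,
                                    aprs_per_seq = 2, apr_len = c(6, 9),
                                    gatekeeper_rates = c(pb1 = 0.4, pe1 = 0.4),
                                    seed = seed)
  chi2 <- composition_chi_square(reference_composition(),
                                 stats::setNames(rep(0.05, 20), aa_alphabet()))
  preds <- lapply(names(synth$seqs),
                  function(id) surrogate_predict_aprs(synth$seqs[id]))
  summ <- dataset_summary(preds)
  gk <- gatekeeper_profile(synth$seqs, synth$aprs)
  write_tsv(as.data.frame(synth$aprs), file.path(out_dir, "planted_aprs.tsv"))
  write_tsv(summ, file.path(out_dir, "dataset_summary.tsv"))

  # disorder contingency
  corpus <- make_disorder_corpus(cfg$or_n, cfg$or_length, target_or = 3.0,
                                 seed = seed + 10)
  ct <- build_contingency(corpus$seqs, corpus$aprs, corpus$disorder)
  or_est <- odds_ratio(ct)
  tests <- association_tests(ct)
  write_tsv(data.frame(cell = c("in_dis", "in_ord", "out_dis", "out_ord"),
                       count = c(ct$in_dis, ct$in_ord, ct$out_dis, ct$out_ord)),
            file.path(out_dir, "contingency.tsv"))

  # structure burial
  toy <- make_toy_structure()
  asa <- compute_asa(toy$model, points = cfg$sasa_points)
  core <- iso_zscore_riso(toy$model, "A", toy$core[1], toy$core[2],
                          asa = asa, points = cfg$sasa_points)
  tail_m <- iso_zscore_riso(toy$model, "A", toy$tail[1], toy$tail[2],
                            asa = asa, points = cfg$sasa_points)

  # conservation
  fam <- make_alignment_family(seed = seed + 20)
  cons <- apr_conservation(fam$aln, fam$parent_aprs)
  ident <- mean_identity(fam$aln)

  # catalytic decoy null
  scen <- make_catalytic_scenario(n_sites = 10, prop_near = 0.6,
                                  seed = seed + 30)
  dn <- decoy_null(scen$model, scen$sites, scen$aprs,
                   n_lists = cfg$n_lists, seed = seed + 31)

  # ranking on the toy APR dossiers
  dossiers <- data.frame(
    segment = c("core", "tail"),
    buried = c(core$z > 0, tail_m$z > 0),
    contact = c(FALSE, FALSE),
    conserved = c(cons$conservation_pct > ident$parent_mean,
                  cons$conservation_pct > ident$parent_mean))
  ranked <- rank_disruption_candidates(dossiers)
  write_tsv(ranked, file.path(out_dir, "disruption_ranking.tsv"))

  manifest <- list(
    seed = seed, config = cfg,
    composition_chi_square = chi2,
    pct_sequences_with_apr = summ$pct_with_apr,
    gatekeeper_mean_per_apr = gk$mean_per_apr,
    odds_ratio = or_est, chisq_p = tests$chisq_p,
    core_iso = core$iso, core_z = core$z,
    tail_iso = tail_m$iso, tail_z = tail_m$z,
    conservation_pct = cons$conservation_pct,
    mean_identity_parent = ident$parent_mean,
    decoy_observed = dn$observed, decoy_null_mean = dn$null_mean,
    decoy_null_sd = dn$null_sd, decoy_z = dn$z)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
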