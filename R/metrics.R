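# Segment burial and solvent-isolatedness metrics for APRs in structures.

# Subset a structure model to residues of one chain with seq_index in `idx`.
subset_model <- function(model, chain, idx) {
  res <- model$residues
  keep_keys <- res$res_key[res$chain == chain & res$seq_index %in% idx]
  if (length(keep_keys) != length(idx))
    stop("segment residues missing from structure: chain ", chain,
         " seq_index ", paste(setdiff(idx, res$seq_index[res$chain == chain]),
                              collapse = ", "))
  atoms <- model$atoms[model$atoms$res_key %in% keep_keys, , drop = FALSE]
  structure_model(atoms[setdiff(names(atoms), "res_key")])
}

#' Burial and isolatedness metrics for one segment
#'
#' For a segment (e.g. an APR) of a protein structure the following are
#' computed, all from the same SASA engine so the segment keeps an identical
#' conformation in and out of context:
#' \describe{
#'   \item{sasa_obs}{sum of the segment residues' ASA within the full
#'     structure (observed SASA).}
#'   \item{sasa_exp}{sum of dataset-average ASA values for the segment's
#'     residue types (expected SASA).}
#'   \item{tot_sa}{SASA of the segment's atoms alone, rest of the protein
#'     deleted, conformation unchanged (total surface area).}
#'   \item{solv_acc}{percent solvent accessibility, `100 * sasa_obs / tot_sa`.}
#'   \item{bur_pref}{burial preference, `sasa_obs / sasa_exp`; below 1 means
#'     more buried than its residue composition predicts.}
#'   \item{prot_bur_sa}{surface buried by the rest of the protein,
#'     `tot_sa - sasa_obs`.}
#'   \item{iso}{solvent isolatedness, `prot_bur_sa / tot_sa`; satisfies
#'     `iso + solv_acc/100 = 1` identically.}
#' }
#'
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @param start,end Segment bounds as 1-based residue indices within the
#'   chain (`seq_index` coordinates).
#' @param avasa Optional named per-type average ASA vector (from
#'   [average_asa_by_type()]); when omitted it is computed from `model`
#'   itself.
#' @param asa Optional precomputed `asa_table` for `model` (avoids
#'   recomputation).
#' @param probe,points,fallback_radius Passed to [compute_asa()].
#' @return Named list of the seven metrics above.
#' @export
segment_metrics <- function(model, chain, start, end, avasa = NULL, asa = NULL,
                            probe = 1.4, points = 960, fallback_radius = NULL) {
  stopifnot(start >= 1, end >= start)
  if (is.null(asa))
    asa <- compute_asa(model, probe = probe, points = points,
                       fallback_radius = fallback_radius)
  idx <- start:end
  rows <- asa[asa$chain == chain & asa$seq_index %in% idx, , drop = FALSE]
  if (nrow(rows) != length(idx))
    stop("segment residues lacking coordinates: chain ", chain, " positions ",
         paste(setdiff(idx, rows$seq_index), collapse = ", "))
  if (is.null(avasa)) avasa <- average_asa_by_type(asa)
  sasa_obs <- sum(rows$asa)
  exp_terms <- avasa[rows$aa]
  if (anyNA(exp_terms))
    stop("no average ASA available for residue type(s): ",
         paste(unique(rows$aa[is.na(exp_terms)]), collapse = ", "))
  sasa_exp <- sum(exp_terms)
  seg <- subset_model(model, chain, idx)
  tot_sa <- sum(compute_asa(seg, probe = probe, points = points,
                            fallback_radius = fallback_radius)$asa)
  prot_bur <- tot_sa - sasa_obs
  list(sasa_obs = sasa_obs, sasa_exp = sasa_exp, tot_sa = tot_sa,
       solv_acc = 100 * sasa_obs / tot_sa,
       bur_pref = sasa_obs / sasa_exp,
       prot_bur_sa = prot_bur,
       iso = prot_bur / tot_sa)
}

# Consecutively-numbered runs of residues with coordinates, per chain.
chain_runs <- function(model, chain) {
  res <- model$residues[model$residues$chain == chain, , drop = FALSE]
  res <- res[order(res$seq_index), , drop = FALSE]
  if (nrow(res) == 0L) stop("no residues in chain ", chain)
  brk <- c(TRUE, diff(res$resno) != 1L)
  split(res$seq_index, cumsum(brk))
}

#' Isolatedness Z-score and relative isolatedness of a segment
#'
#' The segment's solvent isolatedness is standardized against all equal-length
#' windows of the same protein, obtained by sliding a window one residue at a
#' time over every run of consecutively numbered residues with coordinates
#' (the segment's own window included). `z = (iso_seg - mean) / sd` and
#' `r_iso = iso_seg / mean`.
#'
#' @inheritParams segment_metrics
#' @return List with `iso`, `z`, `r_iso`, `window_mean`, `window_sd`,
#'   `n_windows`, and `window_iso` (all window values, in window order).
#'   `z` is `NA` when the window standard deviation is zero.
#' @export
iso_zscore_riso <- function(model, chain, start, end, avasa = NULL, asa = NULL,
                            probe = 1.4, points = 960, fallback_radius = NULL) {
  if (is.null(asa))
    asa <- compute_asa(model, probe = probe, points = points,
                       fallback_radius = fallback_radius)
  L <- end - start + 1L
  runs <- chain_runs(model, chain)
  asa_chain <- asa[asa$chain == chain, , drop = FALSE]
  asa_by_index <- stats::setNames(asa_chain$asa, asa_chain$seq_index)
  win_iso <- numeric(0)
  win_start <- integer(0)
  for (run in runs) {
    if (length(run) < L) next
    for (s in run[seq_len(length(run) - L + 1L)]) {
      idx <- s:(s + L - 1L)
      obs <- sum(asa_by_index[as.character(idx)])
      seg <- subset_model(model, chain, idx)
      tot <- sum(compute_asa(seg, probe = probe, points = points,
                             fallback_radius = fallback_radius)$asa)
      win_iso <- c(win_iso, (tot - obs) / tot)
      win_start <- c(win_start, s)
    }
  }
  if (length(win_iso) < 2L)
    stop("fewer than two sliding windows: Z-score undefined")
  if (!(start %in% win_start))
    stop("segment window not among sliding windows (chain break inside segment?)")
  iso_seg <- win_iso[match(start, win_start)]
  m <- mean(win_iso)
  s <- stats::sd(win_iso)
  list(iso = iso_seg,
       z = if (s > 0) (iso_seg - m) / s else NA_real_,
       r_iso = iso_seg / m,
       window_mean = m, window_sd = s,
       n_windows = length(win_iso), window_iso = win_iso)
}

#' Bin secondary-structure codes for APR residues
#'
#' Maps per-residue secondary-structure codes to three bins (helix: H, G, I;
#' strand: E, B, b; coil: everything else) and counts APR residues per bin.
#'
#' @param assignments Data frame with `seq_id`, `pos` (1-based) and `code`.
#' @param aprs An `apr_table`.
#' @return Named list with counts `helix`, `strand`, `coil`, `n_missing`
#'   (APR residues without an assignment, excluded with a warning) and
#'   `fraction` (the three bins as fractions of assigned APR residues).
#' @export
bin_secondary_structure <- function(assignments, aprs) {
  if (nrow(aprs) == 0L)
    return(list(helix = 0L, strand = 0L, coil = 0L, n_missing = 0L,
                fraction = c(helix = NA_real_, strand = NA_real_, coil = NA_real_)))
  key <- paste(assignments$seq_id, assignments$pos)
  codes <- stats::setNames(toupper(as.character(assignments$code)), key)
  want <- unlist(lapply(seq_len(nrow(aprs)), function(i)
    paste(aprs$seq_id[i], aprs$start[i]:aprs$end[i])))
  found <- codes[want]
  n_missing <- sum(is.na(found))
  if (n_missing > 0)
    warning(n_missing, " APR residue(s) lack a secondary-structure assignment; excluded")
  found <- found[!is.na(found)]
  helix <- sum(found %in% c("H", "G", "I"))
  strand <- sum(found %in% c("E", "B"))
  coil <- length(found) - helix - strand
  tot <- length(found)
  list(helix = helix, strand = strand, coil = coil, n_missing = n_missing,
       fraction = c(helix = helix, strand = strand, coil = coil) /
         if (tot > 0) tot else NA_real_)
}
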