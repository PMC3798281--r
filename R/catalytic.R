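# Catalytic-residue incidence near APRs and the decoy-list permutation null.

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimated incidence of catalytic residues in APRs and flanks
#'
#' Under the null that catalytic residues are placed uniformly over the
#' corpus, the expected number that fall inside APRs and their flanking
#' regions is `n_cata * n_apr_residues / n_total_residues`.
#'
#' @param n_cata Number of catalytic residues in the corpus.
#' @param n_apr_residues Residues inside APRs plus flanking regions (union;
#'   see [count_apr_flank_residues()]).
#' @param n_total_residues Total residues in the corpus.
#' @return List with `raw` (the unrounded estimate), `count` (rounded,
#'   half away from zero) and `pct` (`100 * count / n_cata`).
#' @export
estimate_incidence <- function(n_cata, n_apr_residues, n_total_residues) {
  stopifnot(n_total_residues > 0, n_apr_residues >= 0,
            n_apr_residues <= n_total_residues, n_cata >= 0)
  raw <- n_cata * n_apr_residues / n_total_residues
  cnt <- round_half_up(raw)
  list(raw = raw, count = cnt, pct = 100 * cnt / n_cata)
}

#' Count residues inside APRs and their flanking regions
#'
#' Union count over all sequences of residues within an APR or within `flank`
#' residues of one (truncated at sequence termini); residues covered by
#' several APRs or flanks are counted once.
#'
#' @param seqs Named character vector of sequences.
#' @param aprs An `apr_table`.
#' @param flank Flank width on each side (default 3).
#' @return List with `total`, `in_apr` and `in_flank` (the flank count is the
#'   union of flank positions not already inside any APR).
#' @export
count_apr_flank_residues <- function(seqs, aprs, flank = 3) {
  seqs <- as_sequence_set(seqs)
  flank <- assert_count(flank, "flank", min = 0L)
  in_apr_total <- 0L
  flank_total <- 0L
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    a <- aprs[aprs$seq_id == id, , drop = FALSE]
    if (nrow(a) == 0L) next
    core <- interval_mask(L, a$start, a$end, "APR")
    wide <- interval_mask(L, pmax(1L, a$start - flank), pmin(L, a$end + flank), "APR")
    in_apr_total <- in_apr_total + sum(core)
    flank_total <- flank_total + sum(wide & !core)
  }
  list(total = in_apr_total + flank_total,
       in_apr = in_apr_total, in_flank = flank_total)
}

# Per-residue APR membership and APR-contact flags for one structure.
# APR tables reference structure chains through seq_id == chain id, with
# start/end in within-chain seq_index coordinates.
residue_contact_flags <- function(model, aprs, cutoff) {
  res <- model$residues
  in_apr <- logical(nrow(res))
  for (i in seq_len(nrow(aprs))) {
    hit <- res$chain == aprs$seq_id[i] &
      res$seq_index >= aprs$start[i] & res$seq_index <= aprs$end[i]
    in_apr <- in_apr | hit
  }
  atoms <- model$atoms
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  apr_keys <- res$res_key[in_apr]
  atom_in_apr <- atoms$res_key %in% apr_keys
  contact <- logical(nrow(res))
  if (any(atom_in_apr)) {
    apr_xyz <- xyz[atom_in_apr, , drop = FALSE]
    apr_res <- atoms$res_key[atom_in_apr]
    cut2 <- cutoff^2
    for (k in seq_len(nrow(res))) {
      mine <- atoms$res_key == res$res_key[k]
      other <- apr_res != res$res_key[k]
      if (!any(other)) next
      axyz <- apr_xyz[other, , drop = FALSE]
      mxyz <- xyz[mine, , drop = FALSE]
      found <- FALSE
      for (m in seq_len(nrow(mxyz))) {
        d2 <- (axyz[, 1] - mxyz[m, 1])^2 + (axyz[, 2] - mxyz[m, 2])^2 +
              (axyz[, 3] - mxyz[m, 3])^2
        if (any(d2 <= cut2)) { found <- TRUE; break }
      }
      contact[k] <- found
    }
  }
  data.frame(chain = res$chain, resno = res$resno, icode = res$icode,
             aa = res$aa, seq_index = res$seq_index, res_key = res$res_key,
             in_apr = in_apr, contact = contact, stringsAsFactors = FALSE)
}

resolve_sites <- function(model, sites) {
  res <- model$residues
  icode <- if (is.null(sites$icode)) rep("", nrow(sites)) else
    ifelse(is.na(sites$icode), "", sites$icode)
  keys <- paste(sites$chain, sites$resno, icode, sep = "|")
  ix <- match(keys, res$res_key)
  if (anyNA(ix)) {
    bad <- keys[is.na(ix)]
    stop("catalytic site(s) not found in structure: ", paste(bad, collapse = "; "))
  }
  ix
}

#' Heavy-atom contacts between catalytic residues and APRs
#'
#' A catalytic residue is in structural contact with an APR when at least one
#' of its heavy atoms lies within `cutoff` of a heavy atom of any APR residue
#' other than itself. Residues that are themselves inside an APR are flagged
#' (`in_apr`) and excluded from the contact count.
#'
#' @param model A `structure_model`.
#' @param sites Data frame of catalytic sites: `chain`, `resno`, optional
#'   `icode`.
#' @param aprs `apr_table` with `seq_id` = chain id and coordinates in
#'   within-chain residue indices.
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @return Data frame with one row per site: `chain`, `resno`, `icode`,
#'   `in_apr`, `contact`, `counts` (logical; `contact & !in_apr`).
#' @export
detect_contacts <- function(model, sites, aprs, cutoff = 4.5) {
  flags <- residue_contact_flags(model, aprs, cutoff)
  ix <- resolve_sites(model, sites)
  out <- flags[ix, c("chain", "resno", "icode", "in_apr", "contact")]
  out$counts <- out$contact & !out$in_apr
  rownames(out) <- NULL
  out
}

#' Decoy-list permutation null for catalytic-residue/APR proximity
#'
#' For each true catalytic site a decoy residue is drawn uniformly from the
#' standard-amino-acid residues of the same chain of the same structure; one
#' decoy list replaces every true site this way, and the number of decoys in
#' contact with APRs is recorded per list. The observed count over the true
#' sites is standardized against the null distribution:
#' `z = (observed - mean) / sd`.
#'
#' With `asa_match` set (e.g. `0.10`), decoy candidates are restricted to
#' residues whose ASA lies within `asa_match * 100` percent of the true
#' site's ASA, which controls for solvent exposure.
#'
#' @param models A `structure_model` or named list of them (names =
#'   `structure_id`).
#' @param sites Data frame of sites: optional `structure_id` (required with a
#'   model list), `chain`, `resno`, optional `icode`.
#' @param aprs `apr_table` (see [detect_contacts()]); for multiple structures
#'   prefix handling is per structure via `seq_id` = chain id.
#' @param n_lists Number of decoy lists (>= 100; default 10000).
#' @param cutoff Contact distance, Angstrom.
#' @param asa_match `NULL` for no ASA restriction, or a fraction such as 0.10.
#' @param seed Integer seed.
#' @param exclude_self Remove the true residue itself from its candidate pool.
#' @param exclude_catalytic Remove all true catalytic residues of the chain
#'   from candidate pools.
#' @param whole_structure Draw candidates from the whole structure rather
#'   than the site's chain.
#' @param probe,points Passed to [compute_asa()] when `asa_match` is set.
#' @return List of class `decoy_null_result`: `observed`, `null_mean`,
#'   `null_sd`, `z` (`NA` when `null_sd` is 0), `n_lists`, `cutoff`,
#'   `asa_match`, `seed`, `n_sites`.
#' @export
decoy_null <- function(models, sites, aprs, n_lists = 10000, cutoff = 4.5,
                       asa_match = NULL, seed = 1, exclude_self = FALSE,
                       exclude_catalytic = FALSE, whole_structure = FALSE,
                       probe = 1.4, points = 960) {
  n_lists <- assert_count(n_lists, "n_lists", min = 100L)
  single <- inherits(models, "structure_model")
  if (single) models <- list(structure = models)
  if (is.null(sites$structure_id)) {
    if (!single && length(models) > 1L)
      stop("sites need a structure_id column when several structures are supplied")
    sites$structure_id <- names(models)[1]
  }
  if (!all(sites$structure_id %in% names(models)))
    stop("site references unknown structure: ",
         paste(setdiff(sites$structure_id, names(models)), collapse = ", "))

  observed <- 0L
  cand_flags <- list()   # per site: logical contact contributions of candidates
  for (sid in unique(sites$structure_id)) {
    model <- models[[sid]]
    flags <- residue_contact_flags(model, aprs, cutoff)
    std <- flags$aa %in% aa_alphabet()
    asa_vals <- NULL
    if (!is.null(asa_match)) {
      stopifnot(is.numeric(asa_match), asa_match > 0)
      asa_vals <- compute_asa(model, probe = probe, points = points)$asa
    }
    ss <- sites[sites$structure_id == sid, , drop = FALSE]
    ix <- resolve_sites(model, ss)
    observed <- observed + sum(flags$contact[ix] & !flags$in_apr[ix])
    cat_keys <- flags$res_key[ix]
    for (r in seq_along(ix)) {
      i <- ix[r]
      pool <- std & (if (whole_structure) TRUE else flags$chain == flags$chain[i])
      if (exclude_self) pool <- pool & flags$res_key != flags$res_key[i]
      if (exclude_catalytic) pool <- pool & !(flags$res_key %in% cat_keys)
      if (!is.null(asa_vals)) {
        lo <- asa_vals[i] * (1 - asa_match)
        hi <- asa_vals[i] * (1 + asa_match)
        pool <- pool & asa_vals >= lo & asa_vals <= hi
      }
      if (!any(pool))
        stop("no decoy candidates for site ", flags$res_key[i],
             if (!is.null(asa_match)) " under the ASA-match restriction" else "")
      cand_flags[[length(cand_flags) + 1L]] <-
        flags$contact[pool] & !flags$in_apr[pool]
    }
  }

  counts <- with_seed(seed, {
    tot <- integer(n_lists)
    for (cf in cand_flags) {
      draw <- sample.int(length(cf), n_lists, replace = TRUE)
      tot <- tot + as.integer(cf[draw])
    }
    tot
  })
  m <- mean(counts)
  s <- stats::sd(counts)
  structure(list(observed = observed, null_mean = m, null_sd = s,
                 z = if (s > 0) (observed - m) / s else NA_real_,
                 n_lists = n_lists, cutoff = cutoff,
                 asa_match = if (is.null(asa_match)) NA_real_ else asa_match,
                 seed = seed, n_sites = length(cand_flags)),
            class = "decoy_null_result")
}

#' @export
print.decoy_null_result <- function(x, ...) {
  cat(sprintf(
    "decoy null: observed %d of %d sites in APR contact; null %.2f +/- %.2f over %d lists; Z = %s (cutoff %.1f A)\n",
    x$observed, x$n_sites, x$null_mean, x$null_sd, x$n_lists,
    if (is.na(x$z)) "undefined (sd = 0)" else sprintf("%.2f", x$z), x$cutoff))
  invisible(x)
}

#' Read a catalytic-site table
#'
#' TSV with columns `structure_id`, `chain`, `resno`, optional `icode`,
#' optional `restype`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "resno")
  if (!all(need %in% names(df)))
    stop("site table requires columns: ", paste(need, collapse = ", "))
  df$resno <- as.integer(df$resno)
  df
}
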