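# Synthetic fixtures with known ground truth for every pipeline stage:
# sequences with planted APRs and gate-keepers, disorder corpora with a
# target odds ratio, deterministic toy structures, alignment families with
# controlled mutation rates, and catalytic-proximity scenarios.

APR_CORE_RESIDUES <- c("V", "I", "L", "F")   # beta-branched / hydrophobic core

#' Synthetic sequences with planted APRs and gate-keepers
#'
#' Background residues are drawn i.i.d. from `composition` (default: the
#' folded-protein reference composition). Each sequence receives
#' `aprs_per_seq` planted APRs: windows filled with beta-branched hydrophobic
#' residues (V/I/L/F), placed non-overlapping with at least `gap` background
#' residues between APRs and from the termini so flanking positions exist.
#' Flank positions named in `gatekeeper_rates` are controlled: they carry a
#' gate-keeper (random member of D/E/K/R/P) with exactly the stated
#' probability and a non-gate-keeper background residue otherwise, so a
#' planted rate is recovered directly by [gatekeeper_profile()]. Flank
#' positions not named keep plain background composition (which itself
#' contains roughly 29% gate-keepers).
#'
#' @param n Number of sequences.
#' @param length Sequence length (all sequences equal length).
#' @param aprs_per_seq Planted APRs per sequence (0 allowed).
#' @param apr_len Length of each planted APR (single value or range
#'   `c(min, max)` sampled uniformly).
#' @param gatekeeper_rates Named numeric vector with names among
#'   `c("pb3","pb2","pb1","pe1","pe2","pe3")`, gate-keeper probability per
#'   controlled flank position (default: no position controlled).
#' @param composition Background composition (20 frequencies).
#' @param gap Minimum background spacing around APRs (default 4).
#' @param seed Integer seed.
#' @return List with `seqs` (named character vector) and `aprs` (ground-truth
#'   `apr_table`, `source = "user"`).
#' @export
make_sequences_with_aprs <- function(n, length, aprs_per_seq = 1,
                                     apr_len = 6,
                                     gatekeeper_rates = NULL,
                                     composition = reference_composition(),
                                     gap = 4, seed = 1) {
  n <- assert_count(n, "n")
  length <- assert_count(length, "length")
  aprs_per_seq <- assert_count(aprs_per_seq, "aprs_per_seq", min = 0L)
  composition <- assert_composition(composition)
  positions <- c("pb3", "pb2", "pb1", "pe1", "pe2", "pe3")
  gk_rates <- stats::setNames(rep(0, 6), positions)
  if (!is.null(gatekeeper_rates)) {
    stopifnot(all(names(gatekeeper_rates) %in% positions),
              all(gatekeeper_rates >= 0 & gatekeeper_rates <= 1))
    gk_rates[names(gatekeeper_rates)] <- gatekeeper_rates
  }
  lmin <- min(apr_len); lmax <- max(apr_len)
  if (lmin < 6) stop("planted APRs must be at least 6 residues")
  need <- aprs_per_seq * (lmax + gap) + gap
  if (need > length)
    stop("planted APRs exceed sequence capacity: need up to ", need,
         " residues, have ", length)
  offs <- stats::setNames(c(-3L, -2L, -1L, 1L, 2L, 3L), positions)
  gk <- gatekeeper_residues()
  non_gk <- setdiff(aa_alphabet(), gk)
  controlled <- if (is.null(gatekeeper_rates)) character(0) else names(gatekeeper_rates)
  with_seed(seed, {
    seqs <- character(n)
    tab <- vector("list", n)
    for (i in seq_len(n)) {
      chars <- sample(aa_alphabet(), length, replace = TRUE, prob = composition)
      starts <- integer(0); ends <- integer(0)
      if (aprs_per_seq > 0) {
        # lay APRs left to right; sorted slack spreads them over the free room
        lens <- if (lmin == lmax) rep(lmin, aprs_per_seq) else
          sample(seq.int(lmin, lmax), aprs_per_seq, replace = TRUE)
        free <- length - sum(lens) - gap * (aprs_per_seq + 1L)
        slack <- if (free > 0) sort(sample.int(free + 1L, aprs_per_seq, replace = TRUE) - 1L)
                 else rep(0L, aprs_per_seq)
        for (k in seq_len(aprs_per_seq)) {
          s <- gap + 1L + slack[k] +
            (if (k > 1) sum(lens[seq_len(k - 1L)]) + (k - 1L) * gap else 0L)
          e <- s + lens[k] - 1L
          chars[s:e] <- sample(APR_CORE_RESIDUES, lens[k], replace = TRUE)
          # controlled flank positions carry a gate-keeper with exactly the
          # stated probability (background gate-keeper content overridden)
          for (p in controlled) {
            anchor <- if (substr(p, 2, 2) == "b") s else e
            fp <- anchor + offs[[p]]
            if (fp >= 1L && fp <= length) {
              chars[fp] <- if (stats::runif(1) < gk_rates[[p]]) sample(gk, 1L)
                           else sample(non_gk, 1L, prob = composition[non_gk])
            }
          }
          starts <- c(starts, s); ends <- c(ends, e)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
      tab[[i]] <- if (base::length(starts))
        data.frame(seq_id = sprintf("synth%05d", i), start = starts, end = ends,
                   source = "user", score = NA_real_)
      else NULL
    }
    names(seqs) <- sprintf("synth%05d", seq_len(n))
    aprs <- do.call(rbind, tab)
    if (is.null(aprs))
      aprs <- data.frame(seq_id = character(), start = integer(), end = integer(),
                         source = character(), score = numeric())
    list(seqs = seqs, aprs = apr_intervals(aprs))
  })
}

# Disorder probability inside APRs implied by the target ordered-orientation
# odds ratio and the disorder probability outside.
d_in_from_or <- function(d_out, or) d_out / (or + (1 - or) * d_out)

#' Synthetic corpus with a target APR/order odds ratio
#'
#' Sequences with planted APRs are generated, then each residue is labelled
#' disordered independently: with probability `d_in` inside APRs and `d_out`
#' outside, where (`d_in`, `d_out`) are solved so that the expected 2x2 table
#' has ordered-orientation odds ratio `target_or` and overall disorder
#' coverage `coverage` (default 0.261, a realistic disordered-protein corpus
#' background).
#'
#' @param n,length,aprs_per_seq,apr_len,composition,seed As in
#'   [make_sequences_with_aprs()].
#' @param coverage Overall expected fraction of disordered residues, in (0,1).
#' @param target_or Target odds ratio (ordered orientation), > 0.
#' @return List with `seqs`, `aprs`, `disorder` (interval data frame),
#'   `truth` (realized `contingency_table`), `params` (`d_in`, `d_out`,
#'   `apr_fraction`, `target_or`, `coverage`).
#' @export
make_disorder_corpus <- function(n = 400, length = 500, aprs_per_seq = 4,
                                 apr_len = c(6, 10), coverage = 0.261,
                                 target_or = 3.0,
                                 composition = reference_composition("idp"),
                                 seed = 1) {
  stopifnot(target_or > 0)
  if (!(coverage > 0 && coverage < 1))
    stop("coverage must be in (0, 1)")
  base <- make_sequences_with_aprs(n, length, aprs_per_seq, apr_len,
                                   composition = composition, seed = seed)
  f <- sum(base$aprs$end - base$aprs$start + 1L) / (n * length)
  if (f <= 0 || f >= 1) stop("degenerate APR fraction: ", f)
  g <- function(d_out) f * d_in_from_or(d_out, target_or) + (1 - f) * d_out - coverage
  if (g(1e-12) > 0 || g(1 - 1e-12) < 0)
    stop("no (d_in, d_out) in (0,1) achieves coverage ", coverage,
         " at odds ratio ", target_or)
  d_out <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  d_in <- d_in_from_or(d_out, target_or)
  cells <- c(in_dis = 0L, in_ord = 0L, out_dis = 0L, out_ord = 0L)
  dis_tab <- vector("list", n)
  with_seed(seed + 1, {
    for (i in seq_along(base$seqs)) {
      id <- names(base$seqs)[i]
      a <- base$aprs[base$aprs$seq_id == id, , drop = FALSE]
      in_apr <- interval_mask(length, a$start, a$end)
      p <- ifelse(in_apr, d_in, d_out)
      dis <- stats::runif(length) < p
      cells["in_dis"] <- cells["in_dis"] + sum(in_apr & dis)
      cells["in_ord"] <- cells["in_ord"] + sum(in_apr & !dis)
      cells["out_dis"] <- cells["out_dis"] + sum(!in_apr & dis)
      cells["out_ord"] <- cells["out_ord"] + sum(!in_apr & !dis)
      if (any(dis)) {
        r <- rle(dis)
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        dis_tab[[i]] <- data.frame(seq_id = id, start = s[r$values],
                                   end = e[r$values])
      }
    }
  })
  disorder <- do.call(rbind, dis_tab)
  if (is.null(disorder))
    disorder <- data.frame(seq_id = character(), start = integer(), end = integer())
  list(seqs = base$seqs, aprs = base$aprs, disorder = disorder,
       truth = contingency_table(cells["in_dis"], cells["in_ord"],
                                 cells["out_dis"], cells["out_ord"]),
       params = list(d_in = d_in, d_out = d_out, apr_fraction = f,
                     target_or = target_or, coverage = coverage))
}

#' Deterministic toy structure with a buried core and an exposed tail
#'
#' A single-chain C-alpha trace built from analytic geometry: an alpha-helical
#' coil (radius 2.3 A, rise 1.5 A, 100 degrees per residue) whose interior
#' windows are strongly self-occluded, followed by a straight extended tail
#' (3.8 A spacing) whose windows are maximally exposed. The designated `core`
#' segment (centre of the helix) is strictly more occluded than the `tail`
#' segment by construction, giving a provable solvent-isolatedness ordering.
#'
#' @param n_helix Helix residues (>= 12).
#' @param n_tail Tail residues (>= 8).
#' @param seg_len Length of the designated segments (default 6).
#' @param aa Residue type used for every residue (default `"A"`).
#' @return List with `model` (a `structure_model`, chain `"A"`, all atoms
#'   carbon), `core` and `tail` (`c(start, end)` in residue indices), and
#'   `seg_len`.
#' @export
make_toy_structure <- function(n_helix = 24, n_tail = 12, seg_len = 6, aa = "A") {
  n_helix <- assert_count(n_helix, "n_helix", min = 12L)
  n_tail <- assert_count(n_tail, "n_tail", min = 8L)
  seg_len <- assert_count(seg_len, "seg_len", min = 1L)
  t <- seq_len(n_helix)
  ang <- t * 100 * pi / 180
  hx <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
  tz <- hx[n_helix, 3] + 3.8 * seq_len(n_tail)
  tl <- cbind(rep(0, n_tail), rep(0, n_tail), tz)
  xyz <- rbind(hx, tl)
  if (anyDuplicated(round(xyz, 6))) stop("degenerate geometry: coincident atoms")
  n <- n_helix + n_tail
  model <- structure_model(data.frame(
    chain = "A", resno = seq_len(n), resname = aa, element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
  core_start <- as.integer(floor((n_helix - seg_len) / 2)) + 1L
  tail_start <- n - seg_len + 1L
  list(model = model,
       core = c(core_start, core_start + seg_len - 1L),
       tail = c(tail_start, tail_start + seg_len - 1L),
       seg_len = seg_len)
}

#' Synthetic homologue alignment family with controlled mutation rates
#'
#' Homologue rows are derived from a planted-APR parent by independent
#' per-column substitution (to a uniformly random different residue) at rate
#' `r_in` inside APR columns and `r_out` elsewhere; no gaps are introduced.
#' The expected APR conservation percentage is emitted using the
#' large-alphabet approximation that any mutated APR variant is distinct from
#' all others: `E[n_uniq per APR] ~ 1 + (M - 1) * (1 - (1 - r_in)^len)` for
#' `M` alignment rows (exact when `r_in` is 0).
#'
#' @param n_homologues Number of derived rows (alignment has this + 1 rows).
#' @param length Parent length.
#' @param aprs_per_seq,apr_len,composition As in [make_sequences_with_aprs()].
#' @param r_in,r_out Substitution rates inside / outside APR columns. The
#'   defaults (0.01 inside, 0.25 outside) emulate the distant-homologue regime
#'   where APR columns are under strong purifying constraint, so the measured
#'   APR conservation exceeds the family's mean sequence identity.
#' @param seed Integer seed.
#' @return List with `aln` (an `alignment_set`, parent first), `parent_aprs`
#'   (`apr_table`), `expected_conservation_pct`, `r_in`, `r_out`.
#' @export
make_alignment_family <- function(n_homologues = 9, length = 120,
                                  aprs_per_seq = 3, apr_len = 6,
                                  r_in = 0.01, r_out = 0.25,
                                  composition = reference_composition(),
                                  seed = 1) {
  stopifnot(r_in >= 0, r_in <= 1, r_out >= 0, r_out <= 1)
  n_homologues <- assert_count(n_homologues, "n_homologues")
  base <- make_sequences_with_aprs(1, length, aprs_per_seq, apr_len,
                                   composition = composition, seed = seed)
  parent <- unname(base$seqs[1])
  aprs <- base$aprs
  aprs$seq_id <- "parent"
  in_apr <- interval_mask(length, aprs$start, aprs$end)
  pc <- strsplit(parent, "", fixed = TRUE)[[1]]
  rows <- with_seed(seed + 1, vapply(seq_len(n_homologues), function(h) {
    rate <- ifelse(in_apr, r_in, r_out)
    mut <- stats::runif(length) < rate
    out <- pc
    for (j in which(mut)) out[j] <- sample(setdiff(aa_alphabet(), pc[j]), 1L)
    paste(out, collapse = "")
  }, character(1)))
  aln <- c(parent = parent, stats::setNames(rows, sprintf("hom%03d", seq_len(n_homologues))))
  M <- n_homologues + 1L
  lens <- aprs$end - aprs$start + 1L
  exp_uniq <- sum(1 + n_homologues * (1 - (1 - r_in)^lens))
  exp_total <- nrow(aprs) * M
  list(aln = as_alignment_set(aln),
       parent_aprs = apr_intervals(aprs),
       expected_conservation_pct = 100 * (exp_total - exp_uniq) / exp_total,
       r_in = r_in, r_out = r_out)
}

#' Synthetic catalytic-proximity scenario on a lattice structure
#'
#' A single-chain C-alpha lattice of `rows` x `width` residues (in-row
#' spacing 3.8 A, row spacing 4.0 A) with an APR planted in the first row.
#' Residues in the second row directly above the APR, and the two in-row
#' residues flanking it, are within the 4.5 A contact cutoff by construction;
#' residues in rows three and beyond are not. A fraction `prop_near` of the
#' catalytic sites is placed on contact-eligible residues and the rest far
#' from the APR, giving known ground-truth contact flags.
#'
#' @param width,rows Lattice dimensions (chain length = `rows * width`).
#' @param apr_cols Columns of row 1 covered by the APR, `c(first, last)`
#'   (1-based; length >= 6).
#' @param n_sites Number of catalytic sites.
#' @param prop_near Fraction of sites planted in contact with the APR.
#' @param seed Integer seed.
#' @return List with `model`, `sites` (data frame, plus logical
#'   `truth_contact`), `aprs` (`apr_table`, `seq_id = "A"`),
#'   `near_pool`, `far_pool` (residue indices), `background_rate`
#'   (contact-eligible fraction of the chain).
#' @export
make_catalytic_scenario <- function(width = 12, rows = 10, apr_cols = c(4, 9),
                                    n_sites = 10, prop_near = 0.5, seed = 1) {
  width <- assert_count(width, "width", min = 8L)
  rows <- assert_count(rows, "rows", min = 4L)
  stopifnot(length(apr_cols) == 2, apr_cols[1] >= 2, apr_cols[2] <= width - 1,
            apr_cols[2] - apr_cols[1] + 1 >= 6,
            prop_near >= 0, prop_near <= 1)
  n <- width * rows
  idx <- seq_len(n) - 1L
  col <- idx %% width
  row <- idx %/% width
  model <- structure_model(data.frame(
    chain = "A", resno = seq_len(n), resname = "A", element = "C",
    x = col * 3.8, y = row * 4.0, z = 0, stringsAsFactors = FALSE))
  apr <- apr_intervals(data.frame(seq_id = "A", start = apr_cols[1],
                                  end = apr_cols[2], source = "user",
                                  score = NA_real_))
  near_pool <- c(apr_cols[1] - 1L, apr_cols[2] + 1L,           # in-row flanks
                 width + (apr_cols[1]:apr_cols[2]))            # row 2, same cols
  far_pool <- which(row >= 3 & (col < apr_cols[1] - 1L | col > apr_cols[2] + 1L))
  n_near <- round_half_up(prop_near * n_sites)
  if (n_near > length(near_pool) || (n_sites - n_near) > length(far_pool))
    stop("infeasible placement: not enough near/far residues for ", n_sites,
         " sites at prop_near = ", prop_near)
  picked <- with_seed(seed, c(
    if (n_near > 0) sample(near_pool, n_near) else integer(0),
    if (n_sites - n_near > 0) sample(far_pool, n_sites - n_near) else integer(0)))
  sites <- data.frame(chain = rep("A", length(picked)), resno = picked,
                      icode = rep("", length(picked)),
                      truth_contact = c(rep(TRUE, n_near),
                                        rep(FALSE, n_sites - n_near)),
                      stringsAsFactors = FALSE)
  list(model = model, sites = sites, aprs = apr,
       near_pool = near_pool, far_pool = far_pool,
       background_rate = length(near_pool) / n)
}
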