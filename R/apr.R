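# APR interval data model, interval-table IO, sequence-level aggregation
# statistics, gate-keeper profiling, and a surrogate window predictor.

APR_SOURCES <- c("tango", "waltz", "amylseg", "surrogate", "user")

#' Construct and validate an APR interval table
#'
#' APRs (aggregation prone regions) are stored as a data frame with columns
#' `seq_id`, `start`, `end` (1-based inclusive residue indices), `source`
#' (one of tango, waltz, amylseg, surrogate, user) and optional non-negative
#' `score`. Intervals must satisfy `1 <= start <= end` and be at least
#' `min_len` residues long.
#'
#' @param seq_id,start,end,source,score Column vectors (recycled where length
#'   1); or pass a data frame as `seq_id` alone.
#' @param min_len Minimum interval length (default 6, the minimum prediction
#'   window used throughout).
#' @param seqlen Optional named vector of sequence lengths; when given, `end`
#'   is checked against it.
#' @return A validated `data.frame` of class `apr_table`.
#' @export
apr_intervals <- function(seq_id, start = NULL, end = NULL, source = "user",
                          score = NA_real_, min_len = 6, seqlen = NULL) {
  if (is.data.frame(seq_id)) {
    df <- seq_id
    need <- c("seq_id", "start", "end")
    if (!all(need %in% names(df)))
      stop("APR table requires columns: ", paste(need, collapse = ", "))
    if (is.null(df$source)) df$source <- "user"
    if (is.null(df$score)) df$score <- NA_real_
  } else {
    df <- data.frame(seq_id = as.character(seq_id), start = start, end = end,
                     source = source, score = score, stringsAsFactors = FALSE)
  }
  df$seq_id <- as.character(df$seq_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$source <- as.character(df$source)
  df$score <- as.numeric(df$score)
  if (nrow(df) > 0) {
    if (anyNA(df$start) || anyNA(df$end) || any(df$start < 1L) || any(df$end < df$start))
      stop("APR intervals must satisfy 1 <= start <= end")
    if (any(df$end - df$start + 1L < min_len))
      stop("APR intervals shorter than the minimum length of ", min_len)
    if (!all(df$source %in% APR_SOURCES))
      stop("APR source must be one of: ", paste(APR_SOURCES, collapse = ", "))
    if (any(!is.na(df$score) & df$score < 0))
      stop("APR scores must be non-negative")
    if (!is.null(seqlen)) {
      sl <- seqlen[df$seq_id]
      if (anyNA(sl)) stop("APR refers to unknown sequence id")
      if (any(df$end > sl)) stop("APR interval extends beyond sequence length")
    }
  }
  df <- df[order(df$seq_id, df$source, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("apr_table", "data.frame")
  df
}

#' Read / write APR interval tables as TSV
#'
#' Canonical interchange dialect: tab-separated columns `seq_id`, `start`,
#' `end`, `source`, `score`, with 1-based inclusive coordinates. Converters
#' from raw predictor output files are deliberately not provided (their
#' formats are tool-version dependent); convert such output to this dialect
#' upstream.
#'
#' @param path File path.
#' @param aprs An `apr_table`.
#' @param ... Passed to [apr_intervals()] (e.g. `min_len`).
#' @return `read_apr_tsv` returns an `apr_table`; `write_apr_tsv` returns
#'   `path` invisibly.
#' @export
read_apr_tsv <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  apr_intervals(df, ...)
}

#' @rdname read_apr_tsv
#' @export
write_apr_tsv <- function(aprs, path) {
  utils::write.table(as.data.frame(aprs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length-normalized aggregation propensity
#'
#' The total aggregation score of a sequence divided by its length.
#'
#' @param total_score Non-negative total aggregation score.
#' @param seqlen Sequence length in residues (>= 1).
#' @return Single number, score per residue.
#' @export
aggregation_propensity <- function(total_score, seqlen) {
  stopifnot(is.numeric(total_score), all(total_score >= 0))
  if (any(seqlen < 1)) stop("seqlen must be >= 1")
  total_score / seqlen
}

#' Percentage of a sequence covered by APRs
#'
#' `100 * sum(interval lengths) / seqlen` over non-overlapping intervals.
#'
#' @param seqlen Sequence length in residues.
#' @param aprs `apr_table` rows belonging to one sequence (may be empty).
#' @return Percentage in \[0, 100\].
#' @export
apr_proportion <- function(seqlen, aprs) {
  seqlen <- assert_count(seqlen, "seqlen")
  if (nrow(aprs) == 0L) return(0)
  if (any(aprs$end > seqlen)) stop("APR interval extends beyond sequence length")
  o <- order(aprs$start)
  if (any(aprs$start[o][-1] <= aprs$end[o][-nrow(aprs)]))
    stop("overlapping APR intervals: coverage percentage undefined")
  100 * sum(aprs$end - aprs$start + 1L) / seqlen
}

#' Gate-keeper residue profile around APRs
#'
#' For each APR the up-to-three preceding flank positions (pb1 = position
#' immediately before the APR, pb2, pb3) and succeeding positions (pe1..pe3)
#' are checked for membership in the gate-keeper set \{D, E, K, R, P\}.
#' Positions truncated by a sequence terminus are excluded from that
#' position's denominator.
#'
#' @param seqs Named character vector of sequences.
#' @param aprs `apr_table` with `seq_id` values present in `names(seqs)`.
#' @return List with `position_counts`, `position_totals`,
#'   `position_freq_pct` (named by pb3..pb1, pe1..pe3), `per_apr_counts`
#'   (integer per APR, in \[0, 6\]) and `mean_per_apr`.
#' @export
gatekeeper_profile <- function(seqs, aprs) {
  seqs <- as_sequence_set(seqs)
  positions <- c("pb3", "pb2", "pb1", "pe1", "pe2", "pe3")
  counts <- stats::setNames(integer(6), positions)
  totals <- stats::setNames(integer(6), positions)
  per_apr <- integer(nrow(aprs))
  gk <- gatekeeper_residues()
  for (i in seq_len(nrow(aprs))) {
    s <- seqs[[aprs$seq_id[i]]]
    if (is.null(s) || is.na(s)) stop("APR refers to unknown sequence id: ", aprs$seq_id[i])
    L <- nchar(s)
    if (aprs$end[i] > L) stop("APR interval extends beyond sequence length")
    offs <- stats::setNames(c(-3L, -2L, -1L, 1L, 2L, 3L), positions)
    anchor <- stats::setNames(c(rep(aprs$start[i], 3), rep(aprs$end[i], 3)), positions)
    for (p in positions) {
      pos <- anchor[[p]] + offs[[p]]
      if (pos >= 1L && pos <= L) {
        totals[[p]] <- totals[[p]] + 1L
        if (substr(s, pos, pos) %in% gk) {
          counts[[p]] <- counts[[p]] + 1L
          per_apr[i] <- per_apr[i] + 1L
        }
      }
    }
  }
  freq <- ifelse(totals > 0, 100 * counts / totals, NA_real_)
  list(position_counts = counts, position_totals = totals,
       position_freq_pct = freq, per_apr_counts = per_apr,
       mean_per_apr = if (nrow(aprs)) mean(per_apr) else NA_real_)
}

# Kyte-Doolittle hydropathy index; the surrogate predictor's default scale.
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Surrogate APR predictor (sliding hydropathy window)
#'
#' A deliberately simple stand-in for dedicated APR predictors, used to
#' exercise the pipeline on synthetic data: the mean Kyte-Doolittle
#' hydropathy is computed for every window of `window` residues, windows with
#' mean score >= `threshold` are merged into maximal intervals, and the total
#' aggregation score is the sum of the above-threshold window scores. All
#' output intervals carry `source = "surrogate"`; no claim is made that this
#' reproduces the statistics of dedicated predictors.
#'
#' @param seq Single sequence (named character vector of length 1 accepted).
#' @param window Window length (default 6).
#' @param threshold Minimum mean window score for a window to count.
#' @return List with `seq_id`, `seqlen`, `total_score`, `propensity`
#'   (score/length) and `intervals` (an `apr_table`, possibly empty).
#' @export
surrogate_predict_aprs <- function(seq, window = 6, threshold = 2.0) {
  window <- assert_count(window, "window")
  id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  s <- assert_residues(unname(seq[1]))
  L <- nchar(s)
  empty <- apr_intervals(data.frame(seq_id = character(), start = integer(),
                                    end = integer(), source = character(),
                                    score = numeric()), min_len = window)
  if (window > L || (is.infinite(threshold) && threshold > 0)) {
    return(list(seq_id = id, seqlen = L, total_score = 0,
                propensity = 0, intervals = empty))
  }
  kd <- kyte_doolittle()
  vals <- kd[strsplit(s, "", fixed = TRUE)[[1]]]
  wmeans <- as.numeric(stats::filter(vals, rep(1 / window, window), sides = 1))
  wmeans <- wmeans[window:L]           # wmeans[i] = mean of window starting at i-window+1
  starts <- seq_len(L - window + 1L)
  hit <- wmeans >= threshold
  if (!any(hit)) {
    return(list(seq_id = id, seqlen = L, total_score = 0,
                propensity = 0, intervals = empty))
  }
  total <- sum(wmeans[hit])
  # merge overlapping/adjacent hit windows into maximal intervals
  hs <- starts[hit]
  he <- hs + window - 1L
  brk <- c(TRUE, hs[-1] > he[-length(he)] + 0L)  # new run when next window start > prev end
  grp <- cumsum(brk)
  iv <- data.frame(
    seq_id = id,
    start = tapply(hs, grp, min),
    end = tapply(he, grp, max),
    source = "surrogate",
    score = as.numeric(tapply(wmeans[hit], grp, sum)))
  list(seq_id = id, seqlen = L, total_score = total,
       propensity = total / L,
       intervals = apr_intervals(iv, min_len = window))
}

#' Summary statistics for a set of APR predictions
#'
#' Averages reported per dataset: the percentage of sequences with at least
#' one APR, and, over APR-containing sequences only, the mean/sd sequence
#' length, total APR count, mean/sd APR length, and mean/sd APR residue
#' proportion.
#'
#' @param predictions List of prediction results as returned by
#'   [surrogate_predict_aprs()] (elements need `seqlen` and `intervals`).
#' @return One-row `data.frame`; fields other than `pct_with_apr` and
#'   `n_sequences` are `NA` when no sequence has an APR.
#' @export
dataset_summary <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 1L)
  n_apr <- vapply(predictions, function(p) nrow(p$intervals), integer(1))
  has <- n_apr > 0L
  out <- data.frame(
    n_sequences = length(predictions),
    pct_with_apr = 100 * mean(has),
    mean_seqlen = NA_real_, sd_seqlen = NA_real_,
    n_aprs = sum(n_apr),
    mean_apr_len = NA_real_, sd_apr_len = NA_real_,
    mean_apr_prop = NA_real_, sd_apr_prop = NA_real_)
  if (!any(has)) return(out)
  lens <- vapply(predictions[has], `[[`, numeric(1), "seqlen")
  apr_lens <- unlist(lapply(predictions[has],
                            function(p) p$intervals$end - p$intervals$start + 1L))
  props <- vapply(predictions[has],
                  function(p) apr_proportion(p$seqlen, p$intervals), numeric(1))
  out$mean_seqlen <- mean(lens)
  out$sd_seqlen <- if (length(lens) > 1) stats::sd(lens) else 0
  out$mean_apr_len <- mean(apr_lens)
  out$sd_apr_len <- if (length(apr_lens) > 1) stats::sd(apr_lens) else 0
  out$mean_apr_prop <- mean(props)
  out$sd_apr_prop <- if (length(props) > 1) stats::sd(props) else 0
  out
}
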