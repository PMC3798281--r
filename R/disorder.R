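# Order/disorder vs APR membership: contingency table, odds ratios,
# association tests.

#' Read / write disorder interval tables
#'
#' Disorder annotations use the same TSV dialect as APR tables: `seq_id`,
#' `start`, `end` with 1-based inclusive coordinates (an optional `state`
#' column is ignored on input; all rows are taken as disordered intervals).
#' Residues not covered by any interval are assumed ordered.
#'
#' @param path File path.
#' @param disorder Data frame with `seq_id`, `start`, `end`.
#' @return `read_disorder_tsv` returns a validated data frame.
#' @export
read_disorder_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("disorder table requires columns: ", paste(need, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) && (any(df$start < 1L) || any(df$end < df$start)))
    stop("disorder intervals must satisfy 1 <= start <= end")
  df[c("seq_id", "start", "end")]
}

#' @rdname read_disorder_tsv
#' @export
write_disorder_tsv <- function(disorder, path) {
  utils::write.table(disorder, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-sequence logical mask from an interval table (TRUE inside an interval).
interval_mask <- function(L, starts, ends, what = "interval") {
  m <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > L)
      stop(what, " annotation extends beyond sequence length (", ends[i], " > ", L, ")")
    m[starts[i]:ends[i]] <- TRUE
  }
  m
}

#' Build the 2x2 APR x disorder contingency table
#'
#' Every residue of every sequence is classified once as inside/outside an APR
#' and disordered/ordered. Overlapping disorder intervals are merged with a
#' warning; annotations beyond sequence bounds are an error.
#'
#' @param seqs Named character vector of sequences.
#' @param aprs `apr_table`.
#' @param disorder Disorder interval data frame (`seq_id`, `start`, `end`).
#' @return Object of class `contingency_table`: a named list of counts
#'   `in_dis`, `in_ord`, `out_dis`, `out_ord` plus `total`.
#' @export
build_contingency <- function(seqs, aprs, disorder) {
  seqs <- as_sequence_set(seqs)
  cells <- c(in_dis = 0L, in_ord = 0L, out_dis = 0L, out_ord = 0L)
  warned <- FALSE
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    a <- aprs[aprs$seq_id == id, , drop = FALSE]
    d <- disorder[disorder$seq_id == id, , drop = FALSE]
    if (!warned && nrow(d) > 1) {
      o <- order(d$start)
      if (any(d$start[o][-1] <= d$end[o][-nrow(d)])) {
        warning("overlapping disorder intervals merged")
        warned <- TRUE
      }
    }
    in_apr <- interval_mask(L, a$start, a$end, "APR")
    dis <- interval_mask(L, d$start, d$end, "disorder")
    cells["in_dis"] <- cells["in_dis"] + sum(in_apr & dis)
    cells["in_ord"] <- cells["in_ord"] + sum(in_apr & !dis)
    cells["out_dis"] <- cells["out_dis"] + sum(!in_apr & dis)
    cells["out_ord"] <- cells["out_ord"] + sum(!in_apr & !dis)
  }
  contingency_table(cells["in_dis"], cells["in_ord"],
                    cells["out_dis"], cells["out_ord"])
}

#' Construct a 2x2 contingency table of residue counts
#'
#' @param in_dis,in_ord Residues inside APRs that are disordered / ordered.
#' @param out_dis,out_ord Residues outside APRs that are disordered / ordered.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(in_dis, in_ord, out_dis, out_ord) {
  x <- c(in_dis = in_dis, in_ord = in_ord,
         out_dis = out_dis, out_ord = out_ord)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  out <- as.list(as.numeric(x))
  names(out) <- names(x)
  out$total <- sum(unlist(out))
  class(out) <- "contingency_table"
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- as.matrix.contingency_table(x)
  cat("2x2 residue contingency table (rows: APR membership; cols: disorder)\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$in_dis, x$in_ord, x$out_dis, x$out_ord), nrow = 2, byrow = TRUE,
         dimnames = list(c("in_apr", "out_apr"), c("disordered", "ordered")))
}

#' Odds ratio of APR membership by structural order
#'
#' In the `"ordered"` orientation (the default) the odds that an ordered
#' residue is inside an APR are divided by the odds that a disordered residue
#' is: `(in_ord / out_ord) / (in_dis / out_dis)`. The `"disordered"`
#' orientation returns the reciprocal.
#'
#' @param t A `contingency_table`.
#' @param orientation `"ordered"` or `"disordered"`.
#' @param continuity Add 0.5 to all four cells (use when a cell is zero).
#' @return Single positive number.
#' @export
odds_ratio <- function(t, orientation = c("ordered", "disordered"),
                       continuity = FALSE) {
  orientation <- match.arg(orientation)
  cells <- c(t$in_dis, t$in_ord, t$out_dis, t$out_ord)
  if (continuity) cells <- cells + 0.5
  if (any(cells == 0))
    stop("zero cell: odds ratio undefined (set continuity = TRUE for a ",
         "0.5 continuity correction)")
  or <- (cells[2] / cells[4]) / (cells[1] / cells[3])
  if (orientation == "disordered") 1 / or else or
}

#' Independence tests for the contingency table
#'
#' Pearson's chi-square test of independence plus an exact test. The exact
#' test is the two-sided Fisher test for tables with total count <=
#' `exact_max`; for larger tables the hypergeometric tail is effectively
#' degenerate numerically and the chi-square p-value is reported as the
#' exact-test slot with `exact_method = "chi-square approximation"`.
#'
#' @param t A `contingency_table`.
#' @param exact_max Largest total count for which the exact hypergeometric
#'   test is computed (default 1e5).
#' @return List with `chisq_stat`, `chisq_p`, `exact_p`, `exact_method`.
#' @export
association_tests <- function(t, exact_max = 1e5) {
  m <- as.matrix.contingency_table(t)
  if (sum(m) == 0) stop("empty contingency table")
  cs <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (sum(m) <= exact_max) {
    ep <- stats::fisher.test(m)$p.value
    method <- "fisher exact (two-sided)"
  } else {
    ep <- cs$p.value
    method <- "chi-square approximation"
  }
  list(chisq_stat = unname(cs$statistic), chisq_p = cs$p.value,
       exact_p = ep, exact_method = method)
}
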