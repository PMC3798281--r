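# Homologue-alignment identity filtering and APR conservation scoring.

#' Coerce to a validated alignment set
#'
#' An alignment set is a named character vector of equal-length aligned rows
#' using `-` as the gap character; the first row is the designated parent
#' (typically the structure-derived sequence the APRs were predicted on).
#'
#' @param rows Named character vector of aligned rows (or `AAStringSet`).
#' @return Named character vector of class `alignment_set`.
#' @export
as_alignment_set <- function(rows) {
  if (methods::is(rows, "XStringSet")) {
    nm <- names(rows)
    rows <- as.character(rows)
    names(rows) <- nm
  }
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows))) names(rows) <- sprintf("row%03d", seq_along(rows))
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("aligned rows must all have the same length")
  chars <- unique(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE))
  bad <- setdiff(chars, c(aa_alphabet(), "-"))
  if (length(bad))
    stop("alignment contains non-standard characters: ", paste(bad, collapse = ", "))
  class(rows) <- c("alignment_set", "character")
  rows
}

#' Read a multiple sequence alignment
#'
#' Aligned FASTA is read with `Biostrings`; Clustal `.aln` files are read with
#' `seqinr` when that package is installed. The first record is taken as the
#' parent row.
#'
#' @param path File path.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `alignment_set`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    return(as_alignment_set(Biostrings::readAAStringSet(path)))
  }
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("reading Clustal alignments requires the 'seqinr' package")
  aln <- seqinr::read.alignment(path, format = "clustal")
  rows <- toupper(unlist(aln$seq))
  names(rows) <- aln$nam
  as_alignment_set(rows)
}

#' Percent identity between two aligned rows
#'
#' Identity is counted over columns where both rows are non-gap:
#' `100 * identical columns / mutually non-gap columns`.
#'
#' @param a,b Aligned rows of equal length.
#' @return Percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(a[[1]], "", fixed = TRUE)[[1]]
  cb <- strsplit(b[[1]], "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("rows differ in aligned length")
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no mutually non-gap columns: identity undefined")
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' Filter alignment rows by identity to the parent
#'
#' Retains the parent (always) plus rows whose identity to the parent is at
#' least `min_identity` and, when `drop_identical`, strictly below 100.
#' Mirrors the homologue-selection step that deletes weak hits and removes
#' exact duplicates of the query before conservation analysis.
#'
#' @param aln `alignment_set` (first row = parent).
#' @param min_identity Minimum percent identity to the parent (default 80).
#' @param drop_identical Drop rows 100% identical to the parent (default
#'   `TRUE`).
#' @return Filtered `alignment_set`; a warning is issued when no homologue
#'   survives.
#' @export
filter_homologues <- function(aln, min_identity = 80, drop_identical = TRUE) {
  aln <- as_alignment_set(aln)
  if (length(aln) == 1L) {
    warning("alignment has no homologue rows")
    return(aln)
  }
  parent <- aln[1]
  ident <- vapply(aln[-1], function(r) pairwise_identity(parent, r), numeric(1))
  keep <- ident >= min_identity
  if (drop_identical) keep <- keep & ident < 100
  if (!any(keep)) warning("no homologue passed the identity filter")
  as_alignment_set(c(parent, aln[-1][keep]))
}

# Map 1-based ungapped parent residue indices to alignment column numbers.
parent_columns <- function(parent_row) {
  chars <- strsplit(parent_row, "", fixed = TRUE)[[1]]
  which(chars != "-")
}

#' APR conservation percentage in a homologue alignment
#'
#' Each parent APR is projected onto every row via the parent's aligned
#' columns; the row's residues at those columns (gaps removed) form the APR
#' variant in that homologue. An APR is conserved between two rows when the
#' variants are identical. With `n_total` = (number of APRs) x (number of
#' rows) and `n_uniq` = total number of distinct variants summed over APRs,
#' the conservation percentage is `100 * (n_total - n_uniq) / n_total`,
#' which approaches 100 for large perfectly conserved families and is 0 when
#' every row differs from every other at every APR.
#'
#' @param aln `alignment_set` with >= 2 rows, first row = parent.
#' @param parent_aprs `apr_table` with coordinates on the ungapped parent.
#' @return List with `conservation_pct`, `n_total`, `n_uniq`, and a per-APR
#'   `detail` data frame (`start`, `end`, `n_variants`, `parent_variant`).
#' @export
apr_conservation <- function(aln, parent_aprs) {
  aln <- as_alignment_set(aln)
  if (length(aln) < 2L)
    stop("conservation is undefined for a single-row alignment")
  if (nrow(parent_aprs) == 0L)
    stop("no parent APRs supplied")
  cols <- parent_columns(aln[[1]])
  plen <- length(cols)
  if (any(parent_aprs$end > plen))
    stop("APR interval extends beyond ungapped parent length")
  rows <- strsplit(unclass(aln), "", fixed = TRUE)
  variants_of <- function(start, end) {
    cc <- cols[start:end]
    vapply(rows, function(r) paste(r[cc][r[cc] != "-"], collapse = ""), character(1))
  }
  n_rows <- length(aln)
  n_apr <- nrow(parent_aprs)
  n_uniq_per <- integer(n_apr)
  parent_var <- character(n_apr)
  for (i in seq_len(n_apr)) {
    v <- variants_of(parent_aprs$start[i], parent_aprs$end[i])
    n_uniq_per[i] <- length(unique(v))
    parent_var[i] <- v[[1]]
  }
  n_total <- n_apr * n_rows
  n_uniq <- sum(n_uniq_per)
  list(conservation_pct = 100 * (n_total - n_uniq) / n_total,
       n_total = n_total, n_uniq = n_uniq,
       detail = data.frame(start = parent_aprs$start, end = parent_aprs$end,
                           n_variants = n_uniq_per,
                           parent_variant = parent_var))
}

#' Mean sequence identity of an alignment
#'
#' Both conventions are reported because either may be meant by "average
#' sequence identity": parent-vs-each-homologue, and all-pairs.
#'
#' @param aln `alignment_set` with >= 2 rows.
#' @return List with `parent_mean` and `all_pairs_mean` (percent).
#' @export
mean_identity <- function(aln) {
  aln <- as_alignment_set(aln)
  if (length(aln) < 2L) stop("need at least two rows")
  parent <- aln[1]
  pm <- mean(vapply(aln[-1], function(r) pairwise_identity(parent, r), numeric(1)))
  pairs <- utils::combn(length(aln), 2)
  ap <- mean(apply(pairs, 2, function(ix) pairwise_identity(aln[ix[1]], aln[ix[2]])))
  list(parent_mean = pm, all_pairs_mean = ap)
}
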