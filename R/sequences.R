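# Randomized, scrambled and partitioned sequence datasets, and
# amino-acid composition statistics.

#' Coerce to a validated sequence set
#'
#' A sequence set is a named character vector of residue strings over the
#' 20-letter alphabet. `Biostrings::AAStringSet` objects are accepted and
#' converted.
#'
#' @param x Named character vector or `AAStringSet`.
#' @param drop_ambiguous Drop non-standard residue codes (B, J, O, U, X, Z,
#'   ...) instead of raising an error. Default `FALSE`: all downstream
#'   statistics assume the 20-letter alphabet.
#' @return Named character vector of validated sequences.
#' @export
as_sequence_set <- function(x, drop_ambiguous = FALSE) {
  if (methods::is(x, "XStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  stopifnot(is.character(x), length(x) >= 1L)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- sprintf("seq%04d", seq_along(x))
  vapply(x, assert_residues, character(1), drop_ambiguous = drop_ambiguous)
}

#' Read and write sequence sets as FASTA
#'
#' Thin wrappers over `Biostrings` that return/accept the package's named
#' character-vector sequence sets.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @param drop_ambiguous Passed to [as_sequence_set()].
#' @return `read_fasta_set` returns a named character vector;
#'   `write_fasta_set` returns `path` invisibly.
#' @export
read_fasta_set <- function(path, drop_ambiguous = FALSE) {
  as_sequence_set(Biostrings::readAAStringSet(path), drop_ambiguous = drop_ambiguous)
}

#' @rdname read_fasta_set
#' @export
write_fasta_set <- function(seqs, path) {
  seqs <- as_sequence_set(seqs)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Generate random sequences with uniform residue usage
#'
#' Each residue is drawn independently with probability 5% per amino-acid
#' type, the construction behind a 10,000 x 100-residue uniform-composition
#' null dataset.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @return Named character vector of `n` sequences.
#' @export
generate_uniform_random <- function(n, length, seed) {
  p <- rep(1 / 20, 20)
  names(p) <- aa_alphabet()
  generate_composition_matched(n, length, p, seed)
}

#' Generate random sequences matching a target composition
#'
#' Residues are drawn i.i.d. from `composition`, e.g. the folded-protein
#' reference composition of [reference_composition()], yielding
#' composition-realistic but pattern-free null sequences.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence.
#' @param composition Named numeric vector of 20 frequencies summing to 1.
#' @param seed Integer seed.
#' @return Named character vector of `n` sequences.
#' @export
generate_composition_matched <- function(n, length, composition, seed) {
  n <- assert_count(n, "n")
  length <- assert_count(length, "length")
  composition <- assert_composition(composition)
  draws <- with_seed(seed,
    sample(aa_alphabet(), n * length, replace = TRUE, prob = composition))
  seqs <- vapply(seq_len(n),
                 function(i) paste(draws[((i - 1L) * length + 1L):(i * length)], collapse = ""),
                 character(1))
  names(seqs) <- sprintf("rand%05d", seq_len(n))
  seqs
}

#' Scramble a sequence by random reassignment
#'
#' Randomly selected residues of the parent are assigned to randomly selected
#' positions of the scrambled copy; if a selected target position is already
#' occupied, new positions are drawn until an unoccupied one is found. Every
#' copy therefore has exactly the parent's length and residue multiset but
#' randomized patterning.
#'
#' @param seq Single residue string (or length-1 named character vector).
#' @param copies Number of scrambled copies.
#' @param seed Integer seed.
#' @return Named character vector of `copies` scrambled sequences.
#' @export
scramble_sequence <- function(seq, copies, seed) {
  copies <- assert_count(copies, "copies")
  id <- if (!is.null(names(seq))) names(seq)[1] else "parent"
  s <- assert_residues(unname(seq[1]))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- with_seed(seed, vapply(seq_len(copies), function(i) {
    src_order <- sample.int(L)        # order in which parent residues are moved
    target <- character(L)
    occupied <- logical(L)
    for (j in src_order) {
      repeat {
        pos <- sample.int(L, 1L)
        if (!occupied[pos]) break
      }
      occupied[pos] <- TRUE
      target[pos] <- chars[j]
    }
    paste(target, collapse = "")
  }, character(1)))
  names(out) <- sprintf("%s_scramble%03d", id, seq_len(copies))
  out
}

#' Pooled amino-acid composition of a sequence set
#'
#' @param seqs Named character vector of sequences.
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
compute_composition <- function(seqs) {
  seqs <- as_sequence_set(seqs)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  if (length(chars) == 0L) stop("no residues in input")
  counts <- table(factor(chars, levels = aa_alphabet()))
  p <- as.numeric(counts) / length(chars)
  names(p) <- aa_alphabet()
  p
}

#' Goodness-of-fit chi-square between two compositions
#'
#' Both profiles are converted to counts per `scale` residues (default 1000)
#' and the one-sample goodness-of-fit statistic
#' \eqn{\sum_k (O_k - E_k)^2 / E_k} is returned over the 20 residue types,
#' with `expected` as the reference. The statistic is not symmetric in its
#' arguments. Categories with zero expected frequency are dropped when the
#' observed frequency is also zero and are an error otherwise. Under this
#' convention the folded-protein reference composition against the uniform 5%
#' profile gives 160.84.
#'
#' @param observed,expected Composition vectors (20 frequencies summing to 1).
#' @param scale Pseudo-count total each profile is scaled to.
#' @return The chi-square statistic (single number).
#' @export
composition_chi_square <- function(observed, expected, scale = 1000) {
  observed <- assert_composition(observed)
  expected <- assert_composition(expected)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  if (any(expected == 0 & observed > 0))
    stop("observed mass on a zero-expected category: chi-square degenerate")
  keep <- expected > 0
  o <- observed[keep] * scale
  e <- expected[keep] * scale
  sum((o - e)^2 / e)
}

#' Split sequences into k composition clusters
#'
#' k-means clustering of per-sequence 20-dimensional amino-acid composition
#' vectors, the procedure used to divide a natural corpus into
#' composition-distinct halves that both keep natural residue patterning.
#'
#' @param seqs Named character vector of sequences.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed; `stats::kmeans` is run with a fixed seed and
#'   multiple restarts so the partition is deterministic.
#' @return Named integer vector of cluster labels (1..k), names = sequence ids.
#' @export
kmeans_composition_split <- function(seqs, k = 2, seed = 1) {
  seqs <- as_sequence_set(seqs)
  k <- assert_count(k, "k")
  if (k > length(seqs)) stop("k exceeds the number of sequences")
  feats <- t(vapply(seqs, function(s) compute_composition(s), numeric(20)))
  cl <- if (k == 1L) rep(1L, length(seqs)) else with_seed(seed,
    stats::kmeans(feats, centers = k, nstart = 25, iter.max = 100)$cluster)
  names(cl) <- names(seqs)
  cl
}

#' Two-sample t-test between aggregation-propensity distributions
#'
#' @param a,b Numeric vectors of per-sequence propensities (length >= 2).
#' @param var_equal Use the pooled-variance test (`TRUE`) or Welch's
#'   unequal-variance test (`FALSE`, the default).
#' @return List with `statistic`, `p_value`, `df`, `method`. Two identical
#'   zero-variance samples return the degenerate `t = 0`, `p = 1`.
#' @export
compare_propensity_distributions <- function(a, b, var_equal = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
    return(list(statistic = 0, p_value = 1, df = NA_real_,
                method = "degenerate (both samples constant and equal)"))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
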