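# Amino-acid alphabet, reference compositions, shared validators.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes in the fixed order used by all composition vectors in this
#' package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Reference amino-acid compositions
#'
#' Compositions of two curated corpora used as realistic backgrounds: a set of
#' 495 small monomeric globular proteins with high-resolution crystal
#' structures, and a set of 536 intrinsically disordered proteins. Returned as
#' frequencies summing to 1 over [aa_alphabet()].
#'
#' @param which `"globular"` (the 495-protein folded set, the default) or
#'   `"idp"` (the disordered set).
#' @return Named numeric vector of 20 frequencies.
#' @export
reference_composition <- function(which = c("globular", "idp")) {
  which <- match.arg(which)
  pct <- switch(which,
    globular = c(A = 7.5, C = 1.8, D = 5.8, E = 7.5, F = 3.8, G = 7.1,
                 H = 2.8, I = 5.4, K = 6.5, L = 8.7, M = 2.3, N = 4.3,
                 P = 4.4, Q = 3.8, R = 5.1, S = 6.2, T = 5.3, V = 6.9,
                 W = 1.4, Y = 3.4),
    idp = c(A = 7.5, C = 1.4, D = 5.8, E = 7.7, F = 3.3, G = 6.9,
            H = 2.2, I = 4.6, K = 6.5, L = 8.5, M = 2.3, N = 4.3,
            P = 5.8, Q = 4.9, R = 5.2, S = 7.9, T = 5.6, V = 6.0,
            W = 1.0, Y = 2.7))
  # printed percentages carry rounding error (the idp set sums to 100.1);
  # renormalize so the profile is a valid frequency vector
  p <- pct[aa_alphabet()]
  p / sum(p)
}

#' Gate-keeper residues
#'
#' The five aggregation-opposing residue types (Asp, Glu, Lys, Arg, Pro)
#' commonly found flanking aggregation prone regions.
#'
#' @return Character vector of one-letter codes.
#' @export
gatekeeper_residues <- function() c("D", "E", "K", "R", "P")

# ---- internal helpers -------------------------------------------------------

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_residues <- function(x, drop_ambiguous = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% aa_alphabet())
  if (any(bad)) {
    if (drop_ambiguous) {
      chars <- chars[!bad]
      if (length(chars) == 0L)
        stop("sequence contains no standard residues after dropping ambiguous codes")
      return(paste(chars, collapse = ""))
    }
    stop("non-standard residue code(s): ",
         paste(unique(chars[bad]), collapse = ", "),
         " (use drop_ambiguous = TRUE to discard them)")
  }
  x
}

assert_composition <- function(p, tol = 1e-9) {
  stopifnot(is.numeric(p), length(p) == 20L)
  if (is.null(names(p))) names(p) <- aa_alphabet()
  p <- p[aa_alphabet()]
  if (anyNA(p) || any(p < 0))
    stop("composition must be 20 non-negative frequencies named by amino acid")
  if (abs(sum(p) - 1) > tol)
    stop("composition frequencies must sum to 1 (got ", format(sum(p)), ")")
  p
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop("`", name, "` must be an integer >= ", min)
  as.integer(x)
}
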