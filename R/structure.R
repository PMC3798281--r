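# Structure model, PDB IO, and the Shrake-Rupley solvent accessible
# surface area engine.

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
            HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
            PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
            TRP = "W", TYR = "Y")

#' Van der Waals radii used by the SASA engine
#'
#' Bondi (1964) radii for the heavy elements found in proteins.
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

#' Build a structure model from an atom table
#'
#' The structure model is the package's container for 3D coordinates: an atom
#' data frame (`chain`, `resno`, `icode`, `resname` 3-letter or 1-letter,
#' `element`, `x`, `y`, `z`; heavy atoms only) plus a derived residue table
#' carrying the 1-based `seq_index` of each residue within its chain (file
#' order).
#'
#' @param atoms Data frame as above; hydrogens are dropped.
#' @return Object of class `structure_model` with elements `atoms` and
#'   `residues`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table requires columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$element <- toupper(as.character(atoms$element))
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("structure has no heavy atoms")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$resname <- toupper(as.character(atoms$resname))
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  first <- !duplicated(key)
  res <- data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
                    icode = atoms$icode[first], resname = atoms$resname[first],
                    stringsAsFactors = FALSE)
  res$aa <- ifelse(nchar(res$resname) == 1L & res$resname %in% aa_alphabet(),
                   res$resname,
                   unname(AA3TO1[res$resname]))
  res$seq_index <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along)
  atoms$res_key <- key
  res$res_key <- paste(res$chain, res$resno, res$icode, sep = "|")
  rownames(atoms) <- NULL
  rownames(res) <- NULL
  structure(list(atoms = atoms, residues = res), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "heavy atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Uses `bio3d::read.pdb`; keeps the first model of multi-model files, drops
#' hydrogens, resolves alternate locations to the first listed conformer, and
#' drops heteroatoms (ligands, waters) unless `include_het = TRUE`.
#'
#' @param path PDB file path.
#' @param include_het Keep HETATM records as occluders.
#' @return A `structure_model`.
#' @export
read_structure_pdb <- function(path, include_het = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$alt %in% c(NA, "", "A"), , drop = FALSE]
  if (!include_het) a <- a[a$type == "ATOM", , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*", "", a$elety), 1, 1)
  }
  elem <- ifelse(is.na(elem) | elem == "",
                 substr(gsub("[0-9]", "", a$elety), 1, 1), elem)
  structure_model(data.frame(
    chain = a$chain, resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = a$resid, element = elem,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write a structure model to a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  resname3 <- ifelse(nchar(a$resname) == 1L,
                     names(AA3TO1)[match(a$resname, AA3TO1)], a$resname)
  resname3[is.na(resname3)] <- "UNK"
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(a[c("x", "y", "z")]))),
                   type = "ATOM", resno = a$resno, resid = resname3,
                   chain = a$chain, elety = if (!is.null(a$name)) a$name else a$element,
                   elesy = a$element)
  invisible(path)
}

# Deterministic near-uniform unit-sphere point set (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Expanded (vdW + probe) radius per atom.
expanded_radii <- function(elements, probe, fallback_radius = NULL) {
  r <- vdw_radii()[toupper(elements)]
  if (anyNA(r)) {
    missing <- unique(toupper(elements)[is.na(r)])
    if (is.null(fallback_radius))
      stop("no van der Waals radius for element(s): ",
           paste(missing, collapse = ", "),
           " (supply fallback_radius to use a default)")
    r[is.na(r)] <- fallback_radius
  }
  unname(r) + probe
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's solvent-expanded sphere (van der Waals radius
#' plus probe radius) is sampled with a deterministic Fibonacci point set; a
#' sample point is accessible when it lies outside every other atom's
#' expanded sphere. The atom's ASA is the accessible fraction times
#' `4 * pi * (r + probe)^2`, so an isolated atom recovers the closed form
#' exactly.
#'
#' @param model A `structure_model`.
#' @param probe Probe (solvent) radius in Angstrom, default 1.4.
#' @param points Sample points per atom, default 960.
#' @param fallback_radius Optional radius (Angstrom) for elements missing from
#'   [vdw_radii()]; without it an unknown element is an error.
#' @return Data frame (class `asa_table`): one row per residue with `chain`,
#'   `resno`, `icode`, `aa`, `seq_index`, `asa` (Angstrom^2). Attributes
#'   `atom_asa`, `probe`, `points`, `radius_set` record the calculation.
#' @export
compute_asa <- function(model, probe = 1.4, points = 960, fallback_radius = NULL) {
  stopifnot(inherits(model, "structure_model"), probe >= 0, points >= 12)
  a <- model$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[c("x", "y", "z")])
  R <- expanded_radii(a$element, probe, fallback_radius)
  P <- sphere_points(points)
  maxR <- max(R)
  atom_asa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      atom_asa[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- P * R[i]
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    occluded <- logical(points)
    for (j in nb) {
      if (all(occluded)) break
      free <- !occluded
      dd <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
            (pts[free, 3] - xyz[j, 3])^2
      occluded[free] <- dd < R[j]^2
    }
    atom_asa[i] <- (sum(!occluded) / points) * 4 * pi * R[i]^2
  }
  res <- model$residues
  res$asa <- as.numeric(tapply(atom_asa, factor(a$res_key, levels = res$res_key), sum))
  res$asa[is.na(res$asa)] <- 0
  out <- res[c("chain", "resno", "icode", "aa", "seq_index", "asa")]
  attr(out, "atom_asa") <- atom_asa
  attr(out, "probe") <- probe
  attr(out, "points") <- points
  attr(out, "radius_set") <- "Bondi (1964)"
  class(out) <- c("asa_table", "data.frame")
  out
}

#' Dataset-average ASA per residue type
#'
#' Pools one or more per-residue ASA tables and returns, for each amino-acid
#' type, the mean ASA over all residues of that type in the corpus.
#'
#' @param tables A single `asa_table` or list of them.
#' @return Named numeric vector over [aa_alphabet()]; types absent from the
#'   corpus are `NA`.
#' @export
average_asa_by_type <- function(tables) {
  if (inherits(tables, "asa_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)[c("aa", "asa")]))
  if (nrow(df) == 0L) stop("no residues supplied")
  means <- tapply(df$asa, factor(df$aa, levels = aa_alphabet()), mean)
  out <- as.numeric(means)
  names(out) <- aa_alphabet()
  out
}
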