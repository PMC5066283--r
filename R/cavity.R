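#' Construct a binding-site cavity model
#'
#' Pairs a protein's heavy atoms with a probe-point cloud covering the
#' binding-site surface (for example a docking protomol). The cavity
#' "surface" is the set of heavy atoms strictly closer than `cutoff`
#' (default 4 Angstroms) to at least one probe point — the atoms in close
#' contact with a ligand filling the site.
#'
#' @param atoms Data frame with columns `element` and `x`, `y`, `z`
#'   (Angstroms); hydrogens are not allowed (heavy atoms only).
#' @param probes Numeric matrix (k x 3) of probe coordinates.
#' @param cutoff Contact distance in Angstroms, > 0.
#' @param exposure Optional externally supplied openness measure in
#'   \[0, 1\] (this package does not compute it).
#' @return A `cavity_model` object.
#' @export
cavity_model <- function(atoms, probes, cutoff = 4, exposure = NULL) {
  req <- c("element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms lack column(s): ", paste(missing_cols, collapse = ", "))
  probes <- as.matrix(probes)
  if (ncol(probes) != 3) stop("probes must be a k x 3 coordinate matrix")
  coords <- as.matrix(atoms[c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(coords))) stop("non-finite atom coordinates")
  if (nrow(probes) && !all(is.finite(probes))) stop("non-finite probe coordinates")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (any(toupper(atoms$element) == "H")) stop("hydrogens are not heavy atoms")
  structure(list(atoms = atoms, probes = probes, cutoff = cutoff,
                 exposure = exposure),
            class = "cavity_model")
}

#' @export
print.cavity_model <- function(x, ...) {
  cat("<cavity_model>", nrow(x$atoms), "heavy atoms,", nrow(x$probes),
      "probe points, cutoff", x$cutoff, "A\n")
  invisible(x)
}

# Minimum distance of each atom to any probe point (brute force; cavities
# are a few thousand atoms at most, so O(atoms x probes) is fine).
min_probe_distance <- function(cavity) {
  coords <- as.matrix(cavity$atoms[c("x", "y", "z")])
  if (!nrow(coords)) return(numeric(0))
  if (!nrow(cavity$probes)) stop("empty probe set")
  a2 <- rowSums(coords^2)
  p2 <- rowSums(cavity$probes^2)
  d2 <- outer(a2, p2, `+`) - 2 * coords %*% t(cavity$probes)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Atoms forming the cavity surface
#'
#' Heavy atoms whose minimum distance to any probe point is strictly less
#' than the cutoff.
#'
#' @param cavity A [cavity_model()].
#' @return The subset of the atom data frame on the surface, with an
#'   added `min_dist` column.
#' @export
surface_atoms <- function(cavity) {
  stopifnot(inherits(cavity, "cavity_model"))
  d <- min_probe_distance(cavity)
  out <- cavity$atoms[d < cavity$cutoff, , drop = FALSE]
  out$min_dist <- d[d < cavity$cutoff]
  out
}

#' Fraction of carbon atoms at the cavity surface (FCA)
#'
#' A hydrophobicity proxy: the fraction of carbons among the heavy atoms
#' in contact with the probe surface. The complement 1 - FCA (see
#' [hydrophilicity()]) measures how hydrophilic the site is.
#'
#' @param cavity A [cavity_model()].
#' @return Fraction in \[0, 1\].
#' @export
fca <- function(cavity) {
  surf <- surface_atoms(cavity)
  if (!nrow(surf)) stop("empty cavity surface: no atom within the cutoff")
  mean(toupper(surf$element) == "C")
}

#' @rdname fca
#' @export
hydrophilicity <- function(cavity) 1 - fca(cavity)

#' Number of heavy atoms at the cavity surface
#'
#' The total number of possible contacts the site can make with a bound
#' ligand.
#'
#' @param cavity A [cavity_model()].
#' @return Nonnegative integer count.
#' @export
surface_atom_count <- function(cavity) {
  stopifnot(inherits(cavity, "cavity_model"))
  if (!nrow(cavity$atoms)) return(0L)
  nrow(surface_atoms(cavity))
}

#' Read a cavity from PDB (atoms) plus probe points
#'
#' Protein heavy atoms are taken from ATOM/HETATM records via `bio3d`
#' (first alternate location kept, hydrogens dropped); probes come from an
#' XYZ file or a second PDB.
#'
#' @param pdb_path Protein PDB file.
#' @param probe_path Probe file (`.xyz` or `.pdb`).
#' @param cutoff Contact cutoff in Angstroms.
#' @param exposure Optional externally supplied exposure value.
#' @param chains Optional chain filter (character vector).
#' @return A [cavity_model()].
#' @export
read_cavity <- function(pdb_path, probe_path, cutoff = 4, exposure = NULL,
                        chains = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- elem != "H" & (at$alt %in% c("", "A") | is.na(at$alt))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  atoms <- data.frame(id = at$eleno[keep], element = elem[keep],
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      stringsAsFactors = FALSE)
  probes <- if (grepl("\\.pdb$", probe_path, ignore.case = TRUE)) {
    pp <- bio3d::read.pdb(probe_path, verbose = FALSE)$atom
    as.matrix(pp[c("x", "y", "z")])
  } else read_xyz(probe_path)
  cavity_model(atoms, probes, cutoff = cutoff, exposure = exposure)
}

#' Read probe points from an XYZ file
#'
#' Accepts standard XYZ (count line, comment line, then `element x y z`)
#' or a bare whitespace-separated `x y z` table.
#'
#' @param path File path.
#' @return Numeric matrix (k x 3).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 1 && !is.na(suppressWarnings(as.integer(first)))) {
    n <- as.integer(first)
    lines <- lines[seq(3, 2 + n)]
  }
  rows <- strsplit(trimws(lines), "\\s+")
  coords <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r))
    as.numeric(utils::tail(v[!is.na(v)], 3))
  }, numeric(3)))
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Per-target cavity characteristics table
#'
#' @param cavities Named list of [cavity_model()] objects (names are
#'   target ids).
#' @return Data frame: `target_id`, `FCA`, `one_minus_FCA`,
#'   `surface_atom_count` and `exposure` (NA when not supplied).
#' @export
cavity_table <- function(cavities) {
  rows <- Map(function(id, cav) data.frame(
    target_id = id, FCA = fca(cav), one_minus_FCA = hydrophilicity(cav),
    surface_atom_count = surface_atom_count(cav),
    exposure = cav$exposure %||% NA_real_,
    stringsAsFactors = FALSE), names(cavities), cavities)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
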