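# Default valences used to infer implicit hydrogen counts (neutral organic
# subset; elements not listed get 0 implicit hydrogens).
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, As = 3, Se = 2, Br = 1, Sn = 4,
                      Te = 2, I = 1)

# Standard atomic weights (g/mol) for the elements this package handles.
.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.086,
                  P = 30.974, S = 32.06, Cl = 35.453, K = 39.098,
                  Ca = 40.078, As = 74.922, Se = 78.971, Br = 79.904,
                  Sn = 118.71, Te = 127.60, I = 126.904)

#' Construct a molecule from its heavy-atom graph
#'
#' A `molecule` is a connected heavy-atom graph: element symbols plus a
#' bond list with integer orders. Hydrogens are implicit; when `n_h` is
#' not supplied it is inferred from default valences (C4, N3, O2, ...) as
#' `max(0, valence - sum of incident bond orders)`. Formal charges are not
#' modelled. Multi-fragment inputs (salts) are reduced to their largest
#' fragment with a message.
#'
#' @param compound_id Identifier string.
#' @param elements Character vector of heavy-atom element symbols.
#' @param bonds Data frame (or 2-3 column matrix) with columns `a1`, `a2`
#'   (1-based atom indices) and `order` (1 = single, 2 = double,
#'   3 = triple; defaults to 1).
#' @param n_h Optional integer vector of explicit hydrogen counts per atom.
#' @return A `molecule` object with fields `compound_id`, `atoms`
#'   (data frame: `element`, `n_h`), `bonds` and `multi_fragment` flag.
#' @export
molecule <- function(compound_id, elements, bonds = NULL, n_h = NULL) {
  elements <- as.character(elements)
  known <- elements %in% names(.atomic_mass)
  if (!all(known))
    stop("unknown element(s): ", paste(unique(elements[!known]), collapse = ", "))
  if (is.null(bonds) || !NROW(bonds)) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    if (ncol(bonds) == 2) bonds$order <- 1L
    names(bonds) <- c("a1", "a2", "order")
    if (any(bonds$a1 < 1 | bonds$a2 < 1 |
            bonds$a1 > length(elements) | bonds$a2 > length(elements)))
      stop("bond indices out of range")
  }
  multi <- FALSE
  if (length(elements) > 1) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(elements) -
                                          igraph::vcount(g)))
    comp <- igraph::components(g)
    if (comp$no > 1) {
      multi <- TRUE
      main <- which.max(comp$csize)
      keep <- which(comp$membership == main)
      message("molecule '", compound_id, "': ", comp$no,
              " fragments, keeping the largest (", length(keep), " atoms)")
      idx <- match(seq_along(elements), keep)
      bkeep <- bonds$a1 %in% keep & bonds$a2 %in% keep
      bonds <- data.frame(a1 = idx[bonds$a1[bkeep]],
                          a2 = idx[bonds$a2[bkeep]],
                          order = bonds$order[bkeep])
      elements <- elements[keep]
      if (!is.null(n_h)) n_h <- n_h[keep]
    }
  }
  if (is.null(n_h)) {
    bsum <- numeric(length(elements))
    if (nrow(bonds)) {
      for (k in seq_len(nrow(bonds))) {
        bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + bonds$order[k]
        bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + bonds$order[k]
      }
    }
    val <- .default_valence[elements]
    val[is.na(val)] <- 0
    n_h <- pmax(0, val - bsum)
  }
  structure(list(compound_id = as.character(compound_id),
                 atoms = data.frame(element = elements,
                                    n_h = as.integer(n_h),
                                    stringsAsFactors = FALSE),
                 bonds = bonds, multi_fragment = multi),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$compound_id, "|", nrow(x$atoms), "heavy atoms,",
      nrow(x$bonds), "bonds",
      if (x$multi_fragment) "(largest fragment of a multi-fragment input)",
      "\n")
  invisible(x)
}

# Heavy-atom degree (number of heavy neighbours) of every atom.
heavy_degree <- function(mol) {
  deg <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a1, nbins = length(deg))
    t2 <- tabulate(mol$bonds$a2, nbins = length(deg))
    deg <- t1 + t2
  }
  deg
}

mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  g
}

# Logical vector: is each bond part of a ring? (an edge is in a cycle iff
# it is not a bridge)
ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(mol$bonds))
  res[as.integer(br)] <- FALSE
  res
}

#' Convert a ChemmineR SDF to a molecule
#'
#' @param sdf A `ChemmineR::SDF` object.
#' @param compound_id Identifier (defaults to the SDF header title).
#' @return A [molecule()].
#' @export
as_molecule <- function(sdf, compound_id = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SDF conversion requires the 'ChemmineR' package")
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (NROW(bb)) data.frame(a1 = as.integer(bb[, 1]),
                                    a2 = as.integer(bb[, 2]),
                                    order = as.integer(bb[, 3]))
           else NULL
  id <- compound_id %||% unname(ChemmineR::header(sdf)[["Molecule_Name"]])
  heavy <- !(elements %in% c("H", "D", "T"))
  if (!all(heavy)) {
    # fold explicit hydrogens into implicit counts
    nh <- integer(sum(heavy))
    idx <- cumsum(heavy)
    if (!is.null(bonds)) {
      for (k in seq_len(nrow(bonds))) {
        h1 <- !heavy[bonds$a1[k]]; h2 <- !heavy[bonds$a2[k]]
        if (h1 && !h2) nh[idx[bonds$a2[k]]] <- nh[idx[bonds$a2[k]]] + 1L
        if (h2 && !h1) nh[idx[bonds$a1[k]]] <- nh[idx[bonds$a1[k]]] + 1L
      }
      keep <- heavy[bonds$a1] & heavy[bonds$a2]
      bonds <- data.frame(a1 = idx[bonds$a1[keep]], a2 = idx[bonds$a2[keep]],
                          order = bonds$order[keep])
    }
    # implicit H from valence still needed on top of explicit ones: recompute
    m <- molecule(id, elements[heavy], bonds)
    m$atoms$n_h <- pmax(m$atoms$n_h, nh)
    return(m)
  }
  molecule(id, elements, bonds)
}

#' Parse molecules from SMILES strings
#'
#' Delegates SMILES interpretation to Open Babel via
#' `ChemmineR::smiles2sdf` and converts each record to a [molecule()].
#'
#' @param smiles Character vector of SMILES, optionally named by
#'   compound id.
#' @param ids Compound ids (defaults to names or `cmp1..cmpK`).
#' @return Named list of [molecule()] objects.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing requires the 'ChemmineR' and 'ChemmineOB' packages")
  ids <- ids %||% names(smiles) %||% paste0("cmp", seq_along(smiles))
  sdfset <- ChemmineR::smiles2sdf(setNames(smiles, ids))
  out <- lapply(seq_along(smiles), function(i)
    as_molecule(sdfset[[i]], compound_id = ids[i]))
  names(out) <- ids
  out
}

#' Read molecules from an id-TAB-smiles file
#'
#' One molecule per line: `compound_id<TAB>SMILES`.
#'
#' @param path File path.
#' @return Named list of [molecule()] objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed line(s) (need id<TAB>smiles): ",
                     paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[`, "", 1)
  smi <- vapply(parts, `[`, "", 2)
  parse_smiles(smi, ids)
}

#' Read molecules from an SDF file
#'
#' @param path SDF file path.
#' @return Named list of [molecule()] objects.
#' @export
read_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SDF reading requires the 'ChemmineR' package")
  sdfset <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfset)
  out <- lapply(seq_along(sdfset), function(i)
    as_molecule(sdfset[[i]], compound_id = ids[i]))
  names(out) <- ids
  out
}
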