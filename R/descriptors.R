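#' Embranchment count (EC)
#'
#' Counts the atoms engaged in three or more covalent bonds to heavy-atom
#' neighbours — the branching points of the molecular graph. Following the
#' atom types that define the descriptor (quaternary/tertiary carbons and
#' nitrogens plus branched Se/Sn), the count is restricted by default to
#' the elements C, N, Se and Sn; attached hydrogens never count towards
#' the three bonds. Set `element_filter = NULL` to count every branched
#' heavy atom.
#'
#' @param mol A [molecule()].
#' @param element_filter Character vector of element symbols to consider,
#'   or `NULL` for all heavy elements.
#' @return Nonnegative integer count.
#' @export
embranchment_count <- function(mol, element_filter = c("C", "N", "Se", "Sn")) {
  stopifnot(inherits(mol, "molecule"))
  deg <- heavy_degree(mol)
  keep <- deg >= 3L
  if (!is.null(element_filter))
    keep <- keep & mol$atoms$element %in% element_filter
  sum(keep)
}

#' Molecular weight from the heavy-atom graph
#'
#' Standard atomic weights plus 1.008 g/mol per implicit hydrogen.
#'
#' @param mol A [molecule()].
#' @return MW in g/mol.
#' @export
molecular_weight <- function(mol) {
  sum(.atomic_mass[mol$atoms$element]) + 1.008 * sum(mol$atoms$n_h)
}

#' Hydrogen-bond acceptor count (N/O rule)
#' @param mol A [molecule()].
#' @return Number of nitrogen and oxygen atoms.
#' @export
hba_count <- function(mol) sum(mol$atoms$element %in% c("N", "O"))

#' Hydrogen-bond donor count (N-H / O-H rule)
#' @param mol A [molecule()].
#' @return Number of N or O atoms bearing at least one hydrogen.
#' @export
hbd_count <- function(mol)
  sum(mol$atoms$element %in% c("N", "O") & mol$atoms$n_h > 0)

#' Ring count (smallest set of smallest rings size)
#'
#' The cyclomatic number bonds - atoms + components, which equals the
#' number of rings in a smallest-set-of-smallest-rings perception.
#'
#' @param mol A [molecule()].
#' @return Nonnegative integer.
#' @export
ring_count <- function(mol) {
  comp <- if (nrow(mol$atoms) == 0) 0L else
    igraph::components(mol_graph(mol))$no
  nrow(mol$bonds) - nrow(mol$atoms) + comp
}

#' Rotatable-bond count
#'
#' Non-ring single bonds between two non-terminal heavy atoms (both ends
#' with heavy degree >= 2).
#'
#' @param mol A [molecule()].
#' @return Nonnegative integer.
#' @export
rotatable_bond_count <- function(mol) {
  if (!nrow(mol$bonds)) return(0L)
  deg <- heavy_degree(mol)
  sum(mol$bonds$order == 1 & !ring_bonds(mol) &
        deg[mol$bonds$a1] >= 2 & deg[mol$bonds$a2] >= 2)
}

#' Compute the nine retained properties of a molecule
#'
#' MW, HBA, HBD, RC, RB and EC are computed from the heavy-atom graph by
#' the standard definitions above. AlogP, Estate and PSA belong to
#' external parameterized method families, so they are either delegated to
#' the Open Babel descriptor engine (`engine = "openbabel"`: Crippen-type
#' logP and topological PSA; Estate has no engine and must be supplied) or
#' taken verbatim from `property_row` (`engine = "ingest"`). In full
#' ingest mode every property present in `property_row` passes through
#' bit-identically.
#'
#' @param mol A [molecule()], or `NULL` in pure ingest mode.
#' @param engine `"graph"` (graph properties + `property_row` for the
#'   delegated three), `"openbabel"` (graph + Open Babel logP/PSA) or
#'   `"ingest"` (all nine from `property_row`).
#' @param property_row Named numeric vector/list supplying property values.
#' @param smiles SMILES string for the Open Babel engine (required when
#'   `engine = "openbabel"`).
#' @return Named numeric vector over [screen_properties].
#' @export
compute_properties <- function(mol = NULL,
                               engine = c("graph", "openbabel", "ingest"),
                               property_row = NULL, smiles = NULL) {
  engine <- match.arg(engine)
  row <- if (is.null(property_row)) numeric(0) else unlist(property_row)
  if (engine == "ingest") {
    missing_p <- setdiff(screen_properties, names(row))
    if (length(missing_p))
      stop("missing property value(s) with no engine: ",
           paste(missing_p, collapse = ", "))
    return(setNames(as.numeric(row[screen_properties]), screen_properties))
  }
  stopifnot(inherits(mol, "molecule"))
  out <- c(MW = molecular_weight(mol), AlogP = NA_real_, Estate = NA_real_,
           PSA = NA_real_, HBA = as.numeric(hba_count(mol)),
           HBD = as.numeric(hbd_count(mol)), RC = as.numeric(ring_count(mol)),
           RB = as.numeric(rotatable_bond_count(mol)),
           EC = as.numeric(embranchment_count(mol)))
  if (engine == "openbabel") {
    if (is.null(smiles)) stop("the openbabel engine needs a SMILES string")
    if (!requireNamespace("ChemmineR", quietly = TRUE) ||
        !requireNamespace("ChemmineOB", quietly = TRUE))
      stop("the openbabel engine requires 'ChemmineR' and 'ChemmineOB'")
    pr <- ChemmineR::propOB(
      ChemmineR::smiles2sdf(setNames(smiles, mol$compound_id)))
    out["AlogP"] <- pr$logP
    out["PSA"] <- pr$TPSA
  }
  for (p in c("AlogP", "Estate", "PSA"))
    if (is.na(out[p]) && p %in% names(row)) out[p] <- as.numeric(row[p])
  still <- names(out)[is.na(out)]
  if (length(still))
    stop("missing property value(s) with no engine: ",
         paste(still, collapse = ", "))
  out
}

#' Property table of a chemical library
#'
#' Averages each of the nine properties separately over the actives and
#' the decoys of one target.
#'
#' @param records Data frame with a `group` column ("active"/"decoy") and
#'   one column per property in [screen_properties].
#' @param target_id Target identifier.
#' @return Long data frame: `target_id`, `property`, `actives_mean`,
#'   `decoys_mean`.
#' @export
property_table <- function(records, target_id) {
  stopifnot(all(screen_properties %in% names(records)),
            all(c("active", "decoy") %in% records$group))
  act <- records[records$group == "active", screen_properties, drop = FALSE]
  dec <- records[records$group == "decoy", screen_properties, drop = FALSE]
  data.frame(target_id = target_id, property = screen_properties,
             actives_mean = unname(colMeans(act)),
             decoys_mean = unname(colMeans(dec)),
             stringsAsFactors = FALSE)
}
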