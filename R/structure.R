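# The internal structure model: a flat, ordered atom table plus metadata.
# Coordinates are stored in nm; PDB I/O converts to/from angstroms.

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "DI", "DGL") # DGL: LNA-tagged G

PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                      "HA", "HA2", "HA3")
DNA_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                  "O3'", "C2'", "C1'", "H5'", "H5''", "H4'", "H3'", "H2'",
                  "H2''", "H1'", "HO5'", "HO3'")

HBOND_ROLES <- c("donor", "acceptor", "donor_acceptor", "none")

# Donor/acceptor assignment for standard residues, keyed "RESNAME:ATOM".
# Synthetic structures carry explicit annotations and bypass this table.
.hbond_table <- local({
  tab <- list()
  put <- function(res, atom, role) for (r in res) tab[[paste0(r, ":", atom)]] <<- role
  put(PROTEIN_RESNAMES, "N", "donor")
  put(PROTEIN_RESNAMES, "O", "acceptor")
  put("SER", "OG", "donor_acceptor"); put("THR", "OG1", "donor_acceptor")
  put("TYR", "OH", "donor_acceptor")
  put("ASN", "OD1", "acceptor"); put("ASN", "ND2", "donor")
  put("GLN", "OE1", "acceptor"); put("GLN", "NE2", "donor")
  put("ASP", "OD1", "acceptor"); put("ASP", "OD2", "acceptor")
  put("GLU", "OE1", "acceptor"); put("GLU", "OE2", "acceptor")
  put("LYS", "NZ", "donor")
  put("ARG", "NE", "donor"); put("ARG", "NH1", "donor"); put("ARG", "NH2", "donor")
  put("HIS", "ND1", "donor_acceptor"); put("HIS", "NE2", "donor_acceptor")
  put("TRP", "NE1", "donor")
  for (a in c("OP1", "OP2", "O3'", "O5'", "O4'")) put(DNA_RESNAMES, a, "acceptor")
  put(c("DG", "DGL"), "O6", "acceptor"); put(c("DG", "DGL"), "N7", "acceptor")
  put(c("DG", "DGL"), "N2", "donor"); put(c("DG", "DGL"), "N1", "donor")
  put("DA", "N1", "acceptor"); put("DA", "N3", "acceptor")
  put("DA", "N7", "acceptor"); put("DA", "N6", "donor")
  put("DC", "O2", "acceptor"); put("DC", "N3", "acceptor"); put("DC", "N4", "donor")
  put("DT", "O2", "acceptor"); put("DT", "O4", "acceptor"); put("DT", "N3", "donor")
  tab
})

residue_kind <- function(resname) {
  ifelse(resname %in% PROTEIN_RESNAMES, "protein",
         ifelse(resname %in% DNA_RESNAMES, "dna", "other"))
}

#' Construct a structure object from an atom table
#'
#' The atom table is the package's single source of truth for a molecule:
#' one row per atom, ordered, with residue identity, element, coordinates in
#' nm, and hydrogen-bond annotations. Missing annotation columns are filled
#' with defaults; hydrogens are attached to their parent heavy atom through
#' the `h_parent` serial.
#'
#' @param atoms data.frame with at least columns `serial`, `name`,
#'   `element`, `x`, `y`, `z`, `chain`, `resseq`, `resname`; optionally
#'   `is_hydrogen`, `is_sidechain`, `hbond_role`, `h_parent`, `charge`,
#'   `gb_radius`
#' @param title free-text title
#' @param provenance one of "read", "synthetic", "derived"
#' @return an object of class `apt_structure`
#' @export
new_structure <- function(atoms, title = "",
                          provenance = c("synthetic", "read", "derived")) {
  provenance <- match.arg(provenance)
  req <- c("serial", "name", "element", "x", "y", "z", "chain", "resseq", "resname")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resseq <- as.integer(atoms$resseq)
  if (anyDuplicated(atoms$serial)) stop("atom serials not unique")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  if (is.null(atoms$is_sidechain)) {
    kind <- residue_kind(atoms$resname)
    bb <- ifelse(kind == "dna", atoms$name %in% DNA_BACKBONE,
                 atoms$name %in% PROTEIN_BACKBONE)
    atoms$is_sidechain <- !bb
  }
  if (is.null(atoms$hbond_role)) {
    atoms$hbond_role <- unname(vapply(paste0(atoms$resname, ":", atoms$name),
      function(k) .hbond_table[[k]] %||% "none", character(1)))
  }
  if (!all(atoms$hbond_role %in% HBOND_ROLES))
    stop("invalid hbond_role value")
  if (is.null(atoms$h_parent)) atoms$h_parent <- NA_integer_
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$gb_radius)) atoms$gb_radius <- NA_real_
  atoms$kind <- residue_kind(atoms$resname)
  # a (chain, resseq) pair must name a single residue
  rid <- paste(atoms$chain, atoms$resseq)
  rn <- tapply(atoms$resname, rid, function(v) length(unique(v)))
  if (any(rn > 1)) stop("conflicting resname within a (chain, resseq) residue")
  structure(
    list(atoms = atoms, title = title, provenance = provenance),
    class = "apt_structure"
  )
}

#' @export
print.apt_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<apt_structure> %s\n", if (nzchar(x$title)) x$title else "(untitled)"))
  cat(sprintf("  %d atoms (%d heavy), %d residues, chains: %s, provenance: %s\n",
              nrow(a), sum(!a$is_hydrogen),
              length(unique(paste(a$chain, a$resseq))),
              paste(unique(a$chain), collapse = ","), x$provenance))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an `apt_structure`
#' @return integer count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a structure
#' @param s an `apt_structure`
#' @param heavy_only drop hydrogens first
#' @return n x 3 matrix in nm
#' @export
coords <- function(s, heavy_only = FALSE) {
  a <- s$atoms
  if (heavy_only) a <- a[!a$is_hydrogen, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s an `apt_structure`
#' @param xyz n x 3 matrix in nm, atom order preserved
#' @return modified structure with provenance "derived"
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s$provenance <- "derived"
  s
}

#' Per-residue summary table
#' @param s an `apt_structure`
#' @return data.frame with chain, resseq, resname, kind, n_atoms
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resseq, sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resseq = a$resseq[first],
             resname = a$resname[first], kind = a$kind[first],
             n_atoms = as.integer(table(key)[key[first]]),
             stringsAsFactors = FALSE)
}

# row indices of atoms belonging to a set of residues given as a
# data.frame(chain, resseq)
atom_rows_for_residues <- function(s, res) {
  key <- paste(s$atoms$chain, s$atoms$resseq)
  which(key %in% paste(res$chain, res$resseq))
}

# translate a subset of residues rigidly (used by fixture builders)
translate_residues <- function(s, res, shift) {
  idx <- atom_rows_for_residues(s, res)
  s$atoms$x[idx] <- s$atoms$x[idx] + shift[1]
  s$atoms$y[idx] <- s$atoms$y[idx] + shift[2]
  s$atoms$z[idx] <- s$atoms$z[idx] + shift[3]
  s
}
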