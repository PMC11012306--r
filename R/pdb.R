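# Fixed-width PDB v3.3 coordinate I/O. Scope is deliberately narrow:
# ATOM/HETATM and TER records, altloc '' or 'A' only, no insertion codes,
# no hybrid-36 numbering, single model. Internal units are nm; files are
# written and read in angstroms.

#' Read a PDB coordinate file
#'
#' Loads all `ATOM`/`HETATM` records whose altloc is blank or `'A'`
#' (alternate conformer B and beyond are dropped). Coordinates are
#' converted from angstrom to nm. The element is taken from columns 77-78
#' when present, otherwise inferred from the atom name. Hydrogen-bond
#' donor/acceptor roles are assigned from a built-in table for standard
#' amino acids and DNA nucleotides, and each hydrogen is attached to the
#' nearest heavy atom of its residue (within 1.5 angstrom).
#'
#' @param path file path
#' @return an [new_structure()] object with provenance `"read"`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("empty structure: no ATOM/HETATM records in ", path)
  fields <- vector("list", length(keep))
  j <- 0
  for (i in keep) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed fixed-width ATOM record at line %d of %s", i, path))
    altloc <- substr(ln, 17, 17)
    if (!altloc %in% c(" ", "", "A")) next
    icode <- substr(ln, 27, 27)
    if (!icode %in% c(" ", ""))
      stop(sprintf("insertion code at line %d not supported", i))
    serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
    resseq <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (is.na(serial) || is.na(resseq) || anyNA(xyz))
      stop(sprintf("malformed fixed-width ATOM record at line %d of %s", i, path))
    name <- trimws(substr(ln, 13, 16))
    element <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
    if (!nzchar(element)) {
      # fallback: first alphabetic character of the atom name
      element <- sub("^[0-9']*", "", name)
      element <- toupper(substr(element, 1, 1))
    } else {
      element <- paste0(toupper(substr(element, 1, 1)),
                        tolower(substr(element, 2, 2)))
      element <- trimws(element)
    }
    j <- j + 1
    fields[[j]] <- list(serial = serial, name = name, element = element,
                        x = xyz[1] / 10, y = xyz[2] / 10, z = xyz[3] / 10,
                        chain = substr(ln, 22, 22),
                        resseq = resseq, resname = trimws(substr(ln, 18, 20)))
  }
  if (j == 0) stop("empty structure: all records filtered in ", path)
  fields <- fields[seq_len(j)]
  atoms <- do.call(rbind, lapply(fields, function(f)
    data.frame(f, stringsAsFactors = FALSE)))
  s <- new_structure(atoms, title = basename(path), provenance = "read")
  attach_hydrogens(s)
}

# assign h_parent for each hydrogen: nearest heavy atom in the same residue
# within 0.15 nm
attach_hydrogens <- function(s) {
  a <- s$atoms
  hy <- which(a$is_hydrogen)
  if (!length(hy)) return(s)
  key <- paste(a$chain, a$resseq)
  for (i in hy) {
    cand <- which(key == key[i] & !a$is_hydrogen)
    if (!length(cand)) next
    d2 <- (a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 + (a$z[cand] - a$z[i])^2
    k <- which.min(d2)
    if (d2[k] <= 0.15^2) {
      s$atoms$h_parent[i] <- a$serial[cand[k]]
      # hydrogens inherit the side-chain flag of their parent
      s$atoms$is_sidechain[i] <- a$is_sidechain[cand[k]]
    }
  }
  s
}

#' Write a structure as a PDB coordinate file
#'
#' Fixed-width PDB v3.3; residues are written in input order with a `TER`
#' record closing every chain. Coordinates are converted nm to angstrom and
#' rounded to three decimals (the format's precision).
#'
#' @param s an `apt_structure`
#' @param path output file path
#' @return invisibly, the path
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  if (any(a$resseq > 9999)) stop("resseq > 9999: hybrid-36 numbering not supported")
  if (any(a$serial > 99999)) stop("serial > 99999: hybrid-36 numbering not supported")
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(s$title))
    writeLines(sprintf("TITLE     %s", substr(s$title, 1, 60)), con)
  fmt_name <- function(nm) {
    # standard alignment: names of up to 3 chars start in column 14
    ifelse(nchar(nm) <= 3, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  }
  out <- character(nrow(a) + length(unique(a$chain)))
  k <- 0
  chains <- unique(a$chain)
  for (ch in chains) {
    idx <- which(a$chain == ch)
    for (i in idx) {
      k <- k + 1
      out[k] <- sprintf(
        "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a$serial[i], fmt_name(a$name[i]), " ", a$resname[i], a$chain[i],
        a$resseq[i], " ", a$x[i] * 10, a$y[i] * 10, a$z[i] * 10, 1.0, 0.0,
        toupper(a$element[i]))
    }
    k <- k + 1
    last <- idx[length(idx)]
    out[k] <- sprintf("TER   %5d      %-3s %1s%4d",
                      min(a$serial[last] + 1L, 99999L), a$resname[last],
                      a$chain[last], a$resseq[last])
  }
  writeLines(out[seq_len(k)], con)
  writeLines("END", con)
  invisible(path)
}
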