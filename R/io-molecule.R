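#' @include AllClasses.R AllGenerics.R
NULL

#' Read molecules from an SDF/MOL V2000 file
#'
#' Parsing of atoms, coordinates and bonds is delegated to
#' \code{ChemmineR::read.SDFset}; formal charges are taken from
#' \code{M  CHG} property lines (scanned directly, since ChemmineR's
#' accessors do not surface them). Bond order 4 in the file is kept as the
#' aromatic order class.
#'
#' @param path SDF file path
#' @param name molecule name override; default: the SDF title line
#' @return list of \linkS4class{Molecule} (one per record)
#' @export
readMoleculeSDF <- function(path, name = NULL) {
  sdfset <- ChemmineR::read.SDFset(path)
  raw <- readLines(path)
  recEnds <- grep("^\\$\\$\\$\\$", raw)
  if (!length(recEnds)) recEnds <- length(raw)
  recStarts <- c(1L, utils::head(recEnds, -1) + 1L)
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- if (nrow(bb)) unname(as.matrix(bb[, 1:3, drop = FALSE]))
             else NULL
    ## formal charges from M  CHG lines of this record
    rec <- raw[recStarts[i]:recEnds[min(i, length(recEnds))]]
    chg <- integer(length(elements))
    for (ln in grep("^M  CHG", rec, value = TRUE)) {
      tok <- scan(text = sub("^M  CHG", "", ln), quiet = TRUE)
      cnt <- tok[1]
      for (p in seq_len(cnt))
        chg[tok[2 * p]] <- as.integer(tok[2 * p + 1])
    }
    title <- if (!is.null(name)) name else trimws(rec[1])
    out[[i]] <- Molecule(elements, coords, bonds,
                         formalCharge = sum(chg), units = "angstrom",
                         name = title, conformerId = as.character(i),
                         atomFormalCharges = chg)
  }
  out
}

#' Write a molecule as an SDF/MOL V2000 record
#'
#' @param molecule a \linkS4class{Molecule}
#' @param path output path
#' @return invisibly, the path
#' @export
writeMoleculeSDF <- function(molecule, path) {
  xyz <- atomCoords(molecule, units = "angstrom")
  el <- atomElements(molecule)
  b <- bondMatrix(molecule)
  chg <- molecule@atomFormalCharges
  lines <- c(molecule@name, "  dpolkit", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nAtoms(molecule), nrow(b)))
  lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0",
                            xyz[, 1], xyz[, 2], xyz[, 3], el))
  if (nrow(b))
    lines <- c(lines, sprintf("%3d%3d%3d  0", b[, 1], b[, 2], b[, 3]))
  nz <- which(chg != 0L)
  if (length(nz))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(nz)),
                             paste0(sprintf("%4d%4d", nz, chg[nz]),
                                    collapse = "")))
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule from XYZ plus a JSON bond list
#'
#' Toy-fixture reader: standard XYZ (count, comment, element x y z in
#' Angstrom) plus JSON \code{{"bonds": [[i, j, order], ...],
#' "formal_charge": q}} with 1-based indices; order may be "ar".
#'
#' @param xyzPath XYZ file path
#' @param bondsPath JSON bond-list path
#' @return A \linkS4class{Molecule}.
#' @export
readMoleculeXYZ <- function(xyzPath, bondsPath) {
  lines <- readLines(xyzPath)
  nat <- as.integer(trimws(lines[1]))
  tab <- utils::read.table(text = lines[3:(2 + nat)],
                           col.names = c("el", "x", "y", "z"))
  j <- jsonlite::read_json(bondsPath, simplifyVector = TRUE)
  bonds <- j$bonds
  if (is.list(bonds) && !is.data.frame(bonds)) bonds <- do.call(rbind, bonds)
  q <- if (is.null(j$formal_charge)) 0L else as.integer(j$formal_charge)
  Molecule(tab$el, as.matrix(tab[, c("x", "y", "z")]), bonds,
           formalCharge = q, units = "angstrom",
           name = trimws(lines[2]))
}

#' Read per-atom precharges from a plain table
#'
#' Whitespace-delimited, one atom per line: index, element, charge (e).
#' Lines starting with '#' are comments.
#'
#' @param path table path
#' @return numeric charge vector, ordered by atom index
#' @export
readPrecharges <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("index", "element", "charge"))
  tab$charge[order(tab$index)]
}
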