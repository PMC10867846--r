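#' @include AllClasses.R AllGenerics.R
NULL

#' Default Merz-Singh-Kollman grid specification
#'
#' Ten shells, 17 points per square Angstrom, 0.126 Angstrom radial spacing
#' between successive shells, innermost shell at 1.4 x the Bondi van der
#' Waals radius.
#'
#' @param nLayers number of shells
#' @param density surface point density, points per Angstrom^2
#' @param spacing radial increment between shells, Angstrom
#' @param innerScale scale factor on the vdW radius for the innermost shell
#' @param radii named vdW radius set, Angstrom
#' @return list spec consumed by \code{\link{generateMskGrid}}
#' @export
mskGridSpec <- function(nLayers = 10L, density = 17, spacing = 0.126,
                        innerScale = 1.4, radii = bondiRadii()) {
  stopifnot(nLayers >= 1, density > 0, spacing >= 0, innerScale > 0)
  list(nLayers = as.integer(nLayers), density = density, spacing = spacing,
       innerScale = innerScale, radii = radii, radiusSet = "bondi")
}

## Molecule-fixed orthonormal frame from the principal axes of the atom
## coordinates, with signs fixed against the farthest-from-centroid atoms
## and a right-handed third axis. Generating the sphere lattices in this
## frame makes the grid equivariant under rigid rotation (for molecules
## whose principal moments are non-degenerate; symmetric tops are still
## deterministic, just not strictly equivariant).
moleculeFrame <- function(xyz) {
  if (nrow(xyz) < 2) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  V <- eigen(crossprod(X), symmetric = TRUE)$vectors
  refs <- X[order(-rowSums(X^2)), , drop = FALSE]
  fixSign <- function(v) {
    for (r in seq_len(nrow(refs))) {
      d <- sum(v * refs[r, ])
      if (abs(d) > 1e-8) return(v * sign(d))
    }
    v
  }
  v1 <- fixSign(V[, 1])
  v2 <- fixSign(V[, 2])
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

## Deterministic quasi-uniform points on the unit sphere:
## golden-spiral (Fibonacci) lattice.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a Merz-Singh-Kollman style ESP sampling grid
#'
#' Builds \code{nLayers} shells; shell k (k = 1..nLayers) places a
#' golden-spiral lattice of density \code{density} points/Angstrom^2 on a
#' sphere of radius \code{innerScale * rvdw + (k-1) * spacing} around each
#' atom, then removes points falling inside any other atom's same-shell
#' sphere, so every retained point lies outside the shell surface of every
#' atom. Lattices are generated in a molecule-fixed principal-axes frame,
#' so the grid is deterministic for fixed input and rotates rigidly with
#' the molecule.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param spec grid specification from \code{\link{mskGridSpec}}
#' @return An \linkS4class{ESPGrid}; points in bohr, with per-point shell
#'   provenance.
#' @export
#' @examples
#' m <- Molecule("O", matrix(c(0, 0, 0), 1), bonds = NULL)
#' g <- generateMskGrid(m, mskGridSpec(nLayers = 2, density = 1))
#' table(shellIndex(g))
generateMskGrid <- function(molecule, spec = mskGridSpec()) {
  el <- atomElements(molecule)
  unknown <- setdiff(unique(el), names(spec$radii))
  if (length(unknown))
    stop("no van der Waals radius configured for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  xyz <- atomCoords(molecule, units = "angstrom")
  rvdw <- unname(spec$radii[el])
  frame <- moleculeFrame(xyz)
  pts <- list(); shells <- list()
  cullTol <- 1e-9
  for (k in seq_len(spec$nLayers)) {
    rk <- spec$innerScale * rvdw + (k - 1) * spec$spacing
    layer <- list()
    for (a in seq_len(nrow(xyz))) {
      np <- max(1L, as.integer(round(4 * pi * rk[a]^2 * spec$density)))
      sphere <- fibonacciSphere(np) %*% t(frame)   # molecule-fixed lattice
      layer[[a]] <- sweep(sphere * rk[a], 2, xyz[a, ], "+")
    }
    layer <- do.call(rbind, layer)
    ## drop points inside any atom's same-shell sphere
    keep <- rep(TRUE, nrow(layer))
    for (a in seq_len(nrow(xyz))) {
      d2 <- (layer[, 1] - xyz[a, 1])^2 + (layer[, 2] - xyz[a, 2])^2 +
            (layer[, 3] - xyz[a, 3])^2
      keep <- keep & d2 >= (rk[a] - cullTol)^2
    }
    layer <- layer[keep, , drop = FALSE]
    ## remove near-duplicate points (distinct lattices rarely coincide)
    dup <- duplicated(round(layer, 6))
    layer <- layer[!dup, , drop = FALSE]
    pts[[k]] <- layer
    shells[[k]] <- rep(k, nrow(layer))
  }
  allPts <- do.call(rbind, pts)
  dimnames(allPts) <- NULL
  new("ESPGrid", points = allPts * BOHR_PER_ANGSTROM,
      shell = as.integer(unlist(shells)),
      spec = spec[c("nLayers", "density", "spacing", "innerScale",
                    "radiusSet")])
}

#' Write grid points to a whitespace-delimited file
#'
#' One point per line, x y z in Angstrom, 12 significant digits (Psi4
#' grid.dat dialect). Round-trips bit-stably with \code{\link{readGridFile}}.
#'
#' @param grid an \linkS4class{ESPGrid} or plain matrix of points (bohr)
#' @param path output path
#' @return invisibly, the path
#' @export
writeGridFile <- function(grid, path) {
  pts <- if (is(grid, "ESPGrid")) gridPoints(grid, "angstrom")
         else grid * ANGSTROM_PER_BOHR
  lines <- sprintf("%.12g %.12g %.12g", pts[, 1], pts[, 2], pts[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Read grid points from a whitespace-delimited file (Angstrom)
#' @param path input path
#' @return An \linkS4class{ESPGrid} (single shell label, no spec).
#' @export
readGridFile <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
  dimnames(m) <- NULL
  new("ESPGrid", points = m * BOHR_PER_ANGSTROM,
      shell = rep(1L, nrow(m)), spec = list())
}

#' Write potential values, one per line (hartree/e)
#' @param values numeric vector
#' @param path output path
#' @return invisibly, the path
#' @export
writePotentialFile <- function(values, path) {
  writeLines(sprintf("%.12g", values), path)
  invisible(path)
}

#' Read potential values, one per line (hartree/e)
#' @param path input path
#' @return numeric vector
#' @export
readPotentialFile <- function(path) {
  as.numeric(readLines(path))
}

#' Write an ESP record as a grid/potential file pair plus JSON sidecar
#'
#' Writes \code{<stem>.grid.dat} (Angstrom), \code{<stem>.esp.dat}
#' (hartree/e) and \code{<stem>.json} holding
#' \code{{"field_au": [...], "kind": ...}}.
#'
#' @param record an \linkS4class{ESPRecord}
#' @param stem path stem (no extension)
#' @return invisibly, the stem
#' @export
writeEspRecord <- function(record, stem) {
  writeGridFile(record@grid, paste0(stem, ".grid.dat"))
  writePotentialFile(record@values, paste0(stem, ".esp.dat"))
  jsonlite::write_json(list(field_au = record@appliedField,
                            kind = record@kind),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read an ESP record written by \code{\link{writeEspRecord}}
#' @param stem path stem (no extension)
#' @return An \linkS4class{ESPRecord}.
#' @export
readEspRecord <- function(stem) {
  grid <- readGridFile(paste0(stem, ".grid.dat"))
  values <- readPotentialFile(paste0(stem, ".esp.dat"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ESPRecord(grid, values, appliedField = as.numeric(side$field_au),
            kind = side$kind)
}
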