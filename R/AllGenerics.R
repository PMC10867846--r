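#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a Molecule
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Element symbols
#' @param x a Molecule
#' @return character vector
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))

#' Atomic coordinates
#' @param x a Molecule
#' @param units "bohr" (default, internal) or "angstrom"
#' @return nAtoms x 3 numeric matrix
#' @export
setGeneric("atomCoords", function(x, units = "bohr") standardGeneric("atomCoords"))

#' Bond matrix
#' @param x a Molecule
#' @return integer matrix with columns from, to, order (4 = aromatic)
#' @export
setGeneric("bondMatrix", function(x) standardGeneric("bondMatrix"))

#' Total formal charge
#' @param x a Molecule
#' @return integer charge in e
#' @export
setGeneric("formalCharge", function(x) standardGeneric("formalCharge"))

#' Scaling factor matrix
#' @param x a ScalingTable
#' @return numeric symmetric matrix of pair factors
#' @export
setGeneric("scalingMatrix", function(x) standardGeneric("scalingMatrix"))

#' Grid points
#' @param x an ESPGrid or ESPRecord
#' @param units "bohr" or "angstrom"
#' @return nPoints x 3 matrix
#' @export
setGeneric("gridPoints", function(x, units = "bohr") standardGeneric("gridPoints"))

#' Shell index per grid point
#' @param x an ESPGrid
#' @return integer vector, 1 = innermost shell
#' @export
setGeneric("shellIndex", function(x) standardGeneric("shellIndex"))

#' Potential values of an ESP record
#' @param x an ESPRecord
#' @return numeric vector, hartree/e
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))

#' Applied external field of an ESP record
#' @param x an ESPRecord
#' @return numeric 3-vector, au
#' @export
setGeneric("appliedField", function(x) standardGeneric("appliedField"))

#' Fitted charges
#' @param x a ChargeFitResult
#' @return numeric vector of per-atom charges, e
#' @export
setGeneric("fittedCharges", function(x) standardGeneric("fittedCharges"))

#' Fitted bond charge corrections
#' @param x a BCCFitResult
#' @return named numeric vector of B values, e
#' @export
setGeneric("bccValues", function(x) standardGeneric("bccValues"))

setMethod("nAtoms", "Molecule", function(x) length(x@elements))
setMethod("atomElements", "Molecule", function(x) x@elements)
setMethod("atomCoords", "Molecule", function(x, units = "bohr") {
  units <- match.arg(units, c("bohr", "angstrom"))
  if (units == "bohr") x@coordinates else x@coordinates * ANGSTROM_PER_BOHR
})
setMethod("bondMatrix", "Molecule", function(x) x@bonds)
setMethod("formalCharge", "Molecule", function(x) x@formalCharge)

setMethod("scalingMatrix", "ScalingTable", function(x) x@factors)

setMethod("gridPoints", "ESPGrid", function(x, units = "bohr") {
  units <- match.arg(units, c("bohr", "angstrom"))
  if (units == "bohr") x@points else x@points * ANGSTROM_PER_BOHR
})
setMethod("gridPoints", "ESPRecord", function(x, units = "bohr")
  gridPoints(x@grid, units))
setMethod("shellIndex", "ESPGrid", function(x) x@shell)
setMethod("potentials", "ESPRecord", function(x) x@values)
setMethod("appliedField", "ESPRecord", function(x) x@appliedField)

setMethod("fittedCharges", "ChargeFitResult", function(x) x@charges)
setMethod("bccValues", "BCCFitResult", function(x) x@values)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s'%s: %d atoms, %d bonds, charge %+d\n",
              object@name,
              if (nzchar(object@conformerId))
                sprintf(" [%s]", object@conformerId) else "",
              nAtoms(object), nrow(object@bonds), object@formalCharge))
  cat("  formula:", paste0(names(table(object@elements)),
                           table(object@elements), collapse = " "), "\n")
})

setMethod("show", "ESPGrid", function(object) {
  cat(sprintf("ESPGrid: %d points in %d shells\n",
              nrow(object@points),
              length(unique(object@shell))))
})

setMethod("show", "ESPRecord", function(object) {
  cat(sprintf("ESPRecord (%s): %d values, field (%g, %g, %g) au\n",
              object@kind, length(object@values),
              object@appliedField[1], object@appliedField[2],
              object@appliedField[3]))
})

setMethod("show", "PolarizabilityTypeSet", function(object) {
  cat(sprintf("PolarizabilityTypeSet (%s scheme), %d entries:\n",
              object@scheme, length(object@matchers)))
  for (i in seq_along(object@matchers))
    cat(sprintf("  %-18s %s\n", object@matchers[i],
                ifelse(is.na(object@alphas[i]), "<unset>",
                       sprintf("%.6f bohr^3", object@alphas[i]))))
})

setMethod("show", "ChargeFitResult", function(object) {
  cat(sprintf("ChargeFitResult: %d charges, sum %+.6f e, %s in %d iterations\n",
              length(object@charges), sum(object@charges),
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

setMethod("show", "BCCFitResult", function(object) {
  cat(sprintf("BCCFitResult: %d types (%d covered), objective %.3e\n",
              length(object@values), sum(object@covered), object@objective))
})

setMethod("show", "LiquidSeries", function(object) {
  cat(sprintf("LiquidSeries: %d frames, T = %g K, <V> = %.1f bohr^3\n",
              nrow(object@dipoles), object@temperature, mean(object@volumes)))
})
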