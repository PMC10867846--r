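#' @include AllClasses.R AllGenerics.R polarization.R
NULL

#' Linear ESP design matrix with the induced-dipole contribution
#'
#' Column j gives the potential at each grid point per unit charge on atom
#' j: the direct Coulomb term 1/|r_i - r_j| plus the potential of the
#' induced dipoles that a unit charge on j drives on every polarizable atom
#' m through the scaled permanent field, mu_m = alpha_m f_mj (r_m - r_j) /
#' |r_m - r_j|^3. The model ESP of a charge vector q is then A q, which is
#' what makes the charge and BCC fits plain linear least squares.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param alphas per-atom polarizabilities, bohr^3
#' @param grid an \linkS4class{ESPGrid} or point matrix (bohr)
#' @param scaling optional precomputed \linkS4class{ScalingTable}
#' @param coulombOnly if TRUE, omit the induced-dipole term
#' @return nPoints x nAtoms numeric matrix
#' @export
respDesignMatrix <- function(molecule, alphas, grid, scaling = NULL,
                             coulombOnly = FALSE) {
  pts <- if (is(grid, "ESPGrid")) gridPoints(grid) else as.matrix(grid)
  n <- nAtoms(molecule)
  xyz <- atomCoords(molecule)
  if (is.null(scaling)) scaling <- scalingFactors(molecule)
  f <- scalingMatrix(scaling)
  npts <- nrow(pts)
  A <- matrix(0, npts, n)
  ## point-to-atom geometry, reused across columns
  Rx <- vector("list", n); Ry <- vector("list", n); Rz <- vector("list", n)
  invR <- vector("list", n); invR3 <- vector("list", n)
  for (m in seq_len(n)) {
    rx <- pts[, 1] - xyz[m, 1]
    ry <- pts[, 2] - xyz[m, 2]
    rz <- pts[, 3] - xyz[m, 3]
    r2 <- rx^2 + ry^2 + rz^2
    if (any(r2 < 1e-16))
      stop(sprintf("grid point coincides with atom %d", m), call. = FALSE)
    Rx[[m]] <- rx; Ry[[m]] <- ry; Rz[[m]] <- rz
    invR[[m]] <- 1 / sqrt(r2)
    invR3[[m]] <- invR[[m]]^3
  }
  for (j in seq_len(n)) {
    col <- invR[[j]]
    if (!coulombOnly) {
      for (m in seq_len(n)) {
        w <- alphas[m] * f[m, j]
        if (m == j || w == 0) next
        dmj <- xyz[m, ] - xyz[j, ]
        s <- w * dmj / sum(dmj^2)^1.5
        col <- col + (Rx[[m]] * s[1] + Ry[[m]] * s[2] + Rz[[m]] * s[3]) *
          invR3[[m]]
      }
    }
    A[, j] <- col
  }
  A
}

#' Bundle conformer records into a polarizability-fit problem
#'
#' @param conformers list of entries, each a list with elements
#'   \code{molecule} (a \linkS4class{Molecule}), \code{differences} (list of
#'   difference \linkS4class{ESPRecord}s with their inducing fields), and
#'   optionally \code{baseline}
#' @param typing a \linkS4class{PolarizabilityTypeSet} skeleton (values may
#'   be NA)
#' @return object of class \code{PolFitProblem}
#' @export
polFitProblem <- function(conformers, typing) {
  for (cf in conformers) {
    stopifnot(is(cf$molecule, "Molecule"), length(cf$differences) >= 1)
    for (d in cf$differences)
      if (d@kind != "difference" || all(d@appliedField == 0))
        stop("difference records must carry a nonzero inducing field",
             call. = FALSE)
  }
  structure(list(conformers = conformers, typing = typing),
            class = "PolFitProblem")
}

## Per-record design: column t is the ESP of unit-alpha induced dipoles
## mu_j = E_ext on every atom j of type t.
polFitDesign <- function(molecule, typeIndex, nTypes, field, grid) {
  pts <- if (is(grid, "ESPGrid")) gridPoints(grid) else as.matrix(grid)
  xyz <- atomCoords(molecule)
  A <- matrix(0, nrow(pts), nTypes)
  for (j in seq_len(nAtoms(molecule))) {
    rx <- pts[, 1] - xyz[j, 1]
    ry <- pts[, 2] - xyz[j, 2]
    rz <- pts[, 3] - xyz[j, 3]
    r2 <- rx^2 + ry^2 + rz^2
    contrib <- (field[1] * rx + field[2] * ry + field[3] * rz) / (r2 * sqrt(r2))
    t <- typeIndex[j]
    A[, t] <- A[, t] + contrib
  }
  A
}

#' Fit typed polarizabilities to field-perturbed ESP differences
#'
#' Minimizes, over all conformers and field directions, the squared
#' deviation between the recorded ESP differences and the potential of the
#' induced dipoles mu_j = alpha_type(j) * E_ext (the permanent-charge
#' contribution cancels in the difference, and a uniform field induces the
#' same dipole on every atom of a type). The objective is linear in the
#' typed alphas, so a closed-form least-squares solution exists; a
#' Nelder-Mead solver is run as well (the optimization method of record for
#' this model) and both optima are returned and must agree.
#'
#' @param problem a \code{\link{polFitProblem}}
#' @param method "both" (default), "linear", or "neldermead"
#' @return The typing set with fitted values (alphas in bohr^3), with a
#'   \code{diagnostics} attribute: list(alphaLinear, alphaNelderMead,
#'   objective, nRecords, nPoints).
#' @export
fitPolarizabilities <- function(problem,
                                method = c("both", "linear", "neldermead")) {
  method <- match.arg(method)
  typing <- problem$typing
  nT <- length(typing@matchers)
  G <- matrix(0, nT, nT)
  cvec <- numeric(nT)
  vv <- 0
  nRecords <- 0L
  nPoints <- 0L
  support <- logical(nT)
  for (cf in problem$conformers) {
    ti <- assignPolarizabilities(
      cf$molecule, polTypeSet(typing@scheme, typing@matchers,
                              rep(0, nT)))$typeIndex
    support[unique(ti)] <- TRUE
    for (d in cf$differences) {
      A <- polFitDesign(cf$molecule, ti, nT, d@appliedField, d@grid)
      V <- d@values
      G <- G + crossprod(A)
      cvec <- cvec + crossprod(A, V)[, 1]
      vv <- vv + sum(V^2)
      nRecords <- nRecords + 1L
      nPoints <- nPoints + length(V)
    }
  }
  if (any(!support))
    stop("unidentifiable polarizability type(s): no matching atoms for ",
         paste(typing@matchers[!support], collapse = ", "), call. = FALSE)

  objective <- function(a) {
    ac <- pmax(a, 0)
    pen <- sum(pmin(a, 0)^2) * (1 + vv)
    drop(ac %*% G %*% ac) - 2 * sum(ac * cvec) + vv + pen
  }

  ## closed-form solution with non-negativity by active-set clamping
  solveLinear <- function() {
    free <- rep(TRUE, nT)
    repeat {
      a <- numeric(nT)
      a[free] <- solve(G[free, free, drop = FALSE], cvec[free])
      if (all(a >= -1e-12)) return(pmax(a, 0))
      free[a < -1e-12] <- FALSE
      if (!any(free)) return(numeric(nT))
    }
  }

  alphaLin <- if (method != "neldermead") solveLinear() else NULL
  alphaNM <- NULL
  if (method != "linear") {
    start <- rep(1, nT)
    best <- stats::optim(start, objective, method = "Nelder-Mead",
                         control = list(maxit = 20000, reltol = 1e-15))
    for (k in 1:4) {
      nxt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 20000, reltol = 1e-15))
      if (best$value - nxt$value < 1e-14 * max(1, best$value)) {
        best <- nxt; break
      }
      best <- nxt
    }
    alphaNM <- pmax(best$par, 0)
  }
  alpha <- if (!is.null(alphaLin)) alphaLin else alphaNM
  out <- polTypeSet(typing@scheme, typing@matchers, alpha)
  attr(out, "diagnostics") <- list(
    alphaLinear = alphaLin, alphaNelderMead = alphaNM,
    objective = objective(alpha), nRecords = nRecords, nPoints = nPoints)
  out
}

#' Hyperbolic restraint specification
#'
#' The RESP penalty a * sum_j (sqrt(q_j^2 + b^2) - b) over the restrained
#' atoms. Defaults follow the two-stage protocol: a weak stage-1 restraint
#' (a = 0.005 au) on all non-hydrogen atoms, then a strong stage-2
#' restraint (a = 0.01 au) with forced symmetry equivalencing on the
#' refitted methyl/methylene groups.
#'
#' @param a restraint strength, au (>= 0)
#' @param b restraint tightness, au (> 0)
#' @param restrained which atoms the penalty applies to: "heavy"
#'   (non-hydrogen, classic practice), "all", or "none"
#' @param stage 1 or 2
#' @return list of class \code{RestraintSpec}
#' @export
restraintSpec <- function(a, b = 0.1, restrained = c("heavy", "all", "none"),
                          stage = 1L) {
  restrained <- match.arg(restrained)
  stopifnot(a >= 0, b > 0, stage %in% 1:2)
  structure(list(a = a, b = b, restrained = restrained,
                 stage = as.integer(stage)),
            class = "RestraintSpec")
}

#' Default two-stage restraint schedule
#' @return list of two \code{\link{restraintSpec}}s
#' @export
respStages <- function() {
  list(restraintSpec(0.005, 0.1, "heavy", 1L),
       restraintSpec(0.01, 0.1, "heavy", 2L))
}

## One restrained, charge-constrained least-squares solve with iterated
## diagonal reweighting of the hyperbolic penalty (an MM scheme: each
## iteration minimizes a quadratic majorizer, so the objective is monotone
## non-increasing).
##   A: design (points x atoms); V: target; Gmat: atoms x groups (free
##   variables); qFixed: frozen part of the charge vector; aAtom: per-atom
##   restraint strength; qtot: total charge.
solveRestrainedLS <- function(A, V, Gmat, qFixed, aAtom, b, qtot,
                              maxIter = 200L, tol = 1e-8) {
  ng <- ncol(Gmat)
  AG <- A %*% Gmat
  resid0 <- V - A %*% qFixed
  AtA <- crossprod(AG)
  Atv <- crossprod(AG, resid0)[, 1]
  csum <- colSums(Gmat)                     # group sizes for the constraint
  qtotFree <- qtot - sum(qFixed)
  aGroup <- drop(crossprod(Gmat, aAtom))    # restraint multiplicity per group
  qg <- numeric(ng)
  objectiveOf <- function(qg) {
    q <- qFixed + Gmat %*% qg
    sum((V - A %*% q)^2) + sum(aAtom * (sqrt(q^2 + b^2) - b))
  }
  trace <- objectiveOf(qg)
  it <- 0L
  converged <- FALSE
  lambda <- NA_real_
  repeat {
    it <- it + 1L
    w <- aGroup / sqrt(qg^2 + b^2)
    M <- rbind(cbind(2 * AtA + diag(w, ng), csum),
               c(csum, 0))
    rhs <- c(2 * Atv, qtotFree)
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("rank-deficient charge-fit design: ", conditionMessage(e),
           call. = FALSE))
    qNew <- sol[seq_len(ng)]
    lambda <- sol[ng + 1L]
    delta <- max(abs(qNew - qg))
    qg <- qNew
    trace <- c(trace, objectiveOf(qg))
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  list(qGroups = qg, charges = drop(qFixed + Gmat %*% qg), lambda = lambda,
       iterations = it, converged = converged, trace = trace,
       objective = utils::tail(trace, 1))
}

#' Two-stage RESP-dPol charge fit
#'
#' Fits atom-centered charges to a baseline ESP record, with the model ESP
#' including both the Coulomb term and the potential of the induced dipoles
#' driven by the scaled permanent-charge fields (direct approximation). A
#' Lagrange multiplier constrains the charge sum to the molecule's formal
#' charge; the hyperbolic restraint is handled by iterated diagonal
#' reweighting. Stage 1 fits all atoms with the weak restraint; stage 2
#' freezes everything except sp3 carbons bearing two or more topologically
#' equivalent hydrogens (and those hydrogens), enforces exact within-class
#' charge equality, and refits under the strong restraint.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param baseline a baseline \linkS4class{ESPRecord} (zero applied field)
#' @param alphas per-atom polarizabilities, bohr^3
#' @param stages list of \code{\link{restraintSpec}}s; default
#'   \code{\link{respStages}()}. A single stage-1 spec runs one stage only.
#' @return A \linkS4class{ChargeFitResult}.
#' @export
fitRespDpol <- function(molecule, baseline, alphas, stages = respStages()) {
  stopifnot(is(baseline, "ESPRecord"))
  if (baseline@kind != "baseline" || any(baseline@appliedField != 0))
    stop("RESP-dPol fits to a baseline record with zero applied field",
         call. = FALSE)
  n <- nAtoms(molecule)
  stopifnot(length(alphas) == n)
  A <- respDesignMatrix(molecule, alphas, baseline@grid)
  V <- baseline@values
  qtot <- as.numeric(formalCharge(molecule))
  heavy <- atomElements(molecule) != "H"
  restrainMask <- function(spec) switch(spec$restrained,
    heavy = heavy, all = rep(TRUE, n), none = rep(FALSE, n))
  specs1 <- Filter(function(s) s$stage == 1L, stages)
  specs2 <- Filter(function(s) s$stage == 2L, stages)
  if (!length(specs1)) stop("a stage-1 restraint spec is required")
  s1 <- specs1[[1]]
  fit1 <- solveRestrainedLS(A, V, diag(1, n), numeric(n),
                            ifelse(restrainMask(s1), s1$a, 0), s1$b, qtot)
  details <- list(stage1 = fit1)
  final <- fit1
  if (length(specs2)) {
    s2 <- specs2[[1]]
    refit <- stage2RefitAtoms(molecule)
    if (length(refit)) {
      classes <- symmetryClasses(molecule)
      groups <- unique(classes[refit])
      Gmat <- matrix(0, n, length(groups))
      for (gi in seq_along(groups))
        Gmat[intersect(refit, which(classes == groups[gi])), gi] <- 1
      qFixed <- fit1$charges
      qFixed[refit] <- 0
      fit2 <- solveRestrainedLS(A, V, Gmat, qFixed,
                                ifelse(restrainMask(s2), s2$a, 0), s2$b, qtot)
      details$stage2 <- fit2
      details$refitAtoms <- refit
      final <- fit2
    } else {
      details$stage2 <- NULL
      details$refitAtoms <- integer(0)
    }
  }
  new("ChargeFitResult", charges = final$charges,
      lagrange = final$lambda,
      iterations = final$iterations,
      converged = final$converged,
      objective = final$objective,
      details = details)
}

#' Train bond charge corrections against baseline ESPs
#'
#' Minimizes, summed over all training conformers, the squared deviation
#' between the reference ESP and the model ESP of the corrected charges
#' q = q_pre + T B, where T is the bond-type assignment matrix. Because
#' the columns of T sum to zero, any B conserves each molecule's total
#' charge exactly. The model ESP includes the induced-dipole contribution;
#' by default the induced dipoles respond to the full corrected charges
#' (the fit stays linear in B either way). Rank-deficient directions are
#' resolved by the minimum-norm solution; bond types with no support are
#' reported and set to zero.
#'
#' @param training list of entries, each a list with \code{molecule},
#'   \code{precharges} (per-atom, e) and \code{baseline}
#'   (\linkS4class{ESPRecord})
#' @param table a \linkS4class{BondTypeTable}
#' @param typing a \linkS4class{PolarizabilityTypeSet} with values, or a
#'   list of per-atom alpha vectors aligned with \code{training}
#' @param inducedFrom "corrected" (default) or "precharges": which charges
#'   drive the induced dipoles during the fit
#' @return A \linkS4class{BCCFitResult}.
#' @export
fitBccs <- function(training, table, typing,
                    inducedFrom = c("corrected", "precharges")) {
  inducedFrom <- match.arg(inducedFrom)
  nB <- nrow(table@defs)
  G <- matrix(0, nB, nB)
  cvec <- numeric(nB)
  const <- 0
  support <- logical(nB)
  for (i in seq_along(training)) {
    entry <- training[[i]]
    mol <- entry$molecule
    alphas <- if (is(typing, "PolarizabilityTypeSet"))
      assignPolarizabilities(mol, typing)$alphas else typing[[i]]
    A <- respDesignMatrix(mol, alphas, entry$baseline@grid)
    Tm <- bondTypeMatrix(mol, table)
    support <- support | colSums(abs(Tm)) > 0
    M <- if (inducedFrom == "corrected") A %*% Tm
         else respDesignMatrix(mol, alphas, entry$baseline@grid,
                               coulombOnly = TRUE) %*% Tm
    resid <- entry$baseline@values - A %*% entry$precharges
    G <- G + crossprod(M)
    cvec <- cvec + crossprod(M, resid)[, 1]
    const <- const + sum(resid^2)
  }
  B <- drop(pracma::pinv(G) %*% cvec)
  B[!support] <- 0
  names(B) <- table@defs$name
  obj <- const - 2 * sum(B * cvec) + drop(B %*% G %*% B)
  new("BCCFitResult", values = B, covered = support, objective = obj)
}

#' Assign AM1-BCC-dPol charges
#'
#' q_j = q_j^pre + sum_beta T_j,beta B_beta: population precharges plus the
#' fitted per-bond-type charge transfers. Deterministic, and conserves the
#' total charge because every column of T sums to zero.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param precharges per-atom population precharges, e
#' @param table a \linkS4class{BondTypeTable}
#' @param bccs a \linkS4class{BCCFitResult} or named numeric vector of B
#'   values (e) covering every matched type
#' @return numeric per-atom charges, e
#' @export
assignAm1BccDpol <- function(molecule, precharges, table, bccs) {
  stopifnot(length(precharges) == nAtoms(molecule))
  B <- if (is(bccs, "BCCFitResult")) bccValues(bccs) else bccs
  Tm <- bondTypeMatrix(molecule, table)
  used <- colnames(Tm)[colSums(abs(Tm)) > 0]
  missing <- used[!used %in% names(B) | is.na(B[used])]
  if (length(missing))
    stop("no BCC value for matched bond type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  Bfull <- ifelse(is.na(B[colnames(Tm)]), 0, B[colnames(Tm)])
  drop(precharges + Tm %*% Bfull)
}
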