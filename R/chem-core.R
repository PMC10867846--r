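#' @include AllClasses.R AllGenerics.R smarts.R
NULL

moleculeGraph <- function(mol) {
  b <- bondMatrix(mol)
  igraph::graph_from_edgelist(
    if (nrow(b)) b[, 1:2, drop = FALSE] else matrix(integer(0), ncol = 2),
    directed = FALSE) |>
    igraph::add_vertices(max(0L, nAtoms(mol) -
      if (nrow(b)) max(b[, 1:2]) else 0L))
}

#' Bonded-path scaling factors for charge-polarizability interactions
#'
#' Builds the symmetric pair table f with f = 0 for 1-2 and 1-3 pairs
#' (shortest bonded path length 1 or 2), f = 0.5 for 1-4 pairs (path length
#' 3), and f = 1 otherwise. In rings, the minimum path length decides.
#' Pairs in different connected components (including isolated atoms) get
#' f = 1; an atom with no bonds triggers a warning, since its classification
#' cannot use a bonded path.
#'
#' @param molecule a \linkS4class{Molecule}
#' @return A \linkS4class{ScalingTable}.
#' @export
#' @examples
#' eth <- Molecule(c("C","C","H","H","H","H","H","H"),
#'   rbind(c(0,0,0), c(1.54,0,0), c(-.5,.9,0), c(-.5,-.9,.3), c(-.5,0,-1),
#'         c(2,.9,0), c(2,-.9,.3), c(2,0,-1)),
#'   bonds = rbind(c(1,2,1), c(1,3,1), c(1,4,1), c(1,5,1),
#'                 c(2,6,1), c(2,7,1), c(2,8,1)))
#' scalingMatrix(scalingFactors(eth))[3, 6]  # H(C1)-H(C2), 1-4 pair: 0.5
scalingFactors <- function(molecule) {
  n <- nAtoms(molecule)
  g <- moleculeGraph(molecule)
  if (n > 0 && any(igraph::degree(g) == 0))
    warning("molecule has atoms with no bonds; their pair factors are 1.0")
  d <- igraph::distances(g)
  f <- matrix(1, n, n)
  f[d <= 2] <- 0
  f[d == 3] <- 0.5
  diag(f) <- 0
  new("ScalingTable", factors = f)
}

#' Assign typed polarizabilities to the atoms of a molecule
#'
#' Element scheme: direct symbol lookup. Pattern scheme: every entry is
#' tried in order and the last matching entry wins (SMIRNOFF hierarchy
#' convention), so generic patterns come first and specific overrides last.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param types a \linkS4class{PolarizabilityTypeSet} with values set
#' @return list with \code{alphas} (numeric per atom, bohr^3) and
#'   \code{typeIndex} (integer per atom: which entry assigned it)
#' @export
#' @examples
#' ts <- polTypeSet("element", c("C", "H", "O"), c(9.6, 2.6, 4.8))
#' m <- Molecule(c("C","H","H","H","H"),
#'   rbind(c(0,0,0), c(.6,.6,.6), c(-.6,-.6,.6), c(-.6,.6,-.6), c(.6,-.6,-.6)),
#'   bonds = cbind(1, 2:5, 1))
#' assignPolarizabilities(m, ts)$alphas
assignPolarizabilities <- function(molecule, types) {
  n <- nAtoms(molecule)
  idx <- rep(NA_integer_, n)
  if (types@scheme == "element") {
    idx <- match(atomElements(molecule), types@matchers)
  } else {
    ctx <- moleculeMatchContext(molecule)
    patterns <- lapply(types@matchers, parseSmarts)
    for (t in seq_along(patterns)) {
      hit <- vapply(seq_len(n), function(a)
        matchFromAnchor(ctx, patterns[[t]], a), TRUE)
      idx[hit] <- t  # later entries overwrite: last match wins
    }
  }
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop(sprintf("no polarizability type matches atom(s) %s (%s)",
                 paste(bad, collapse = ", "),
                 paste(atomElements(molecule)[bad], collapse = ", ")),
         call. = FALSE)
  }
  list(alphas = types@alphas[idx], typeIndex = idx)
}

#' Topological symmetry classes
#'
#' Partitions atoms into classes related by graph automorphisms respecting
#' elements, formal charges and bond orders, by iterative canonical-rank
#' (Morgan/Weisfeiler-Lehman) refinement of atom invariants. Used for the
#' forced symmetry restraints of stage-2 charge fitting.
#'
#' @param molecule a \linkS4class{Molecule}
#' @return integer vector of class labels (1-based, ordered by first
#'   occurrence); equal labels mean topologically equivalent atoms
#' @export
#' @examples
#' # methane: one carbon class, one hydrogen class
#' m <- Molecule(c("C","H","H","H","H"),
#'   rbind(c(0,0,0), c(.6,.6,.6), c(-.6,-.6,.6), c(-.6,.6,-.6), c(.6,-.6,-.6)),
#'   bonds = cbind(1, 2:5, 1))
#' symmetryClasses(m)
symmetryClasses <- function(molecule) {
  n <- nAtoms(molecule)
  if (n == 0) return(integer(0))
  ctx <- moleculeMatchContext(molecule)
  key <- paste(atomElements(molecule), ctx$degree, ctx$hCount,
               molecule@atomFormalCharges,
               vapply(seq_len(n), function(i)
                 paste(sort(ctx$ords[[i]]), collapse = ","), ""))
  rank <- match(key, unique(key))
  repeat {
    newKey <- vapply(seq_len(n), function(i) {
      nb <- ctx$nbrs[[i]]
      env <- if (length(nb))
        paste(sort(paste(rank[nb], ctx$ords[[i]], sep = ":")), collapse = "|")
      else ""
      paste(rank[i], env, sep = "#")
    }, "")
    newRank <- match(newKey, unique(newKey))
    if (length(unique(newRank)) == length(unique(rank))) break
    rank <- newRank
  }
  match(rank, unique(rank))
}

#' Bond-type assignment matrix
#'
#' Builds the atoms x types matrix T with T[j, beta] = (number of bonds of
#' type beta where atom j is the first-pattern end) minus (number where it is
#' the second-pattern end). Each bond is assigned to the first type in the
#' table whose bond order matches and whose two atom-environment patterns
#' match the bond's ends (in either orientation). A bond matching a type in
#' both orientations (homonuclear, identical environments) contributes zero.
#' Column sums over atoms are zero by construction, so applying corrections
#' through T conserves total charge exactly.
#'
#' @param molecule a \linkS4class{Molecule}
#' @param table a \linkS4class{BondTypeTable}
#' @return numeric matrix (nAtoms x nTypes), with the type names as colnames
#' @export
bondTypeMatrix <- function(molecule, table) {
  defs <- table@defs
  ctx <- moleculeMatchContext(molecule)
  p1 <- lapply(defs$smarts1, parseSmarts)
  p2 <- lapply(defs$smarts2, parseSmarts)
  b <- bondMatrix(molecule)
  Tm <- matrix(0, nAtoms(molecule), nrow(defs),
               dimnames = list(NULL, defs$name))
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]; ord <- b[r, 3]
    assigned <- FALSE
    for (t in seq_len(nrow(defs))) {
      if (defs$order[t] != ord) next
      fwd <- matchFromAnchor(ctx, p1[[t]], i) && matchFromAnchor(ctx, p2[[t]], j)
      rev <- matchFromAnchor(ctx, p1[[t]], j) && matchFromAnchor(ctx, p2[[t]], i)
      if (!fwd && !rev) next
      if (fwd) { Tm[i, t] <- Tm[i, t] + 1; Tm[j, t] <- Tm[j, t] - 1 }
      if (rev) { Tm[j, t] <- Tm[j, t] + 1; Tm[i, t] <- Tm[i, t] - 1 }
      assigned <- TRUE
      break
    }
    if (!assigned)
      stop(sprintf("bond %d-%d (order %d) matches no bond type",
                   i, j, ord), call. = FALSE)
  }
  Tm
}

## Stage-2 refit selection: sp3 carbons bearing >= 2 topologically
## equivalent hydrogens, plus those hydrogens (classic RESP practice).
stage2RefitAtoms <- function(molecule) {
  ctx <- moleculeMatchContext(molecule)
  classes <- symmetryClasses(molecule)
  el <- atomElements(molecule)
  sel <- logical(nAtoms(molecule))
  for (c_idx in which(el == "C")) {
    if (ctx$degree[c_idx] != 4L) next
    if (any(ctx$ords[[c_idx]] != 1L)) next     # sp3: four single bonds
    hs <- ctx$nbrs[[c_idx]][el[ctx$nbrs[[c_idx]]] == "H"]
    if (length(hs) < 2L) next
    tab <- table(classes[hs])
    eqv <- hs[classes[hs] %in% as.integer(names(tab[tab >= 2]))]
    if (length(eqv) >= 2L) sel[c(c_idx, eqv)] <- TRUE
  }
  which(sel)
}

#' Read a polarizability type set from JSON
#'
#' Format: \code{{"scheme": "element"|"pattern", "entries":
#' [{"match": ..., "alpha_bohr3": ...}, ...]}}. Entries are kept in file
#' order (hierarchy order for patterns). \code{alpha_bohr3} may be null for
#' a skeleton.
#'
#' @param path JSON file path
#' @return A \linkS4class{PolarizabilityTypeSet}.
#' @export
readPolTypeSet <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- j$entries$alpha_bohr3
  if (is.null(a)) a <- rep(NA_real_, length(j$entries$match))
  polTypeSet(j$scheme, j$entries$match, as.numeric(a))
}

#' Write a polarizability type set to JSON
#' @param types a \linkS4class{PolarizabilityTypeSet}
#' @param path output path
#' @return invisibly, the path
#' @export
writePolTypeSet <- function(types, path) {
  jsonlite::write_json(
    list(scheme = types@scheme,
         entries = data.frame(match = types@matchers,
                              alpha_bohr3 = types@alphas)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a bond-type table (with optional fitted values) from JSON
#'
#' Format: \code{{"types": [{"name":..., "smarts1":..., "smarts2":...,
#' "order":...,"bcc_e":...}, ...]}}; order may be "ar" for aromatic and
#' \code{bcc_e} is optional.
#'
#' @param path JSON file path
#' @return list with \code{table} (\linkS4class{BondTypeTable}) and
#'   \code{values} (named numeric or NULL)
#' @export
readBccTable <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- bondTypeTable(j$types$name, j$types$smarts1, j$types$smarts2,
                       j$types$order)
  vals <- NULL
  if (!is.null(j$types$bcc_e)) {
    vals <- as.numeric(j$types$bcc_e)
    names(vals) <- j$types$name
  }
  list(table = tab, values = vals)
}

#' Write a bond-type table with fitted values to JSON
#' @param table a \linkS4class{BondTypeTable}
#' @param values named numeric BCC values (e), or a
#'   \linkS4class{BCCFitResult}
#' @param path output path
#' @return invisibly, the path
#' @export
writeBccTable <- function(table, values, path) {
  if (is(values, "BCCFitResult")) values <- bccValues(values)
  d <- table@defs
  d$order <- ifelse(d$order == AROMATIC_ORDER, "ar", as.character(d$order))
  d$bcc_e <- as.numeric(values[d$name])
  jsonlite::write_json(list(types = d), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
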