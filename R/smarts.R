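## Minimal SMARTS matcher for atom-environment typing.
##
## Supported subset (documented in the methods vignette):
##   atoms    [#6], [C], [c], [CX4], [#8H1], [N+], [*], bare C/N/O/H/c/n/o, *
##   prims    #<n> atomic number; element symbol (lowercase = aromatic);
##            X<n>/D<n> degree; H<n> attached-hydrogen count; a/A aromatic/
##            aliphatic; +<n>/-<n> formal charge; * wildcard; '&'/';' AND
##   bonds    - = # : ~  (default bond = single-or-aromatic)
##   topology branches (...), single-digit ring closures
## Disjunction (','), recursive SMARTS ($(...)), stereo and maps are not
## supported and raise an error; hydrogens must be explicit atoms.

ATOMIC_NUMBERS <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L,
                    P = 15L, S = 16L, Cl = 17L, Br = 35L)

emptyAtomPred <- function() {
  list(any = FALSE, atomicNumber = NA_integer_, aromatic = NA,
       degree = NA_integer_, hCount = NA_integer_, charge = NA_integer_)
}

## Parse a SMARTS string into a pattern graph:
## list(atoms = list of predicates, bonds = data.frame(a, b, type))
parseSmarts <- function(smarts) {
  chars <- strsplit(smarts, "")[[1]]
  pos <- 1L
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  stack <- integer(0)      # open-branch anchors
  prev <- 0L               # last atom emitted
  pendingBond <- NULL      # bond symbol awaiting the next atom
  rings <- list()          # digit -> list(atom, type)

  peek <- function() if (pos <= n) chars[pos] else ""
  takeDigits <- function() {
    s <- ""
    while (pos <= n && grepl("^[0-9]$", chars[pos])) {
      s <- paste0(s, chars[pos]); pos <<- pos + 1L
    }
    s
  }
  fail <- function(what)
    stop(sprintf("unsupported SMARTS '%s': %s", smarts, what), call. = FALSE)

  parseBracket <- function() {
    pred <- emptyAtomPred()
    repeat {
      ch <- peek()
      if (ch == "]") { pos <<- pos + 1L; break }
      if (ch == "") fail("unterminated bracket atom")
      if (ch %in% c("&", ";")) { pos <<- pos + 1L; next }
      if (ch == ",") fail("disjunction (',') not supported")
      if (ch == "$") fail("recursive SMARTS not supported")
      if (ch == "#") {
        pos <<- pos + 1L
        d <- takeDigits()
        if (!nzchar(d)) fail("'#' must be followed by an atomic number")
        pred$atomicNumber <- as.integer(d)
      } else if (ch == "*") {
        pos <<- pos + 1L; pred$any <- TRUE
      } else if (ch %in% c("X", "D")) {
        pos <<- pos + 1L
        d <- takeDigits()
        if (!nzchar(d)) fail(paste0("'", ch, "' needs a count"))
        pred$degree <- as.integer(d)
      } else if (ch == "H") {
        pos <<- pos + 1L
        d <- takeDigits()
        pred$hCount <- if (nzchar(d)) as.integer(d) else 1L
      } else if (ch == "a") {
        pos <<- pos + 1L; pred$aromatic <- TRUE
      } else if (ch == "A") {
        pos <<- pos + 1L; pred$aromatic <- FALSE
      } else if (ch %in% c("+", "-")) {
        sign <- if (ch == "+") 1L else -1L
        pos <<- pos + 1L
        reps <- 1L
        while (peek() == ch) { reps <- reps + 1L; pos <<- pos + 1L }
        d <- takeDigits()
        pred$charge <- sign * (if (nzchar(d)) as.integer(d) else reps)
      } else if (grepl("^[A-Z]$", ch)) {
        sym <- ch; pos <<- pos + 1L
        if (grepl("^[a-z]$", peek()) &&
            paste0(sym, peek()) %in% names(ATOMIC_NUMBERS)) {
          sym <- paste0(sym, peek()); pos <<- pos + 1L
        }
        if (!sym %in% names(ATOMIC_NUMBERS))
          fail(paste("unknown element", sym))
        pred$atomicNumber <- ATOMIC_NUMBERS[[sym]]
        pred$aromatic <- FALSE
      } else if (grepl("^[a-z]$", ch)) {
        sym <- toupper(ch); pos <<- pos + 1L
        if (!sym %in% names(ATOMIC_NUMBERS))
          fail(paste("unknown aromatic element", ch))
        pred$atomicNumber <- ATOMIC_NUMBERS[[sym]]
        pred$aromatic <- TRUE
      } else {
        fail(paste("unsupported primitive", ch))
      }
    }
    pred
  }

  addAtom <- function(pred) {
    atoms[[length(atoms) + 1L]] <<- pred
    idx <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<-
        list(a = prev, b = idx,
             type = if (is.null(pendingBond)) "default" else pendingBond)
    }
    pendingBond <<- NULL
    prev <<- idx
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "[") {
      pos <- pos + 1L
      addAtom(parseBracket())
    } else if (grepl("^[A-Z]$", ch)) {
      sym <- ch; pos <- pos + 1L
      if (grepl("^[a-z]$", peek()) &&
          paste0(sym, peek()) %in% names(ATOMIC_NUMBERS)) {
        sym <- paste0(sym, peek()); pos <- pos + 1L
      }
      if (!sym %in% names(ATOMIC_NUMBERS)) fail(paste("unknown element", sym))
      pred <- emptyAtomPred()
      pred$atomicNumber <- ATOMIC_NUMBERS[[sym]]
      pred$aromatic <- FALSE
      addAtom(pred)
    } else if (grepl("^[a-z]$", ch)) {
      sym <- toupper(ch); pos <- pos + 1L
      if (!sym %in% names(ATOMIC_NUMBERS))
        fail(paste("unknown aromatic element", ch))
      pred <- emptyAtomPred()
      pred$atomicNumber <- ATOMIC_NUMBERS[[sym]]
      pred$aromatic <- TRUE
      addAtom(pred)
    } else if (ch == "*") {
      pos <- pos + 1L
      pred <- emptyAtomPred(); pred$any <- TRUE
      addAtom(pred)
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pendingBond <- ch; pos <- pos + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("^[0-9]$", ch)) {
      key <- ch; pos <- pos + 1L
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev,
                             type = if (is.null(pendingBond)) "default"
                                    else pendingBond)
        pendingBond <- NULL
      } else {
        open <- rings[[key]]
        type <- if (!is.null(pendingBond)) pendingBond else open$type
        bonds[[length(bonds) + 1L]] <- list(a = open$atom, b = prev,
                                            type = type)
        rings[[key]] <- NULL
        pendingBond <- NULL
      }
    } else {
      fail(paste("unexpected character", ch))
    }
  }
  if (length(Filter(Negate(is.null), rings))) fail("unclosed ring bond")
  if (!length(atoms)) fail("no atoms")
  list(atoms = atoms,
       bonds = if (length(bonds))
         do.call(rbind, lapply(bonds, as.data.frame))
       else data.frame(a = integer(0), b = integer(0),
                       type = character(0)))
}

## Per-molecule context used by the matcher (computed once per molecule).
moleculeMatchContext <- function(mol) {
  n <- nAtoms(mol)
  b <- bondMatrix(mol)
  nbrs <- vector("list", n)
  ords <- vector("list", n)
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]; o <- b[r, 3]
      nbrs[[i]] <- c(nbrs[[i]], j); ords[[i]] <- c(ords[[i]], o)
      nbrs[[j]] <- c(nbrs[[j]], i); ords[[j]] <- c(ords[[j]], o)
    }
  }
  elements <- atomElements(mol)
  z <- unname(ATOMIC_NUMBERS[elements])
  degree <- vapply(nbrs, length, 1L)
  hCount <- vapply(seq_len(n), function(i)
    sum(elements[nbrs[[i]]] == "H"), 1L)
  aromatic <- vapply(seq_len(n), function(i)
    any(ords[[i]] == AROMATIC_ORDER), TRUE)
  list(n = n, z = z, degree = degree, hCount = hCount, aromatic = aromatic,
       charge = mol@atomFormalCharges, nbrs = nbrs, ords = ords)
}

atomPredOk <- function(ctx, i, pred) {
  if (pred$any) return(TRUE)
  if (!is.na(pred$atomicNumber) &&
      (is.na(ctx$z[i]) || ctx$z[i] != pred$atomicNumber)) return(FALSE)
  if (!is.na(pred$aromatic) && ctx$aromatic[i] != pred$aromatic) return(FALSE)
  if (!is.na(pred$degree) && ctx$degree[i] != pred$degree) return(FALSE)
  if (!is.na(pred$hCount) && ctx$hCount[i] != pred$hCount) return(FALSE)
  if (!is.na(pred$charge) && ctx$charge[i] != pred$charge) return(FALSE)
  TRUE
}

bondTypeOk <- function(order, type) {
  switch(type,
         "-" = order == 1L,
         "=" = order == 2L,
         "#" = order == 3L,
         ":" = order == AROMATIC_ORDER,
         "~" = TRUE,
         "default" = order == 1L || order == AROMATIC_ORDER,
         stop("unknown bond type ", type))
}

## Backtracking embedding of the pattern with pattern atom 1 anchored at
## molecule atom `anchor`. Injective over molecule atoms.
matchFromAnchor <- function(ctx, pattern, anchor) {
  np <- length(pattern$atoms)
  if (!atomPredOk(ctx, anchor, pattern$atoms[[1L]])) return(FALSE)
  if (np == 1L) return(TRUE)
  pb <- pattern$bonds
  ## adjacency of the pattern graph
  padj <- vector("list", np)
  if (nrow(pb)) for (r in seq_len(nrow(pb))) {
    padj[[pb$a[r]]] <- c(padj[[pb$a[r]]], r)
    padj[[pb$b[r]]] <- c(padj[[pb$b[r]]], r)
  }
  map <- rep(NA_integer_, np)
  map[1L] <- anchor

  extend <- function(map) {
    free <- which(is.na(map))
    if (!length(free)) return(TRUE)
    ## next pattern atom adjacent to a mapped one (pattern is connected)
    nxt <- NA_integer_; via <- NULL
    for (p in free) {
      brs <- padj[[p]]
      anchored <- brs[!is.na(map[ifelse(pb$a[brs] == p, pb$b[brs], pb$a[brs])])]
      if (length(anchored)) { nxt <- p; via <- anchored; break }
    }
    if (is.na(nxt)) return(TRUE)  # disconnected pattern piece: vacuous
    r0 <- via[1L]
    other <- if (pb$a[r0] == nxt) pb$b[r0] else pb$a[r0]
    mOther <- map[other]
    cands <- ctx$nbrs[[mOther]]
    cords <- ctx$ords[[mOther]]
    for (ci in seq_along(cands)) {
      cand <- cands[ci]
      if (cand %in% map) next
      if (!bondTypeOk(cords[ci], pb$type[r0])) next
      if (!atomPredOk(ctx, cand, pattern$atoms[[nxt]])) next
      ## all other pattern bonds from nxt into the mapped set must exist
      ok <- TRUE
      for (r in padj[[nxt]]) {
        if (r == r0) next
        oth <- if (pb$a[r] == nxt) pb$b[r] else pb$a[r]
        mo <- map[oth]
        if (is.na(mo)) next
        k <- which(ctx$nbrs[[cand]] == mo)
        if (!length(k) || !bondTypeOk(ctx$ords[[cand]][k[1L]], pb$type[r])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      map2 <- map; map2[nxt] <- cand
      if (extend(map2)) return(TRUE)
    }
    FALSE
  }
  extend(map)
}

#' Match a SMARTS pattern against one atom
#'
#' Tests whether the first atom of \code{smarts} can be embedded at atom
#' \code{atom} of \code{mol}, using the package's documented SMARTS subset.
#'
#' @param mol a \linkS4class{Molecule}
#' @param atom atom index (1-based)
#' @param smarts pattern string, or a pre-parsed pattern from
#'   \code{parseSmarts} (internal)
#' @param ctx optional precomputed match context (internal reuse)
#' @return logical
#' @export
#' @examples
#' m <- Molecule(c("C", "O", "H", "H", "H", "H"),
#'   rbind(c(0,0,0), c(1.43,0,0), c(-.5,.9,0), c(-.5,-.5,.9),
#'         c(-.5,-.5,-.9), c(1.8,.9,0)),
#'   bonds = rbind(c(1,2,1), c(1,3,1), c(1,4,1), c(1,5,1), c(2,6,1)))
#' smartsMatchesAtom(m, 1, "[#6X4]-[#8]")  # alcohol carbon
smartsMatchesAtom <- function(mol, atom, smarts, ctx = NULL) {
  pattern <- if (is.character(smarts)) parseSmarts(smarts) else smarts
  if (is.null(ctx)) ctx <- moleculeMatchContext(mol)
  matchFromAnchor(ctx, pattern, atom)
}
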