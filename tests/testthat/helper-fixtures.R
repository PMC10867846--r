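## Hand-built molecules and independent oracles shared across tests.

BOHR <- 1.8897261254578281

ethaneMol <- function() {
  ct <- -1 / 3; st <- 2 * sqrt(2) / 3
  phi <- c(0, 120, 240) * pi / 180
  h1 <- 1.09 * cbind(rep(ct, 3), st * cos(phi), st * sin(phi))
  h2 <- sweep(-h1, 2, c(1.54, 0, 0), "+")
  Molecule(c("C", "C", rep("H", 6)),
           rbind(c(0, 0, 0), c(1.54, 0, 0), h1, h2),
           bonds = rbind(c(1, 2, 1), cbind(1, 3:5, 1), cbind(2, 6:8, 1)))
}

butaneMol <- function() {
  ## idealized all-anti backbone; hydrogens only where the tests need them
  cpos <- rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.3, 1.33, 0), c(3.84, 1.33, 0))
  h4 <- c(4.4, 2.28, 0)   # one hydrogen on C4
  Molecule(c("C", "C", "C", "C", "H"),
           rbind(cpos, h4),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1)))
}

methanolMol <- function() {
  readMoleculeSDF(system.file("extdata", "methanol.sdf",
                              package = "dpolkit"))[[1]]
}

ethanolMol <- function() {
  ct <- -1 / 3; st <- 2 * sqrt(2) / 3
  phi <- c(0, 120, 240) * pi / 180
  hMe <- 1.09 * cbind(rep(ct, 3), st * cos(phi), st * sin(phi))
  Molecule(c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
           rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.1, 1.3, 0),
                 hMe,
                 c(1.9, -0.5, 0.9), c(1.9, -0.5, -0.9),
                 c(3.06, 1.25, 0)),
           bonds = rbind(c(1, 2, 1), c(2, 3, 1), cbind(1, 4:6, 1),
                         c(2, 7, 1), c(2, 8, 1), c(3, 9, 1)))
}

formaldehydeMol <- function() {
  Molecule(c("C", "O", "H", "H"),
           rbind(c(0, 0, 0), c(1.21, 0, 0),
                 c(-0.55, 0.94, 0), c(-0.55, -0.94, 0)),
           bonds = rbind(c(1, 2, 2), c(1, 3, 1), c(1, 4, 1)))
}

## random connected molecule: spanning tree plus optional ring-closing edge
randomMolecule <- function(n, ring = FALSE, elements = c("C", "H", "O", "N")) {
  el <- sample(elements, n, replace = TRUE)
  xyz <- matrix(runif(n * 3, -4, 4), n, 3)
  bonds <- NULL
  if (n > 1)
    bonds <- cbind(vapply(2:n, function(k) sample.int(k - 1, 1), 1L), 2:n, 1L)
  if (ring && n >= 4) {
    repeat {
      cand <- sort(sample.int(n, 2))
      key <- paste(bonds[, 1], bonds[, 2])
      if (!paste(cand[1], cand[2]) %in% key) break
    }
    bonds <- rbind(bonds, c(cand, 1))
  }
  Molecule(el, xyz, bonds)
}

## breadth-first-search shortest bonded path length (independent of igraph)
bfsPathLength <- function(n, bonds, from, to) {
  if (from == to) return(0L)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      if (w == to) return(dist[w])
      queue <- c(queue, w)
    }
  }
  NA_integer_
}

bfsScalingOracle <- function(mol) {
  n <- nAtoms(mol)
  b <- bondMatrix(mol)
  f <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { f[i, j] <- 0; next }
    d <- bfsPathLength(n, b, i, j)
    f[i, j] <- if (!is.na(d) && d <= 2) 0 else if (!is.na(d) && d == 3) 0.5 else 1
  }
  f
}

## plain-loop oracles for the physics core
fieldOracle <- function(mol, charges, externalField = c(0, 0, 0)) {
  xyz <- atomCoords(mol)
  f <- bfsScalingOracle(mol)
  n <- nAtoms(mol)
  E <- matrix(rep(externalField, each = n), n, 3)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    d <- xyz[j, ] - xyz[k, ]
    E[j, ] <- E[j, ] + f[j, k] * charges[k] * d / sum(d^2)^1.5
  }
  E
}

espOracle <- function(mol, charges, dipoles, pts) {
  xyz <- atomCoords(mol)
  V <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) for (j in seq_len(nAtoms(mol))) {
    r <- pts[i, ] - xyz[j, ]
    rn <- sqrt(sum(r^2))
    V[i] <- V[i] + charges[j] / rn
    if (!is.null(dipoles)) V[i] <- V[i] + sum(dipoles[j, ] * r) / rn^3
  }
  V
}

rotationMatrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotateMolecule <- function(mol, R) {
  Molecule(atomElements(mol), atomCoords(mol) %*% t(R),
           bondMatrix(mol), formalCharge(mol), units = "bohr",
           name = mol@name, conformerId = mol@conformerId,
           atomFormalCharges = mol@atomFormalCharges)
}

## small grid specs keep unit tests fast; the full default spec is used
## where a test is specifically about the study protocol
tinyGrid <- function() mskGridSpec(nLayers = 2, density = 2)

toyBccTable <- function() {
  bondTypeTable(
    name = c("c4-c3", "c4-c4", "c-o", "c=o", "c-n", "ar-cc", "ar-ch",
             "c-h", "o-h", "n-h"),
    smarts1 = c("[#6X4]", "[#6X4]", "[#6]", "[#6]", "[#6]", "[c]", "[c]",
                "[#6]", "[#8]", "[#7]"),
    smarts2 = c("[#6X3]", "[#6X4]", "[#8]", "[#8]", "[#7]", "[c]", "[#1]",
                "[#1]", "[#1]", "[#1]"),
    order = c(1, 1, 1, 2, 1, "ar", 1, 1, 1, 1))
}
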