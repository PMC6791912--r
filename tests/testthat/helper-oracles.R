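# Independent oracles and shared fixtures for the test suite. Everything here
# is deliberately written as plain loops, separate from the package's
# vectorized/igraph-based implementations.

# small named fixture set, all <= 14 heavy atoms
fixtureSmiles <- function() c(
  chloromethane  = "CCl",
  ethane         = "CC",
  dichloromethane = "ClCCl",
  propane        = "CCC",
  chloropropane  = "CCCCl",
  nbutane        = "CCCC",
  isobutane      = "CC(C)C",
  neopentane     = "CC(C)(C)C",
  ndecane        = "CCCCCCCCCC",
  ethene         = "C=C",
  benzene        = "c1ccccc1",
  chlorobenzene  = "c1ccccc1Cl",
  dichlorophenol = "C1=CC(=C(C=C1Cl)Cl)O",
  acetone        = "CC(C)=O",
  trimethylamine = "CN(C)C",
  chloroanisole  = "COC1=CC=C(C=C1)Cl",
  acidchloride   = "CCC(=O)Cl",
  thioether      = "CCSC",
  pyridine       = "c1ccncc1")

# adjacency list from a MolecularGraph's bond table
adjList <- function(g) {
  bd <- chloroMS::bonds(g)
  n <- chloroMS::atomCount(g)
  adj <- vector("list", n)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], bd$j[k])
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], bd$i[k])
  }
  adj
}

# plain BFS all-pairs distances
bfsDistances <- function(g) {
  adj <- adjList(g)
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!is.finite(D[s, w])) {
        D[s, w] <- D[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  D
}

# brute-force E-state by the double loop over all atom pairs
bruteEstate <- function(g) {
  I <- chloroMS::intrinsicStates(g)
  D <- bfsDistances(g)
  n <- length(I)
  S <- numeric(n)
  for (i in seq_len(n)) {
    s <- I[i]
    for (j in seq_len(n)) if (j != i && is.finite(D[i, j]))
      s <- s + (I[i] - I[j]) / (D[i, j] + 1)^2
    S[i] <- s
  }
  S
}

# exhaustive simple-path enumeration: sum of bond-order products per length
brutePathSums <- function(g, maxOrder) {
  bd <- chloroMS::bonds(g)
  n <- chloroMS::atomCount(g)
  nb <- vector("list", n)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    nb[[bd$i[k]]] <- rbind(nb[[bd$i[k]]], c(bd$j[k], bd$order[k]))
    nb[[bd$j[k]]] <- rbind(nb[[bd$j[k]]], c(bd$i[k], bd$order[k]))
  }
  sums <- numeric(maxOrder)
  walk <- function(path, prod) {
    v <- path[length(path)]
    for (r in seq_len(NROW(nb[[v]]))) {
      if (is.null(nb[[v]])) break
      w <- nb[[v]][r, 1]
      if (w %in% path) next
      d <- length(path)           # bonds in the extended path
      p2 <- prod * nb[[v]][r, 2]
      # count only paths whose endpoints satisfy start < end (each once)
      if (w > path[1]) sums[d] <<- sums[d] + p2
      if (d < maxOrder) walk(c(path, w), p2)
    }
  }
  for (s in seq_len(n)) walk(s, 1)
  sums
}

# brute-force Mann-Whitney AUC: all-pairs comparison of class-1 vs class-2
# scores, ties counted half
aucByPairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s2 <- scores[labels == 2]
  tot <- 0
  for (a in s1) for (b in s2)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s2))
}

# independent Galvez charge index: explicit loops over pairs and bonds
bruteGalvez <- function(g, order) {
  D <- bfsDistances(g)
  bd <- chloroMS::bonds(g)
  n <- nrow(D)
  m <- function(i, j) {
    # M_ij = sum_k A_ik * Dstar_kj
    tot <- 0
    for (r in seq_len(nrow(bd))) {
      k <- if (bd$i[r] == i) bd$j[r] else if (bd$j[r] == i) bd$i[r] else next
      if (k != j && is.finite(D[k, j]) && D[k, j] > 0) tot <- tot + 1 / D[k, j]^2
    }
    tot
  }
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (is.finite(D[i, j]) && D[i, j] == order)
      tot <- tot + abs(m(i, j) - m(j, i))
  tot
}

# independent Barysz VE1: predecessor-tracking BFS paths + dense eigen
bruteBaryszVE1 <- function(g, weighting) {
  at <- chloroMS::atoms(g)
  bd <- chloroMS::bonds(g)
  zTab <- c(C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
            Cl = 17, Br = 35, I = 53)
  mTab <- c(C = 12.011, N = 14.007, O = 15.999, F = 18.998, Si = 28.085,
            P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904)
  w <- if (weighting == "mass") mTab[at$element] else zTab[at$element]
  wC <- if (weighting == "mass") mTab[["C"]] else zTab[["C"]]
  n <- nrow(at)
  adj <- adjList(g)
  bondOrder <- function(i, j) {
    for (r in seq_len(nrow(bd)))
      if ((bd$i[r] == i && bd$j[r] == j) || (bd$i[r] == j && bd$j[r] == i))
        return(bd$order[r])
    stop("no bond")
  }
  B <- matrix(0, n, n)
  diag(B) <- 1 - wC / w
  for (s in seq_len(n)) {
    pred <- rep(NA_integer_, n); dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!is.finite(dist[u])) {
        dist[u] <- dist[v] + 1; pred[u] <- v; queue <- c(queue, u)
      }
    }
    for (t in seq_len(n)) {
      if (t == s || !is.finite(dist[t])) next
      v <- t; tot <- 0
      while (v != s) {
        tot <- tot + wC^2 / (bondOrder(pred[v], v) * w[pred[v]] * w[v])
        v <- pred[v]
      }
      B[s, t] <- tot
    }
  }
  B <- (B + t(B)) / 2        # path choice may differ by direction; symmetrize
  e <- eigen(B, symmetric = TRUE)
  sum(abs(e$vectors[, which.max(e$values)]))
}

# multiset invariants of a molecular graph, for isomorphism-style comparison
graphSignature <- function(g) {
  at <- chloroMS::atoms(g)
  bd <- chloroMS::bonds(g)
  list(atoms = sort(paste(at$element, at$hcount, at$aromatic, at$charge)),
       bonds = sort(table(bd$order)),
       degrees = sort(vapply(seq_len(nrow(at)), function(i)
         sum(bd$i == i | bd$j == i), 0L)))
}
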