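#' Per-atom electron state: delta, delta-v and principal quantum number
#'
#' The Kier-Hall atomic inputs to the electrotopological state: `delta` is
#' the count of sigma-bonded heavy neighbours, `deltav` the valence-electron
#' count minus bonded hydrogens (charge-adjusted: a positive charge removes a
#' valence electron), and `quantum` the principal quantum number of the
#' element's valence shell (C,N,O,F = 2; Si,P,S,Cl = 3; Br = 4; I = 5).
#'
#' @param graph a [MolecularGraph-class]
#' @return data.frame with columns `delta`, `deltav`, `quantum`, one row per
#'   heavy atom
#' @export
electronStates <- function(graph) {
  at <- graph@atoms
  info <- .elementInfo(at$element)
  deg <- integer(nrow(at))
  bd <- graph@bonds
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    deg[bd$i[k]] <- deg[bd$i[k]] + 1L
    deg[bd$j[k]] <- deg[bd$j[k]] + 1L
  }
  data.frame(delta = deg,
             deltav = (info$Zv - at$charge) - at$hcount,
             quantum = info$quantum)
}

# E-state atom-type bond letters, ordered d < t < a < s (dsCH, tsC, aasC, ...)
.BOND_LETTER_PRIORITY <- c(d = 1L, t = 2L, a = 3L, s = 4L)

#' E-state atom-type symbols
#'
#' Classifies every heavy atom by its bond environment: one letter per
#' incident bond (s = single, d = double, t = triple, a = aromatic, ordered
#' d, t, a, s), the element symbol, and a trailing hydrogen count, e.g.
#' `aasC` (ring carbon bearing a substituent), `sssN`, `dO`, `aaCH`, `sOH`.
#' The classification depends only on (element, incident bond orders, H
#' count).
#'
#' @param graph a [MolecularGraph-class]
#' @return character vector of type symbols, one per heavy atom
#' @export
estateAtomTypes <- function(graph) {
  at <- graph@atoms
  bd <- graph@bonds
  letters <- vector("list", nrow(at))
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    l <- switch(as.character(bd$order[k]), "1" = "s", "2" = "d", "3" = "t", "1.5" = "a")
    letters[[bd$i[k]]] <- c(letters[[bd$i[k]]], l)
    letters[[bd$j[k]]] <- c(letters[[bd$j[k]]], l)
  }
  vapply(seq_len(nrow(at)), function(a) {
    ll <- letters[[a]]
    ll <- ll[order(.BOND_LETTER_PRIORITY[ll])]
    h <- at$hcount[a]
    hsuf <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    paste0(paste(ll, collapse = ""), at$element[a], hsuf)
  }, "")
}

#' Intrinsic states
#'
#' Kier-Hall intrinsic state of each heavy atom,
#' \eqn{I = ((2/N)^2 \delta^v + 1) / \delta}: the electronic character an
#' atom would have in isolation from the rest of the molecule.
#'
#' @param graph a [MolecularGraph-class]
#' @return numeric vector, one positive finite value per heavy atom
#' @export
intrinsicStates <- function(graph) {
  es <- electronStates(graph)
  if (any(es$delta == 0))
    stop("degenerate molecule: isolated heavy atom (delta = 0) has no intrinsic state")
  ((2 / es$quantum)^2 * es$deltav + 1) / es$delta
}

#' Electrotopological state (E-state) indices
#'
#' Per-atom E-state \eqn{S_i = I_i + \sum_{j \ne i} (I_i - I_j)/(d_{ij}+1)^2}
#' with \eqn{d_{ij}} the topological distance in bonds. The pairwise
#' perturbations are antisymmetric, so \eqn{\sum_i S_i = \sum_i I_i} exactly.
#'
#' @param graph a [MolecularGraph-class]
#' @return numeric vector of E-state values, one per heavy atom
#' @export
estateIndices <- function(graph) {
  I <- intrinsicStates(graph)
  D <- distanceMatrix(graph)
  W <- 1 / (D + 1)^2
  W[!is.finite(W)] <- 0        # disconnected fragments do not interact
  diag(W) <- 0
  as.numeric(I + I * rowSums(W) - W %*% I)
}

#' Atom-type E-state aggregates
#'
#' Count, minimum and maximum of the E-state index S over each atom type
#' present in the molecule, named `n<type>`, `min<type>`, `max<type>` (e.g.
#' `minaasC`, `nsssN`, `maxdO`). Types absent from the molecule follow the
#' empty-type policy: 0 by default, or NA with `emptyAs = NA`.
#'
#' @param graph a [MolecularGraph-class]
#' @param types optional character vector of type symbols to report; default
#'   is all types present in the molecule
#' @param emptyAs value emitted for min/max/count of an absent type (0, the
#'   common descriptor-software convention, or NA)
#' @return named numeric vector
#' @export
estateAggregates <- function(graph, types = NULL, emptyAs = 0) {
  S <- estateIndices(graph)
  ty <- estateAtomTypes(graph)
  if (is.null(types)) types <- sort(unique(ty))
  out <- numeric(0)
  for (tt in types) {
    s <- S[ty == tt]
    if (length(s)) {
      vals <- c(length(s), min(s), max(s))
    } else {
      vals <- rep(as.numeric(emptyAs), 3)
      vals[1] <- 0                      # a count is 0 regardless of policy
    }
    names(vals) <- paste0(c("n", "min", "max"), tt)
    out <- c(out, vals)
  }
  out
}
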