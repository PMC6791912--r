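# carbon hybridization: sp from a triple bond or two double bonds, sp2 from
# aromaticity or one double bond, sp3 otherwise
.hybridization <- function(graph) {
  at <- graph@atoms; bd <- graph@bonds
  nd <- integer(nrow(at)); nt <- integer(nrow(at))
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    if (bd$order[k] == 2) { nd[bd$i[k]] <- nd[bd$i[k]] + 1L; nd[bd$j[k]] <- nd[bd$j[k]] + 1L }
    if (bd$order[k] == 3) { nt[bd$i[k]] <- nt[bd$i[k]] + 1L; nt[bd$j[k]] <- nt[bd$j[k]] + 1L }
  }
  ifelse(nt >= 1L | nd >= 2L, 1L, ifelse(at$aromatic | nd == 1L, 2L, 3L))
}

.neighborList <- function(graph) {
  adj <- vector("list", nrow(graph@atoms))
  bd <- graph@bonds
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], bd$j[k])
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], bd$i[k])
  }
  adj
}

.CARBON_TYPE_NAMES <- c("C1SP1", "C2SP1", "C1SP2", "C2SP2", "C3SP2",
                        "C1SP3", "C2SP3", "C3SP3", "C4SP3")

#' Carbon-type counts (CkSPn)
#'
#' Counts carbons of hybridization SPn bonded to exactly k other carbon
#' atoms; aromatic carbons count as sp2. C2SP2, for example, is an sp2 carbon
#' attached to two other carbons -- the signature of internal aromatic /
#' conjugated carbons.
#'
#' @param graph a [MolecularGraph-class]
#' @return named numeric vector C1SP1, C2SP1, C1SP2..C3SP2, C1SP3..C4SP3
#' @export
carbonTypes <- function(graph) {
  at <- graph@atoms
  hyb <- .hybridization(graph)
  adj <- .neighborList(graph)
  out <- stats::setNames(numeric(length(.CARBON_TYPE_NAMES)), .CARBON_TYPE_NAMES)
  for (a in which(at$element == "C")) {
    k <- sum(at$element[adj[[a]]] == "C")
    nm <- paste0("C", k, "SP", hyb[a])
    if (nm %in% names(out)) out[nm] <- out[nm] + 1
  }
  out
}

#' Bond-order-weighted path counts (piPCn)
#'
#' \eqn{piPC_n = \ln(1 + \sum_p \prod_k b_k)} over all simple paths p of n
#' bonds, each undirected path counted once, with conventional bond orders
#' (aromatic = 1.5) multiplied along the path. No path of that length gives
#' 0.
#'
#' @param graph a [MolecularGraph-class]
#' @param maxOrder longest path length (in bonds) to report
#' @return named numeric vector piPC1..piPC\code{maxOrder}
#' @export
piPathCounts <- function(graph, maxOrder = 10L) {
  nA <- nrow(graph@atoms)
  bd <- graph@bonds
  adj <- vector("list", nA)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], list(c(bd$j[k], bd$order[k])))
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], list(c(bd$i[k], bd$order[k])))
  }
  sums <- numeric(maxOrder)
  onPath <- logical(nA)
  dfs <- function(v, depth, prod) {
    for (e in adj[[v]]) {
      w <- e[1]
      if (onPath[w]) next
      p2 <- prod * e[2]
      sums[depth] <<- sums[depth] + p2
      if (depth < maxOrder) {
        onPath[w] <<- TRUE
        dfs(w, depth + 1L, p2)
        onPath[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(nA)) {
    onPath[s] <- TRUE
    dfs(s, 1L, 1)
    onPath[s] <- FALSE
  }
  out <- log(1 + sums / 2)   # each undirected path was found from both ends
  names(out) <- paste0("piPC", seq_len(maxOrder))
  out
}

#' Barysz-matrix eigenvector descriptor (VE1)
#'
#' Builds the Barysz weighted distance matrix -- diagonal
#' \eqn{1 - w_C/w_i}; off-diagonal the sum over bonds k on the shortest
#' topological i-j path of \eqn{w_C^2/(b_k w_a w_b)} with \eqn{b_k} the
#' conventional bond order (aromatic 1.5) -- and returns the sum of absolute
#' components of the unit eigenvector of the largest eigenvalue
#' (sign-invariant by construction). Weighting by atomic mass gives VE1_Dzm,
#' by atomic number VE1_DzZ.
#'
#' @param graph a connected [MolecularGraph-class] with at least 2 heavy
#'   atoms; for a disconnected graph the largest component is used with a
#'   warning
#' @param weighting "mass" or "atomic-number"
#' @return a single numeric value
#' @export
baryszVE1 <- function(graph, weighting = c("mass", "atomic-number")) {
  weighting <- match.arg(weighting)
  at <- graph@atoms
  info <- .elementInfo(at$element)
  w <- if (weighting == "mass") info$mass else info$Z
  wC <- if (weighting == "mass") .ELEMENTS["C", "mass"] else .ELEMENTS["C", "Z"]
  ig <- .asIgraph(graph)
  comp <- igraph::components(ig)
  keep <- seq_len(nrow(at))
  if (comp$no > 1) {
    warning("disconnected graph: Barysz descriptor computed on the largest component")
    keep <- which(comp$membership == which.max(comp$csize))
    ig <- igraph::induced_subgraph(ig, keep)
    w <- w[keep]
  }
  nA <- length(keep)
  if (nA < 2) stop("Barysz descriptor needs at least 2 connected heavy atoms")
  # per-bond weight wC^2/(b * w_a * w_b), summed along one shortest path
  eo <- igraph::as_edgelist(ig, names = FALSE)
  bw <- wC^2 / (igraph::E(ig)$order * w[eo[, 1]] * w[eo[, 2]])
  B <- matrix(0, nA, nA)
  diag(B) <- 1 - wC / w
  for (i in seq_len(nA - 1L)) {
    sp <- igraph::shortest_paths(ig, from = i, to = (i + 1L):nA, output = "epath")
    for (t in seq_along(sp$epath)) {
      val <- sum(bw[as.integer(sp$epath[[t]])])
      B[i, i + t] <- B[i + t, i] <- val
    }
  }
  e <- eigen(B, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  sum(abs(v))
}

#' Extended topochemical atom shape index (ETA_Shape_Y)
#'
#' Fraction of the molecule's total ETA alpha contributed by Y-shaped
#' (heavy-atom degree 3) vertices, with
#' \eqn{\alpha_i = ((Z_i - Z^v_i)/Z^v_i) \cdot 1/(N_i - 1)}. Always in
#' \[0, 1\].
#'
#' @param graph a [MolecularGraph-class]
#' @return a single numeric value
#' @export
etaShapeY <- function(graph) {
  at <- graph@atoms
  info <- .elementInfo(at$element)
  alpha <- ((info$Z - info$Zv) / info$Zv) * (1 / (info$quantum - 1))
  deg <- lengths(.neighborList(graph))
  tot <- sum(alpha)
  if (tot == 0) return(0)
  sum(alpha[deg == 3L]) / tot
}

#' Galvez topological charge index (GGIk)
#'
#' With A the (unit) adjacency matrix and D* the elementwise inverse-square
#' topological distance matrix (zero diagonal), forms M = A D* and the
#' antisymmetric charge-transfer matrix CT = M - M'; GGIk sums |CT_ij| over
#' atom pairs at topological distance k.
#'
#' @param graph a [MolecularGraph-class]
#' @param order topological distance k (>= 1)
#' @return a single numeric value (0 when no pair lies at distance k)
#' @export
galvezChargeIndex <- function(graph, order) {
  stopifnot(order >= 1)
  nA <- nrow(graph@atoms)
  if (nA < 2) return(0)
  D <- distanceMatrix(graph)
  A <- matrix(0, nA, nA)
  bd <- graph@bonds
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    A[bd$i[k], bd$j[k]] <- 1
    A[bd$j[k], bd$i[k]] <- 1
  }
  Ds <- 1 / D^2
  Ds[!is.finite(Ds)] <- 0
  M <- A %*% Ds
  CT <- M - t(M)
  sel <- D == order & upper.tri(D)
  sum(abs(CT[sel]))
}

#' Simple rule-based counts
#'
#' Two documented counts:
#' \describe{
#'   \item{nHBAcc}{hydrogen-bond acceptor count: N and O atoms, excluding
#'     pyrrole-type aromatic N (aromatic N carrying H or three connections),
#'     amide N (N single-bonded to a carbonyl carbon), and aromatic O.
#'     Carbonyl O accepts.}
#'   \item{nHCsatu}{count of hydrogens attached to saturated (sp3) carbons.}
#' }
#'
#' @param graph a [MolecularGraph-class]
#' @return named numeric vector `nHBAcc`, `nHCsatu`
#' @export
simpleCounts <- function(graph) {
  at <- graph@atoms
  adj <- .neighborList(graph)
  hyb <- .hybridization(graph)
  bd <- graph@bonds
  # carbonyl carbons: C with a double bond to O
  carbonylC <- logical(nrow(at))
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    if (bd$order[k] == 2) {
      i <- bd$i[k]; j <- bd$j[k]
      if (at$element[i] == "C" && at$element[j] == "O") carbonylC[i] <- TRUE
      if (at$element[j] == "C" && at$element[i] == "O") carbonylC[j] <- TRUE
    }
  }
  acc <- 0L
  for (a in seq_len(nrow(at))) {
    el <- at$element[a]
    if (!el %in% c("N", "O")) next
    if (el == "O" && at$aromatic[a]) next
    if (el == "N") {
      if (at$aromatic[a] && (at$hcount[a] > 0 || length(adj[[a]]) >= 3)) next
      if (!at$aromatic[a] && any(carbonylC[adj[[a]]])) next   # amide N
    }
    acc <- acc + 1L
  }
  nHCsatu <- sum(at$hcount[at$element == "C" & hyb == 3L])
  c(nHBAcc = as.numeric(acc), nHCsatu = as.numeric(nHCsatu))
}
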