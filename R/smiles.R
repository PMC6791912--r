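#' Parse a SMILES string into a MolecularGraph
#'
#' Builds the hydrogen-suppressed heavy-atom graph: elements, formal charges,
#' implicit hydrogen counts, bond orders, and perceived aromaticity. Both
#' aromatic (lowercase) and Kekulé ring writings are accepted and normalized
#' to the same internal representation: Kekulé rings of sp2-capable atoms are
#' aromatized when their ring pi-electron count satisfies the Hückel 4n+2
#' rule. Stereo bond tokens (`/`, `\`) and chirality marks are parsed and
#' discarded. Implicit hydrogen counts follow the usual organic-subset
#' valence rules and are assigned before aromatization, so Kekulé and
#' aromatic writings of the same molecule yield identical graphs.
#'
#' @param smiles a single non-empty SMILES string
#' @return a [MolecularGraph-class] object
#' @examples
#' g <- parseSmiles("ClCCl")
#' atomCount(g)
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SMILES must be a single non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  atoms <- list()   # each: element, charge, hset (explicit H from brackets), aromatic
  bonds <- list()   # each: i, j, sym (bond token or "" for default)
  stack <- integer(0)
  prev <- NA_integer_
  pending <- ""
  ring <- list()    # digit -> list(atom, sym)

  perr <- function(pos, what)
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 pos, substr(smiles, pos, pos), what))

  addAtom <- function(element, aromatic, charge = 0L, hset = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         hset = hset, aromatic = aromatic)
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, sym = pending)
    }
    prev <<- idx
    pending <<- ""
    idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) perr(i, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) perr(i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
          perr(i, "'%' ring closure needs two digits")
        digit <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { digit <- ch; i <- i + 1L }
      if (is.na(prev)) perr(i - 1L, "ring closure with no preceding atom")
      if (!is.null(ring[[digit]])) {
        op <- ring[[digit]]
        sym <- if (nzchar(pending)) pending else op$sym
        if (op$atom == prev) perr(i - 1L, "ring closure to the same atom")
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, sym = sym)
        ring[[digit]] <- NULL
      } else {
        ring[[digit]] <- list(atom = prev, sym = pending)
      }
      pending <- ""
    } else if (ch == "[") {
      close <- i
      while (close <= n && chars[close] != "]") close <- close + 1L
      if (close > n) perr(i, "unterminated bracket atom")
      body <- substr(smiles, i + 1L, close - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[cnosp])(@{0,2})(H[0-9]*)?([+-]+[0-9]*|)(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) perr(i, paste0("malformed bracket atom [", body, "]"))
      elem <- m[3]
      aromatic <- elem %in% c("c", "n", "o", "s", "p")
      if (aromatic) elem <- toupper(elem)
      hpart <- m[5]
      hset <- if (is.na(hpart) || !nzchar(hpart)) 0L
              else if (hpart == "H") 1L else as.integer(substring(hpart, 2))
      cpart <- m[6]
      charge <- 0L
      if (nzchar(cpart)) {
        sign <- if (substr(cpart, 1, 1) == "+") 1L else -1L
        num <- gsub("[+-]", "", cpart)
        charge <- if (nzchar(num)) sign * as.integer(num)
                  else sign * nchar(gsub("[0-9]", "", cpart))
      }
      .elementInfo(elem)  # unsupported-element error
      addAtom(elem, aromatic, charge, hset)
      i <- close + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br", "Si")) { elem <- two; i <- i + 2L }
      else if (ch %in% c("C", "N", "O", "S", "P", "F", "I", "B")) {
        if (ch == "B") perr(i, "boron is outside the supported element set")
        elem <- ch; i <- i + 1L
      } else perr(i, "unknown atom symbol")
      addAtom(elem, FALSE)
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      addAtom(toupper(ch), TRUE); i <- i + 1L
    } else {
      perr(i, "unexpected character")
    }
  }
  if (length(stack)) stop("SMILES parse error: unclosed branch '('")
  if (length(ring)) stop("SMILES parse error: unclosed ring bond(s) ",
                         paste(names(ring), collapse = ", "))
  if (!length(atoms)) stop("SMILES parse error: no atoms")

  at <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    charge   = vapply(atoms, `[[`, 0L, "charge"),
    hset     = vapply(atoms, `[[`, NA_integer_, "hset"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    stringsAsFactors = FALSE)

  if (length(bonds)) {
    bd <- data.frame(
      i = vapply(bonds, `[[`, 0L, "i"),
      j = vapply(bonds, `[[`, 0L, "j"),
      sym = vapply(bonds, `[[`, "", "sym"),
      stringsAsFactors = FALSE)
    key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
    if (anyDuplicated(key)) stop("SMILES parse error: duplicate bond")
  } else {
    bd <- data.frame(i = integer(0), j = integer(0), sym = character(0),
                     stringsAsFactors = FALSE)
  }

  .finishGraph(at, bd, smiles)
}

# Resolve bond orders, implicit hydrogens and aromaticity; validate valence.
.finishGraph <- function(at, bd, smiles) {
  nA <- nrow(at)
  order <- rep(1, nrow(bd))
  order[bd$sym == "="] <- 2
  order[bd$sym == "#"] <- 3
  order[bd$sym == ":"] <- 1.5
  # default bond between two lowercase-aromatic atoms: aromatic if it lies on
  # a cycle (not a bridge) -- the biphenyl inter-ring bond stays single
  cand <- which(bd$sym == "" & at$aromatic[bd$i] & at$aromatic[bd$j])
  if (length(cand)) {
    g <- igraph::graph_from_edgelist(cbind(bd$i, bd$j), directed = FALSE)
    if (nA > igraph::vcount(g)) g <- igraph::add_vertices(g, nA - igraph::vcount(g))
    br <- igraph::bridges(g)
    isBridge <- rep(FALSE, nrow(bd))
    isBridge[as.integer(br)] <- TRUE
    order[cand[!isBridge[cand]]] <- 1.5
  }
  bd$order <- order; bd$sym <- NULL

  # implicit hydrogens (hydrogen-suppressed graph):
  #  - bracket atoms: explicit H count
  #  - plain non-aromatic atoms: fill to the smallest normal valence that
  #    accommodates the explicit bonds (S: 2/4/6, P: 3/5)
  #  - plain aromatic C: 4 - degree - 1 (one electron held by the pi system)
  #  - plain aromatic N/O/S/P: 0 (pyrrole-type NH must be written [nH])
  bsum <- numeric(nA); deg <- integer(nA)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    bsum[bd$i[k]] <- bsum[bd$i[k]] + bd$order[k]
    bsum[bd$j[k]] <- bsum[bd$j[k]] + bd$order[k]
    deg[bd$i[k]] <- deg[bd$i[k]] + 1L
    deg[bd$j[k]] <- deg[bd$j[k]] + 1L
  }
  normalVal <- list(C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
                    F = 1, Cl = 1, Br = 1, I = 1, Si = 4, H = 1)
  h <- integer(nA)
  for (a in seq_len(nA)) {
    el <- at$element[a]
    use <- as.integer(ceiling(bsum[a]))
    if (!is.na(at$hset[a])) {
      h[a] <- at$hset[a]
    } else if (at$aromatic[a]) {
      h[a] <- if (el == "C") max(0L, 3L - deg[a]) else 0L
    } else {
      vs <- normalVal[[el]] - at$charge[a] * as.integer(el == "O") +
            at$charge[a] * as.integer(el %in% c("N", "P"))
      fit <- vs[vs >= use]
      if (!length(fit))
        stop(sprintf("valence error: atom %d (%s) has explicit bonded valence %d exceeding %d",
                     a, el, use, max(vs)))
      h[a] <- as.integer(fit[1] - use)
    }
  }
  # bracket atoms: verify the stated H count fits an allowed valence
  for (a in which(!is.na(at$hset) & !at$aromatic)) {
    el <- at$element[a]
    use <- as.integer(ceiling(bsum[a])) + h[a]
    vs <- normalVal[[el]] + at$charge[a] * as.integer(el %in% c("N", "P")) -
          at$charge[a] * as.integer(el == "O")
    if (use > max(vs) + abs(at$charge[a]))
      stop(sprintf("valence error: atom %d (%s) has bonded valence %d exceeding %d",
                   a, el, use, as.integer(max(vs))))
  }
  at$hcount <- h; at$hset <- NULL

  g <- new("MolecularGraph", atoms = at, bonds = bd, smiles = smiles)
  g <- .aromatize(g)

  # every aromatic-flagged atom must sit on a ring of aromatic atoms
  ar <- which(g@atoms$aromatic)
  if (length(ar)) {
    abond <- g@bonds[g@bonds$order == 1.5, , drop = FALSE]
    onRing <- unique(c(abond$i, abond$j))
    if (!all(ar %in% onRing))
      stop("SMILES parse error: aromatic atom outside any aromatic ring")
  }
  validObject(g)
  g
}

# Hückel aromatization of Kekulé-written rings: a cycle of 5-7 sp2-capable
# atoms is aromatic when its in-ring pi-electron count is 4n+2. Contributions:
# atom with a double bond to a ring member of the same cycle -> 1; O/S with
# only single ring bonds -> 2 (lone pair); N with only single bonds -> 2
# (pyrrole-type); anything else (sp3 C, exocyclic-double C as in quinones) is
# not sp2-capable and vetoes the ring.
.aromatize <- function(g) {
  at <- g@atoms; bd <- g@bonds
  if (!nrow(bd)) return(g)
  cycles <- .simpleCycles(nrow(at), bd, maxLen = 7L)
  if (!length(cycles)) return(g)
  bondOrder <- function(i, j) {
    k <- which((bd$i == i & bd$j == j) | (bd$i == j & bd$j == i))
    bd$order[k]
  }
  dblPartner <- vector("list", nrow(at))
  for (k in seq_len(nrow(bd))) if (bd$order[k] == 2) {
    dblPartner[[bd$i[k]]] <- c(dblPartner[[bd$i[k]]], bd$j[k])
    dblPartner[[bd$j[k]]] <- c(dblPartner[[bd$j[k]]], bd$i[k])
  }
  aromaticAtoms <- logical(nrow(at))
  aromaticBondKeys <- character(0)
  for (cyc in cycles) {
    if (length(cyc) < 5L) next
    pis <- integer(length(cyc))
    ok <- TRUE
    for (t in seq_along(cyc)) {
      a <- cyc[t]
      el <- at$element[a]
      if (at$aromatic[a]) { pis[t] <- 1L; next }  # already perceived
      if (any(dblPartner[[a]] %in% cyc)) pis[t] <- 1L
      else if (length(dblPartner[[a]])) { ok <- FALSE; break }   # exocyclic C=O etc.
      else if (el %in% c("O", "S")) pis[t] <- 2L
      else if (el %in% c("N", "P")) pis[t] <- 2L
      else { ok <- FALSE; break }                                # saturated C
    }
    if (!ok) next
    npi <- sum(pis)
    if (npi %% 4L == 2L) {
      aromaticAtoms[cyc] <- TRUE
      m <- length(cyc)
      for (t in seq_len(m)) {
        a <- cyc[t]; b <- cyc[if (t == m) 1L else t + 1L]
        aromaticBondKeys <- c(aromaticBondKeys, paste(min(a, b), max(a, b)))
      }
    }
  }
  if (!any(aromaticAtoms)) return(g)
  at$aromatic <- at$aromatic | aromaticAtoms
  key <- paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j))
  bd$order[key %in% aromaticBondKeys] <- 1.5
  new("MolecularGraph", atoms = at, bonds = bd, smiles = g@smiles)
}

# All simple cycles up to maxLen, each reported once (smallest atom first,
# direction fixed). Molecule-sized graphs only.
.simpleCycles <- function(nA, bd, maxLen = 7L) {
  adj <- vector("list", nA)
  for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], bd$j[k])
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], bd$i[k])
  }
  out <- list()
  seen <- character(0)
  path <- integer(maxLen)
  dfs <- function(start, v, depth) {
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        cyc <- path[seq_len(depth)]
        rot <- which.min(cyc)
        cyc2 <- c(cyc[rot:depth], cyc[seq_len(rot - 1L)])
        if (length(cyc2) > 2L && cyc2[2] > cyc2[length(cyc2)])
          cyc2 <- c(cyc2[1], rev(cyc2[-1]))
        k <- paste(cyc2, collapse = ",")
        if (!k %in% seen) { seen <<- c(seen, k); out[[length(out) + 1L]] <<- cyc2 }
      } else if (depth < maxLen && w > start && !w %in% path[seq_len(depth)]) {
        path[depth + 1L] <<- w
        dfs(start, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(nA)) {
    path[1L] <- s
    dfs(s, s, 1L)
  }
  out
}

#' Write a MolecularGraph back to SMILES
#'
#' Depth-first emitter with ring-closure digits; aromatic atoms are written
#' lowercase and aromatic bonds omitted. With `shuffle = TRUE` the traversal
#' order is randomized, producing an alternative valid writing of the same
#' molecule (useful for representation-invariance checks).
#'
#' @param graph a [MolecularGraph-class]
#' @param shuffle randomize atom/branch order (seeded by the caller via
#'   `set.seed`)
#' @return a SMILES string that reparses to an isomorphic graph
#' @export
writeSmiles <- function(graph, shuffle = FALSE) {
  at <- graph@atoms; bd <- graph@bonds
  nA <- nrow(at)
  if (!nA) stop("empty graph")
  adj <- vector("list", nA)
  if (nrow(bd)) for (k in seq_len(nrow(bd))) {
    adj[[bd$i[k]]] <- c(adj[[bd$i[k]]], list(list(to = bd$j[k], order = bd$order[k])))
    adj[[bd$j[k]]] <- c(adj[[bd$j[k]]], list(list(to = bd$i[k], order = bd$order[k])))
  }
  visited <- logical(nA)
  ringBonds <- list(); ringIdx <- 0L

  bondSym <- function(order, i, j) {
    if (order == 2) "="
    else if (order == 3) "#"
    else if (order == 1.5) ""
    else if (at$aromatic[i] && at$aromatic[j]) "-"  # single bond between aromatic atoms
    else ""
  }
  atomTok <- function(a) {
    el <- at$element[a]
    needBracket <- at$charge[a] != 0 ||
      (at$aromatic[a] && el != "C" && at$hcount[a] > 0) ||
      (el %in% c("S", "P") && FALSE)
    sym <- if (at$aromatic[a]) tolower(el) else el
    if (!needBracket) return(sym)
    h <- if (at$hcount[a] == 0) "" else if (at$hcount[a] == 1) "H"
         else paste0("H", at$hcount[a])
    chg <- if (at$charge[a] == 0) ""
           else if (at$charge[a] == 1) "+" else if (at$charge[a] == -1) "-"
           else sprintf("%+d", at$charge[a])
    paste0("[", sym, h, chg, "]")
  }

  closure <- list()       # edge key -> ring digit, once assigned
  openDigit <- new.env()  # atom index (as char) -> pending "symDigit" strings
  starts <- if (shuffle) sample(seq_len(nA)) else seq_len(nA)

  dfsEmit <- function(v, parent) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (shuffle && length(nb) > 1) nb <- nb[sample(length(nb))]
    ringPart <- ""
    childEdges <- list()
    for (e in nb) {
      w <- e$to
      if (!is.na(parent) && w == parent) next
      kk <- paste(min(v, w), max(v, w))
      if (!is.null(closure[[kk]])) next
      if (visited[w]) {
        ringIdx <<- ringIdx + 1L
        dig <- if (ringIdx < 10) as.character(ringIdx) else paste0("%", ringIdx)
        closure[[kk]] <<- dig
        pend <- get0(as.character(w), envir = openDigit, ifnotfound = character(0))
        assign(as.character(w), c(pend, paste0(bondSym(e$order, v, w), dig)),
               envir = openDigit)
        ringPart <- paste0(ringPart, bondSym(e$order, v, w), dig)
      } else {
        childEdges[[length(childEdges) + 1L]] <- e
      }
    }
    childStrs <- character(0)
    for (e in childEdges) {
      w <- e$to
      kk <- paste(min(v, w), max(v, w))
      # w can be reached through a cycle among earlier children, in which
      # case its back edge to v was already registered as a ring closure
      if (visited[w]) next
      childStrs <- c(childStrs, paste0(bondSym(e$order, v, w), dfsEmit(w, v)))
    }
    # pending ring digits for v are appended by descendants during recursion,
    # so fetch them only after all children have been emitted
    mine <- get0(as.character(v), envir = openDigit, ifnotfound = character(0))
    body <- paste0(atomTok(v), paste0(mine, collapse = ""), ringPart)
    if (length(childStrs) > 1)
      body <- paste0(body,
                     paste0("(", childStrs[-length(childStrs)], ")", collapse = ""),
                     childStrs[length(childStrs)])
    else if (length(childStrs) == 1)
      body <- paste0(body, childStrs[1])
    body
  }

  frags <- character(0)
  for (s in starts) if (!visited[s]) frags <- c(frags, dfsEmit(s, NA_integer_))
  paste(frags, collapse = ".")
}

#' @describeIn parseSmiles number of heavy atoms in the graph
#' @param graph a [MolecularGraph-class]
#' @export
atomCount <- function(graph) nrow(graph@atoms)

#' @describeIn parseSmiles number of bonds in the graph
#' @export
bondCount <- function(graph) nrow(graph@bonds)

#' Atom and bond tables of a MolecularGraph
#'
#' Accessors for the atom table (element, charge, implicit H count, aromatic
#' flag) and bond table (i, j, order with 1.5 = aromatic).
#'
#' @param graph a [MolecularGraph-class]
#' @return a data.frame
#' @export
atoms <- function(graph) graph@atoms

#' @rdname atoms
#' @export
bonds <- function(graph) graph@bonds

# igraph view of the heavy-atom skeleton (orders as edge attribute)
.asIgraph <- function(graph) {
  nA <- nrow(graph@atoms)
  if (nrow(graph@bonds)) {
    g <- igraph::graph_from_edgelist(cbind(graph@bonds$i, graph@bonds$j),
                                     directed = FALSE)
    if (nA > igraph::vcount(g)) g <- igraph::add_vertices(g, nA - igraph::vcount(g))
    igraph::E(g)$order <- graph@bonds$order
  } else {
    g <- igraph::make_empty_graph(nA, directed = FALSE)
  }
  g
}

#' Topological distance matrix
#'
#' Pairwise shortest-path distances in bonds between heavy atoms
#' (`Inf` between disconnected fragments).
#'
#' @param graph a [MolecularGraph-class]
#' @return an integer-valued symmetric matrix with zero diagonal
#' @export
distanceMatrix <- function(graph) {
  d <- igraph::distances(.asIgraph(graph))
  dimnames(d) <- NULL
  d
}

#' Nominal molecular weight
#'
#' Integer isotope-free molecular weight (Cl counted as 35), the m/z at which
#' the all-(35)Cl molecular ion [M] is expected in a unit-resolution EI
#' spectrum.
#'
#' @param graph a [MolecularGraph-class]
#' @return integer nominal MW including implicit hydrogens
#' @export
nominalMW <- function(graph) {
  at <- graph@atoms
  sum(.NOMINAL_MASS[at$element]) + sum(at$hcount) * .NOMINAL_MASS[["H"]]
}
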