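#' Synthetic organochlorine dataset generator configuration
#'
#' The generator emulates the statistical shape of a NIST-style
#' organochlorine EI-MS training collection: valence-valid chlorinated
#' molecules (aromatic and aliphatic, with O/N/S-containing functional
#' groups), integer peak intensities on the 0-9999 NIST scale, and a planted
#' structure-class relationship with the chemistry of molecular-ion
#' stability: aromaticity and chlorine substitution stabilize the radical
#' cation (raise the class-1 probability), reactive carbonyl groups
#' destabilize it.
#'
#' Class-1 probability is
#' `plogis(beta[1] + beta[2]*aromaticCfraction + beta[3]*nCl + beta[4]*carbonyl)`,
#' flipped with probability `eps`. The steep default coefficients make the
#' structure-class rule nearly deterministic, so label noise is dominated by
#' the explicit flip rate.
#'
#' @param n number of molecules
#' @param seed RNG seed (all generator randomness derives from it)
#' @param weights named non-negative fragment-grammar weights: `aromatic`
#'   vs `aliphatic` scaffold odds, and inclusion probabilities for
#'   `carbonyl`, `ester`, `amine`, `phenol`, `acidChloride`, `thioether`
#'   substituents
#' @param clProbs probabilities of drawing 1..length(clProbs) chlorine atoms
#' @param beta logistic coefficients (intercept, aromatic-C fraction,
#'   chlorine count, carbonyl flag)
#' @param eps label flip probability in \[0, 0.5)
#' @return validated config list
#' @export
generatorConfig <- function(n = 1500L, seed = 1L,
                            weights = c(aromatic = 0.65, aliphatic = 0.35,
                                        carbonyl = 0.15, ester = 0.15,
                                        amine = 0.15, phenol = 0.20,
                                        acidChloride = 0.08, thioether = 0.08),
                            clProbs = c(0.45, 0.30, 0.15, 0.10),
                            beta = c(-6, 22, 0.5, -18),
                            eps = 0.05) {
  if (n < 1) stop("config error: n must be >= 1")
  if (eps < 0 || eps >= 0.5) stop("config error: eps must lie in [0, 0.5)")
  need <- c("aromatic", "aliphatic", "carbonyl", "ester", "amine", "phenol",
            "acidChloride", "thioether")
  if (!all(need %in% names(weights)))
    stop("config error: weights must name ", paste(need, collapse = ", "))
  if (any(weights < 0) || all(weights == 0))
    stop("config error: weights must be non-negative and not all zero")
  if (weights["aromatic"] + weights["aliphatic"] == 0)
    stop("config error: unsatisfiable grammar, both scaffold weights are zero")
  if (any(clProbs < 0) || sum(clProbs) <= 0)
    stop("config error: invalid chlorine-count distribution")
  if (length(beta) != 4) stop("config error: beta must have 4 coefficients")
  list(n = as.integer(n), seed = as.integer(seed), weights = weights,
       clProbs = clProbs / sum(clProbs), beta = beta, eps = eps)
}

# substituent fragments (written as SMILES branches)
.FRAGMENTS <- c(carbonyl = "C(C)=O", ester = "C(=O)OC", amine = "N(C)C",
                phenol = "O", acidChloride = "C(=O)Cl", thioether = "SC")

# one molecule from the grammar; returns a SMILES string
.genOneMolecule <- function(w, clProbs) {
  aromatic <- runif(1) < w["aromatic"] / (w["aromatic"] + w["aliphatic"])
  groups <- names(.FRAGMENTS)[runif(length(.FRAGMENTS)) < w[names(.FRAGMENTS)]]
  nCl <- sample.int(length(clProbs), 1, prob = clProbs)
  if (aromatic) {
    nSlots <- 4L                       # substitutable ring positions
    if (length(groups) > nSlots - 1L) groups <- sample(groups, nSlots - 1L)
    # optionally one alkyl side chain for size variety
    subs <- c(.FRAGMENTS[groups],
              if (runif(1) < 0.5) strrep("C", sample.int(4, 1)))
    nCl <- min(nCl, nSlots - length(subs))
    if (nCl < 1) { subs <- subs[-length(subs)]; nCl <- 1L }
    subs <- c(subs, rep("Cl", nCl))
    slots <- character(nSlots)
    slots[sample.int(nSlots, length(subs))] <- paste0("(", subs, ")")
    paste0("c1", paste0("c", slots, collapse = ""), "c1")
  } else {
    L <- sample(4:8, 1)
    if (length(groups) > 0) groups <- groups[groups != "phenol"]  # no aryl OH
    cap <- L - 1L
    if (length(groups) > cap - 1L) groups <- sample(groups, cap - 1L)
    nCl <- max(1L, min(nCl, cap - length(groups)))
    subs <- c(.FRAGMENTS[groups], rep("Cl", nCl))
    pos <- sample.int(L - 1L, length(subs))   # keep last chain C bare
    slots <- character(L)
    for (t in seq_along(subs))
      slots[pos[t]] <- paste0(slots[pos[t]], "(", subs[t], ")")
    paste0("C", slots[1],
           paste0(rep("C", L - 1L), slots[-1], collapse = ""))
  }
}

#' Generate valence-valid organochlorine SMILES
#'
#' Draws `config$n` molecules from the fragment grammar. Every molecule
#' parses without valence errors and contains at least one chlorine;
#' scaffold and substituent composition follow the grammar weights.
#'
#' @param config a list from [generatorConfig()]
#' @return character vector of SMILES
#' @export
genMolecules <- function(config = generatorConfig()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  vapply(seq_len(config$n), function(i)
    .genOneMolecule(config$weights, config$clProbs), "")
}

#' Generate a labelled synthetic spectrum dataset
#'
#' Generates molecules, plants the structure-class rule (see
#' [generatorConfig()]), flips labels with probability `eps`, and draws
#' [M] intensities consistent with the criterion-I labels (class 1: uniform
#' 801-9999; class 2: uniform 0-800) plus loosely fragmentation-linked
#' [M-35] intensities. Criterion-II labels are then assigned from the
#' [M-35] intensities.
#'
#' @param config a list from [generatorConfig()]
#' @return data.frame with columns `id`, `smiles`, `m_intensity`,
#'   `m35_intensity`, `class_I`, `class_II`
#' @export
genLabelledDataset <- function(config = generatorConfig()) {
  smiles <- genMolecules(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.deriveSeed(config$seed, 1L))
  b <- config$beta
  n <- config$n
  m <- integer(n); m35 <- integer(n); cls <- integer(n)
  for (i in seq_len(n)) {
    g <- parseSmiles(smiles[i])
    at <- g@atoms
    aromFrac <- sum(at$aromatic & at$element == "C") / nrow(at)
    nCl <- sum(at$element == "Cl")
    carb <- as.numeric(any(estateAtomTypes(g) == "dO"))
    p1 <- plogis(b[1] + b[2] * aromFrac + b[3] * nCl + b[4] * carb)
    c1 <- rbinom(1, 1, p1) == 1
    if (runif(1) < config$eps) c1 <- !c1
    cls[i] <- if (c1) 1L else 2L
    m[i] <- if (c1) sample(801:9999, 1) else sample(0:800, 1)
    # fragmenting ions ([M] class 2) tend to show a strong dechlorination peak
    m35[i] <- if (c1) sample(0:9999, 1)
              else if (runif(1) < 0.7) sample(101:9999, 1) else sample(0:100, 1)
  }
  data.frame(id = sprintf("syn%05d", seq_len(n)), smiles = smiles,
             m_intensity = m, m35_intensity = m35,
             class_I = cls, class_II = assignClass(m35, "II"),
             stringsAsFactors = FALSE)
}

#' Write MSP spectrum fixtures for a labelled dataset
#'
#' One NIST MSP file per record: the molecular-ion peak at the molecule's
#' nominal MW with the stored [M] intensity (omitted when 0), the [M-35]
#' peak at MW-35, and random minor fragment peaks. A base peak of 9999 is
#' guaranteed, so [readMsp()] recovers the stored intensities exactly.
#'
#' @param records data.frame as from [genLabelledDataset()]
#' @param dir output directory (created if needed)
#' @param seed RNG seed for the minor peaks
#' @return invisible character vector of file paths
#' @export
genMspFixtures <- function(records, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paths <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    mw <- nominalMW(parseSmiles(records$smiles[i]))
    mz <- numeric(0); int <- numeric(0)
    if (records$m_intensity[i] > 0) { mz <- mw; int <- records$m_intensity[i] }
    if (records$m35_intensity[i] > 0) { mz <- c(mz, mw - 35); int <- c(int, records$m35_intensity[i]) }
    lo <- 40; hi <- max(lo + 10, mw - 40)
    pool <- setdiff(seq(lo, hi), c(mw, mw - 35))
    minor <- sample(pool, min(sample(3:8, 1), length(pool)))
    minorInt <- sample(10:9000, length(minor), replace = TRUE)
    if (!length(int) || max(c(int, minorInt)) < 9999) minorInt[1] <- 9999
    mz <- c(mz, minor); int <- c(int, minorInt)
    ord <- order(mz)
    path <- file.path(dir, paste0(records$id[i], ".msp"))
    writeLines(c(paste0("Name: ", records$id[i]),
                 paste0("MW: ", mw),
                 paste0("Num Peaks: ", length(mz)),
                 paste(mz[ord], int[ord], sep = " ")),
               path)
    paths[i] <- path
  }
  invisible(paths)
}
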