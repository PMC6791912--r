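#' Default native descriptor set
#'
#' The descriptor names computed natively from the molecular graph: the
#' atom-type E-state aggregates highlighted by sensitivity analysis of
#' molecular-ion classification models (minaasC, nsssN, maxdO, maxaasC,
#' maxsssCH, maxaaCH, minaaCH and kindred aggregates over aromatic-carbon,
#' carbonyl, hydroxyl, ether, chlorine and methyl types), carbon-type counts,
#' bond-order-weighted path counts piPC1-piPC10, Barysz eigenvector
#' descriptors (VE1_Dzm, VE1_DzZ), ETA_Shape_Y, Galvez charge indices
#' GGI1-GGI8, and the simple counts nHBAcc and nHCsatu.
#'
#' @return character vector of descriptor names
#' @export
defaultDescriptorSet <- function() {
  estateTypes <- c("aasC", "aaCH", "sssCH", "sssN", "dO", "sOH", "ssO",
                   "sCl", "sCH3", "dssC")
  c(as.vector(t(outer(c("n", "min", "max"), estateTypes, paste0))),
    "naAromAtom",
    .CARBON_TYPE_NAMES,
    paste0("piPC", 1:10),
    "VE1_Dzm", "VE1_DzZ", "ETA_Shape_Y",
    paste0("GGI", 1:8),
    "nHBAcc", "nHCsatu")
}

#' Compute native descriptors for one molecule
#'
#' @param graph a [MolecularGraph-class]
#' @param descriptors descriptor names to compute (default
#'   [defaultDescriptorSet()]); names of the form `n<type>`, `min<type>`,
#'   `max<type>` are resolved as atom-type E-state aggregates
#' @param emptyAs empty-type policy for E-state aggregates (0 or NA)
#' @return named numeric vector in the requested order
#' @export
computeDescriptors <- function(graph, descriptors = defaultDescriptorSet(),
                               emptyAs = 0) {
  pools <- list()
  value1 <- function(name) {
    if (name %in% .CARBON_TYPE_NAMES) {
      if (is.null(pools$carbon)) pools$carbon <<- carbonTypes(graph)
      return(pools$carbon[[name]])
    }
    if (grepl("^piPC[0-9]+$", name)) {
      if (is.null(pools$pipc)) pools$pipc <<- piPathCounts(graph, 10L)
      return(pools$pipc[[name]])
    }
    if (grepl("^GGI[0-9]+$", name))
      return(galvezChargeIndex(graph, as.integer(sub("GGI", "", name))))
    if (name == "VE1_Dzm") return(baryszVE1(graph, "mass"))
    if (name == "VE1_DzZ") return(baryszVE1(graph, "atomic-number"))
    if (name == "ETA_Shape_Y") return(etaShapeY(graph))
    if (name == "naAromAtom") return(sum(graph@atoms$aromatic))
    if (name %in% c("nHBAcc", "nHCsatu")) {
      if (is.null(pools$simple)) pools$simple <<- simpleCounts(graph)
      return(pools$simple[[name]])
    }
    m <- regmatches(name, regexec("^(n|min|max)([dtas]+[A-Z][A-Za-z0-9]*)$", name))[[1]]
    if (length(m)) {
      if (is.null(pools$estate))
        pools$estate <<- list(S = estateIndices(graph), ty = estateAtomTypes(graph))
      s <- pools$estate$S[pools$estate$ty == m[3]]
      if (m[2] == "n") return(length(s))
      if (!length(s)) return(as.numeric(emptyAs))
      return(if (m[2] == "min") min(s) else max(s))
    }
    stop("unknown native descriptor: ", name)
  }
  out <- vapply(descriptors, value1, 0)
  names(out) <- descriptors
  out
}

#' Build a DescriptorMatrix from SMILES
#'
#' One row per input compound; a molecule that fails to parse (or a
#' descriptor that fails to compute) yields missing values for that row,
#' never a silently dropped row. All rows failing is an error.
#'
#' @param smiles character vector of SMILES
#' @param ids compound ids (default seq-numbered)
#' @param descriptors descriptor names (default [defaultDescriptorSet()])
#' @param emptyAs empty-type policy passed to [computeDescriptors()]
#' @return a [DescriptorMatrix-class] with provenance "native"
#' @export
computeDescriptorMatrix <- function(smiles, ids = NULL,
                                    descriptors = defaultDescriptorSet(),
                                    emptyAs = 0) {
  if (!length(smiles)) stop("empty SMILES list")
  if (is.null(ids)) ids <- paste0("cmpd", seq_along(smiles))
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  vals <- matrix(NA_real_, length(smiles), length(descriptors),
                 dimnames = list(ids, descriptors))
  failed <- character(0)
  for (r in seq_along(smiles)) {
    row <- tryCatch(
      computeDescriptors(parseSmiles(smiles[r]), descriptors, emptyAs),
      error = function(e) { failed <<- c(failed, ids[r]); NULL })
    if (!is.null(row)) vals[r, ] <- row
  }
  if (length(failed) == length(smiles))
    stop("descriptor computation failed for every compound")
  if (length(failed))
    warning("descriptor computation failed for: ", paste(failed, collapse = ", "))
  new("DescriptorMatrix", values = vals,
      provenance = rep("native", ncol(vals)))
}

#' Import an externally computed descriptor table
#'
#' Reads a PaDEL-style CSV (an id column, by default `Name`, followed by
#' numeric descriptor columns). Non-numeric cells become missing values.
#'
#' @param path CSV file path
#' @param idColumn name of the compound-id column
#' @return a [DescriptorMatrix-class] with provenance "imported"
#' @export
importDescriptorCsv <- function(path, idColumn = "Name") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!idColumn %in% names(df))
    stop("descriptor CSV format error: no '", idColumn, "' column in ", path)
  ids <- as.character(df[[idColumn]])
  df[[idColumn]] <- NULL
  vals <- as.matrix(as.data.frame(lapply(df, function(x)
    suppressWarnings(as.numeric(x))), check.names = FALSE))
  if (!ncol(vals)) stop("descriptor CSV format error: no descriptor columns")
  rownames(vals) <- ids
  new("DescriptorMatrix", values = vals,
      provenance = rep("imported", ncol(vals)))
}

#' Export a DescriptorMatrix as PaDEL-compatible CSV
#'
#' First column `Name`, then one column per descriptor.
#'
#' @param dm a [DescriptorMatrix-class]
#' @param path output CSV path
#' @export
exportDescriptorCsv <- function(dm, path) {
  df <- data.frame(Name = rownames(dm@values), dm@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Merge two descriptor matrices on compound id
#'
#' Rows are aligned on shared compound ids; columns are concatenated.
#' Duplicate descriptor names are an error.
#'
#' @param a,b [DescriptorMatrix-class] objects
#' @return a [DescriptorMatrix-class] over the common compounds
#' @export
mergeDescriptors <- function(a, b) {
  common <- intersect(rownames(a@values), rownames(b@values))
  if (!length(common)) stop("no shared compound ids to merge on")
  if (length(intersect(colnames(a@values), colnames(b@values))))
    stop("duplicate descriptor names across matrices")
  new("DescriptorMatrix",
      values = cbind(a@values[common, , drop = FALSE],
                     b@values[common, , drop = FALSE]),
      provenance = c(a@provenance, b@provenance))
}

#' Column subset of a DescriptorMatrix
#'
#' Keeps the named descriptors in the given order, preserving row order.
#'
#' @param dm a [DescriptorMatrix-class]
#' @param columns descriptor names to keep (must all exist; must be non-empty)
#' @return a [DescriptorMatrix-class]
#' @export
subsetDescriptors <- function(dm, columns) {
  if (!length(columns)) stop("empty descriptor selection")
  missing <- setdiff(columns, colnames(dm@values))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  idx <- match(columns, colnames(dm@values))
  new("DescriptorMatrix",
      values = dm@values[, idx, drop = FALSE],
      provenance = dm@provenance[idx])
}

#' @describeIn subsetDescriptors numeric value grid (compounds x descriptors)
#' @export
descriptorValues <- function(dm) dm@values

#' @describeIn subsetDescriptors compound ids (row names)
#' @export
compoundIds <- function(dm) rownames(dm@values)

#' @describeIn subsetDescriptors descriptor names (column names)
#' @export
descriptorNames <- function(dm) colnames(dm@values)

#' @describeIn subsetDescriptors per-column provenance ("native"/"imported")
#' @export
descriptorProvenance <- function(dm) {
  stats::setNames(dm@provenance, colnames(dm@values))
}
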