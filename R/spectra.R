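#' Assign a spectrum class from a peak intensity
#'
#' Binary labeling of an EI-MS spectrum on the NIST intensity scale (base
#' peak = 9999). Criterion I classifies the molecular-ion [M] peak: class 1
#' iff intensity > 800 NIST units, else class 2 (strict inequality; "lower
#' or equal" is class 2). Criterion II classifies the dechlorination [M-35]
#' peak with threshold 100. Class 1 marks a stable ion, class 2 rapid
#' fragmentation.
#'
#' @param intensity integer intensity/ies in NIST units, 0..9999
#' @param criterion "I" ([M], threshold 800) or "II" ([M-35], threshold 100)
#' @param threshold override the criterion's default threshold
#' @return integer vector of classes (1 or 2)
#' @examples
#' assignClass(c(430, 1099, 800), "I")  # 2, 1, 2
#' @export
assignClass <- function(intensity, criterion = c("I", "II"), threshold = NULL) {
  criterion <- match.arg(criterion)
  if (any(!is.finite(intensity)) || any(intensity < 0) || any(intensity > 9999))
    stop("intensity out of range: NIST units must lie in [0, 9999]")
  if (is.null(threshold)) threshold <- if (criterion == "I") 800 else 100
  ifelse(intensity > threshold, 1L, 2L)
}

#' Rescale spectrum intensities to NIST units
#'
#' Multiplies intensities by 9999/max and rounds half-up so the base peak
#' maps to exactly 9999. Idempotent on already-scaled spectra.
#'
#' @param intensities numeric vector with at least one strictly positive
#'   value
#' @return integer vector on the 0..9999 scale
#' @export
rescaleToNist <- function(intensities) {
  if (!length(intensities) || all(intensities <= 0))
    stop("all-zero spectrum: cannot rescale to NIST units")
  as.integer(roundHalfUp(intensities * 9999 / max(intensities)))
}

#' Read a NIST MSP spectrum and extract [M] / [M-35] intensities
#'
#' Parses a single-spectrum NIST MSP text file (Name:, optional MW:,
#' Num Peaks:, then m/z-intensity pairs separated by ';' or whitespace),
#' rescales the peak list to NIST units, and reports the intensity at the
#' nominal molecular weight ([M], 0 if no peak within +/- 0.5 m/z) and at
#' MW - 35 ([M-35], loss of one (35)Cl).
#'
#' @param path MSP file path
#' @param nominalMW integer nominal molecular weight; defaults to the file's
#'   `MW:` header
#' @return list with `name`, `mw`, `peaks` (data.frame mz/intensity in NIST
#'   units), `m` and `m35` intensities
#' @export
readMsp <- function(path, nominalMW = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit)) trimws(sub("^[^:]*:", "", hit[1])) else NA_character_
  }
  name <- header("Name")
  mwHeader <- suppressWarnings(as.numeric(header("MW")))
  npk <- suppressWarnings(as.integer(header("Num Peaks")))
  if (is.na(npk)) stop("MSP format error: missing 'Num Peaks:' header in ", path)
  if (is.null(nominalMW)) {
    if (is.na(mwHeader)) stop("MSP format error: no MW header and no nominalMW given")
    nominalMW <- mwHeader
  }
  start <- grep("^Num Peaks:", lines, ignore.case = TRUE)[1] + 1L
  body <- paste(lines[seq(start, length(lines))], collapse = " ")
  tok <- strsplit(gsub(";", " ", body), "[[:space:]]+")[[1]]
  tok <- tok[nzchar(tok)]
  nums <- suppressWarnings(as.numeric(tok))
  if (any(is.na(nums)) || length(nums) %% 2L != 0L)
    stop("MSP format error: malformed peak list in ", path)
  mz <- nums[seq(1, length(nums), 2)]
  int <- nums[seq(2, length(nums), 2)]
  if (length(mz) != npk)
    stop(sprintf("MSP format error: header declares %d peaks but %d found in %s",
                 npk, length(mz), path))
  int <- rescaleToNist(int)
  m <- {
    hit <- which(abs(mz - nominalMW) <= 0.5)
    if (length(hit)) as.integer(max(int[hit])) else 0L
  }
  m35 <- {
    hit <- which(abs(mz - (nominalMW - 35)) <= 0.5)
    if (length(hit)) as.integer(max(int[hit])) else 0L
  }
  list(name = name, mw = nominalMW,
       peaks = data.frame(mz = mz, intensity = int),
       m = m, m35 = m35)
}

#' Filter descriptor columns by completeness and variance
#'
#' Implements the information-content filter applied before network
#' building: a column is dropped when it is not computable for every
#' compound (any missing value) or when its sample variance is at or below
#' the threshold. Column order is preserved.
#'
#' @param dm a [DescriptorMatrix-class]
#' @param threshold variance threshold (default 0.001; strictly greater
#'   survives)
#' @return character vector of retained column names
#' @export
varianceFilter <- function(dm, threshold = 0.001) {
  v <- dm@values
  if (!nrow(v) || !ncol(v)) stop("empty descriptor matrix")
  keep <- vapply(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    !anyNA(col) && stats::var(col) > threshold
  }, TRUE)
  if (!any(keep)) stop("variance filter dropped every descriptor column")
  colnames(v)[keep]
}

#' Random train/validation/test split
#'
#' Splits compound ids into train/validation/test parts with sizes given by
#' largest-remainder apportionment of the fractions (default 70/15/15),
#' reproducibly for a given seed. With `stratifyOn`, apportionment is done
#' within each label group so the parts have balanced label proportions.
#'
#' @param ids character or integer vector of ids (n >= 3)
#' @param fractions three positive fractions summing to 1
#' @param seed RNG seed for the shuffle
#' @param stratifyOn optional label vector aligned with `ids`
#' @return list with `train`, `validation`, `test` id vectors plus `seed`
#'   and `fractions`
#' @export
splitDataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                         stratifyOn = NULL) {
  n <- length(ids)
  if (n < 3) stop("need at least 3 ids to split")
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  if (anyDuplicated(ids)) stop("ids must be unique")

  apportion <- function(n, fr) {
    raw <- n * fr
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }

  withr_seed <- function(expr) {   # localized RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }

  if (is.null(stratifyOn)) {
    sizes <- apportion(n, fractions)
    shuffled <- withr_seed(sample(ids))
    parts <- list(train = shuffled[seq_len(sizes[1])],
                  validation = shuffled[sizes[1] + seq_len(sizes[2])],
                  test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
  } else {
    if (length(stratifyOn) != n) stop("stratifyOn must align with ids")
    parts <- list(train = ids[0], validation = ids[0], test = ids[0])
    withr_seed({
      for (lv in unique(stratifyOn)) {
        grp <- sample(ids[stratifyOn == lv])
        sz <- apportion(length(grp), fractions)
        parts$train <- c(parts$train, grp[seq_len(sz[1])])
        parts$validation <- c(parts$validation, grp[sz[1] + seq_len(sz[2])])
        parts$test <- c(parts$test, grp[sz[1] + sz[2] + seq_len(sz[3])])
      }
    })
  }
  c(parts, list(seed = seed, fractions = fractions))
}
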