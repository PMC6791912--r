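#' @import methods
#' @importFrom stats var sd rnorm runif rbinom plogis t.test wilcox.test ks.test
#' @importFrom utils read.csv write.csv head
NULL

# Element table for the supported organic set.
#  Z       atomic number
#  Zv      valence electron count of the neutral element
#  quantum principal quantum number of the valence shell (H=1; C..F=2; Si..Cl=3; Br=4; I=5)
#  mass    standard atomic weight
#  valence default (lowest normal) valence used for implicit-H filling
#  maxval  maximum accepted bonded valence before a valence error is raised
.ELEMENTS <- data.frame(
  symbol  = c("H",  "C",  "N",  "O",  "F",  "Si", "P",  "S",  "Cl", "Br", "I"),
  Z       = c(1,    6,    7,    8,    9,    14,   15,   16,   17,   35,   53),
  Zv      = c(1,    4,    5,    6,    7,    4,    5,    6,    7,    7,    7),
  quantum = c(1,    2,    2,    2,    2,    3,    3,    3,    3,    4,    5),
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974, 32.06,
              35.45, 79.904, 126.904),
  valence = c(1,    4,    3,    2,    1,    4,    3,    2,    1,    1,    1),
  maxval  = c(1,    4,    4,    2,    1,    4,    5,    6,    1,    1,    1),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# Integer isotope-free masses for nominal molecular weight (35 for Cl so that
# [M] sits at the all-35Cl isotopologue mass).
.NOMINAL_MASS <- c(H = 1, C = 12, N = 14, O = 16, F = 19, Si = 28, P = 31,
                   S = 32, Cl = 35, Br = 79, I = 127)

.elementInfo <- function(symbol) {
  bad <- setdiff(unique(symbol), rownames(.ELEMENTS))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  .ELEMENTS[symbol, , drop = FALSE]
}

# round-half-up (NIST intensity convention); base round() is round-half-even
roundHalfUp <- function(x) floor(x + 0.5)
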