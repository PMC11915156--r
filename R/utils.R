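# Shared constants and small numeric helpers.

#' The 20-letter amino-acid alphabet used throughout
#'
#' @return Character vector of the 20 standard one-letter residue codes,
#'   alphabetical order.
#' @export
aminoAcidAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Flanking positions of a cysteine-centered window
#'
#' Positions -7..-1 and +1..+7 relative to the central cysteine (position 0).
#'
#' @return Integer vector of length 14.
#' @export
flankPositions <- function() {
  c(-7:-1, 1:7)
}

#' Residue order grouped by physicochemical property
#'
#' Positively charged, negatively charged, polar uncharged, special, then
#' hydrophobic residues; the order used for property-grouped PWM heatmaps.
#'
#' @return Character vector: a permutation of [aminoAcidAlphabet()].
#' @export
aminoAcidPropertyOrder <- function() {
  c("K", "R", "H",                # positively charged
    "D", "E",                     # negatively charged
    "S", "T", "N", "Q",           # polar uncharged
    "C", "G", "P",                # special
    "A", "V", "I", "L", "M", "F", "W", "Y")  # hydrophobic/aromatic
}

# Monoisotopic masses of the elements appearing in common adduct formulas (Da).
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Monoisotopic mass of a molecular formula
#'
#' Computes the monoisotopic mass of a simple molecular formula such as
#' `"C6H7NO2"` (the N-ethylmaleimide adduct) from standard atomic masses.
#'
#' @param formula Character scalar, e.g. `"C6H7NO2"`. Supported elements:
#'   C, H, N, O, S, P.
#' @return Numeric scalar, mass in Da.
#' @examples
#' monoisotopicMass("C6H7NO2")  # NEM adduct, 125.0477
#' @export
monoisotopicMass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(toks, collapse = "")) ||
      nchar(paste(toks, collapse = "")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.MONO_MASS)) stop("unknown element: ", el)
    total <- total + .MONO_MASS[[el]] * n
  }
  total
}

# Equal-variance two-tailed Student's t test that tolerates zero-variance
# groups: t.test() refuses constant data, but identical constant groups are a
# legitimate degenerate case (t = 0, p = 1).
studentT <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2L || ny < 2L) {
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  }
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      return(list(statistic = 0, df = nx + ny - 2, p.value = 1))
    }
    return(list(statistic = sign(d) * Inf, df = nx + ny - 2, p.value = 0))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

# Mean and standard error of the mean.
meanSem <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
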