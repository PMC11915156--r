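# Cysteine-centered sequence windows and pLogo-style exact binomial
# enrichment scoring.
#
# The foreground is a set of 15-mer windows (cysteine fixed at the center,
# flanks -7..+7, '-' padding at protein termini). For residue r at flank
# position j, with k foreground windows carrying r at j out of N windows with
# a non-pad residue at j, and background probability p of r at j, the score
# is the signed -log10 exact binomial tail:
#   k/N >= p : -log10 P(X >= k)   (enrichment, positive)
#   k/N <  p :  log10 P(X <= k)   (depletion, negative)
# with X ~ Binomial(N, p). Significance uses a Bonferroni bound over the
# 20 x 14 cells of the logo.

.PAD <- "-"

#' Extract a cysteine-centered 15-mer window
#'
#' @param db Protein database ([readProteinFasta()] / `AAStringSet`).
#' @param accession Protein accession.
#' @param position 1-based protein coordinate; the residue there must be 'C'.
#' @param flank Flank width (default 7, giving 15-mers).
#' @return Character scalar of length \code{2 * flank + 1}; positions beyond
#'   the protein termini are padded with \code{"-"}.
#' @examples
#' db <- Biostrings::AAStringSet(c(P1 = "MACDEFKG"))
#' extractWindow(db, "P1", 3)  # "-----MACDEFKG--"
#' @export
extractWindow <- function(db, accession, position, flank = 7L) {
  if (!accession %in% names(db)) stop("accession not in database: ", accession)
  seq <- as.character(db[[accession]])
  position <- as.integer(position)
  if (position < 1L || position > nchar(seq) ||
      substr(seq, position, position) != "C") {
    stop("residue at ", accession, ":", position, " is not a cysteine")
  }
  idx <- (position - flank):(position + flank)
  chars <- rep(.PAD, length(idx))
  ok <- idx >= 1L & idx <= nchar(seq)
  chars[ok] <- strsplit(substr(seq, max(1L, position - flank),
                               min(nchar(seq), position + flank)), "")[[1]]
  paste(chars, collapse = "")
}

#' Extract windows for a table of sites
#'
#' @param db Protein database.
#' @param sites data.frame with columns \code{accession}, \code{position}.
#' @param flank Flank width (default 7).
#' @return Character vector of windows, parallel to the rows of \code{sites}.
#' @export
extractWindows <- function(db, sites, flank = 7L) {
  vapply(seq_len(nrow(sites)), function(i) {
    extractWindow(db, sites$accession[i], sites$position[i], flank)
  }, "")
}

# windows (15-mers) -> n x 14 character matrix of flank residues.
.windowFlankMatrix <- function(windows, flank = 7L) {
  wlen <- 2L * flank + 1L
  if (any(nchar(windows) != wlen)) {
    stop("all windows must have length ", wlen)
  }
  m <- do.call(rbind, strsplit(windows, ""))
  center <- flank + 1L
  if (any(m[, center] != "C")) stop("window centers must be 'C'")
  m <- m[, -center, drop = FALSE]
  colnames(m) <- as.character(flankPositions())
  m
}

#' Per-position background residue frequencies
#'
#' Computes background probabilities p(residue, position) over all
#' cysteine-centered windows of a proteome (every cysteine of every protein),
#' or over a supplied window set. Pad characters are excluded from both the
#' numerator and the denominator. Foreground windows are deliberately not
#' subtracted.
#'
#' @param background An `AAStringSet` proteome or a character vector of
#'   15-mer windows.
#' @param flank Flank width (default 7).
#' @param positional If \code{FALSE}, a pooled alternative: the overall
#'   (position-independent) flank residue composition is replicated across
#'   all 14 positions.
#' @return 20 x 14 numeric matrix; each column sums to 1.
#' @export
backgroundFrequencies <- function(background, flank = 7L, positional = TRUE) {
  if (is(background, "AAStringSet") || is(background, "XStringSet")) {
    windows <- proteomeCysWindows(background, flank)
  } else {
    windows <- background
  }
  if (!length(windows)) stop("empty background")
  m <- .windowFlankMatrix(windows, flank)
  alpha <- aminoAcidAlphabet()
  counts <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != .PAD]
    vapply(alpha, function(r) sum(col == r), 1L)
  }, integer(length(alpha)))
  rownames(counts) <- alpha
  colnames(counts) <- colnames(m)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("background has no non-pad residues at position(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  if (!positional) {
    pooled <- rowSums(counts) / sum(counts)
    p <- matrix(pooled, nrow = length(alpha), ncol = ncol(counts),
                dimnames = dimnames(counts))
    return(p)
  }
  sweep(counts, 2, totals, "/")
}

#' All cysteine-centered windows of a proteome
#'
#' @param db An `AAStringSet`.
#' @param flank Flank width (default 7).
#' @return Character vector with one window per cysteine occurrence.
#' @export
proteomeCysWindows <- function(db, flank = 7L) {
  unlist(lapply(names(db), function(acc) {
    seq <- as.character(db[[acc]])
    pos <- gregexpr("C", seq, fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(character(0))
    vapply(pos, function(p) extractWindow(db, acc, p, flank), "")
  }))
}

#' Signed -log10 exact binomial tail score
#'
#' The pLogo enrichment statistic: for \code{k/N >= p} the score is
#' \code{-log10 P(X >= k)} (positive); otherwise \code{log10 P(X <= k)}
#' (negative), with \code{X ~ Binomial(N, p)}. Tails are exact (no normal
#' approximation); log-scale tail evaluation keeps extreme scores accurate.
#'
#' @param k Observed foreground count(s), \code{0 <= k <= N}.
#' @param N Foreground size(s) (windows with a non-pad residue at the
#'   position).
#' @param p Background probability(ies), strictly inside (0, 1).
#' @return Numeric vector of signed scores.
#' @examples
#' plogoScore(5, 5, 0.1)   # P(X >= 5) = 1e-5 -> 5
#' plogoScore(0, 5, 0.1)   # log10(0.9^5) = -0.2288
#' @export
plogoScore <- function(k, N, p) {
  n <- max(length(k), length(N), length(p))
  k <- rep_len(as.numeric(k), n)
  N <- rep_len(as.numeric(N), n)
  p <- rep_len(as.numeric(p), n)
  if (any(p <= 0 | p >= 1)) stop("background probability must be in (0, 1)")
  if (any(k < 0 | k > N)) stop("k must satisfy 0 <= k <= N")
  if (any(N < 1)) stop("N must be >= 1")
  enriched <- k / N >= p
  out <- numeric(n)
  if (any(enriched)) {
    lt <- pbinom(k[enriched] - 1, N[enriched], p[enriched],
                 lower.tail = FALSE, log.p = TRUE)
    out[enriched] <- -lt / log(10)
  }
  if (any(!enriched)) {
    lt <- pbinom(k[!enriched], N[!enriched], p[!enriched], log.p = TRUE)
    out[!enriched] <- lt / log(10)
  }
  out
}

#' Bonferroni significance threshold on the score scale
#'
#' \code{-log10(alpha / (nResidues * nPositions))}. With the defaults
#' (alpha 0.05, 20 residues, 14 positions) this is 3.7477, displayed as 3.75.
#'
#' @param alpha Per-logo significance level in (0, 1); default 0.05.
#' @param nResidues Number of residues (default 20).
#' @param nPositions Number of flank positions (default 14).
#' @return Numeric scalar.
#' @export
significanceThreshold <- function(alpha = 0.05, nResidues = 20L,
                                  nPositions = 14L) {
  stopifnot(alpha > 0, alpha <= 1, nResidues >= 1, nPositions >= 1)
  -log10(alpha / (nResidues * nPositions))
}

#' Build the pLogo PWM for a foreground window set
#'
#' Counts foreground residues per flank position (pads excluded) and scores
#' every (residue, position) cell against the background with
#' [plogoScore()]. Cells whose background probability is degenerate (0 or 1)
#' cannot be scored by a binomial tail: a never-seen background residue
#' scores \code{Inf} when observed and 0 when absent, and symmetrically for
#' probability 1.
#'
#' @param foreground Character vector of 15-mer windows, or a list with
#'   \code{db} and \code{sites} to extract them.
#' @param background 20 x 14 probability matrix from
#'   [backgroundFrequencies()], or an `AAStringSet`/window vector to derive
#'   one from.
#' @param alpha Per-logo significance level (default 0.05).
#' @param threshold Explicit score threshold; overrides the Bonferroni
#'   computation when supplied (the study's printed 3.75 can be given
#'   directly).
#' @param flank Flank width (default 7).
#' @return A [PlogoPwm-class].
#' @export
buildPwm <- function(foreground, background, alpha = 0.05, threshold = NULL,
                     flank = 7L) {
  if (!is.character(foreground)) {
    stop("foreground must be a character vector of windows")
  }
  if (!is.matrix(background)) {
    background <- backgroundFrequencies(background, flank)
  }
  alphabet <- aminoAcidAlphabet()
  stopifnot(identical(rownames(background), alphabet),
            ncol(background) == 2L * flank)
  m <- .windowFlankMatrix(foreground, flank)
  counts <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != .PAD]
    vapply(alphabet, function(r) sum(col == r), 1L)
  }, integer(length(alphabet)))
  rownames(counts) <- alphabet
  colnames(counts) <- colnames(m)
  nFg <- colSums(counts)
  scores <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    if (nFg[j] == 0L) next
    p <- background[, j]
    ok <- p > 0 & p < 1
    scores[ok, j] <- plogoScore(counts[ok, j], nFg[j], p[ok])
    scores[!ok & p == 0, j] <- ifelse(counts[!ok & p == 0, j] > 0, Inf, 0)
    scores[!ok & p == 1, j] <- ifelse(counts[!ok & p == 1, j] < nFg[j], -Inf, 0)
  }
  thr <- threshold %||% significanceThreshold(alpha, length(alphabet),
                                              ncol(counts))
  new("PlogoPwm", scores = scores, counts = counts,
      nForeground = as.integer(nFg), background = background,
      threshold = thr, nWindows = length(foreground))
}

#' Reorder a PWM score matrix by residue property groups
#'
#' Rows are reordered for heatmap rendering; values are unchanged.
#'
#' @param pwm A [PlogoPwm-class] or a 20 x 14 score matrix.
#' @param residueOrder Permutation of the 20-letter alphabet; default
#'   [aminoAcidPropertyOrder()].
#' @return Matrix with rows in \code{residueOrder}.
#' @export
pwmHeatmapMatrix <- function(pwm, residueOrder = aminoAcidPropertyOrder()) {
  scores <- if (is(pwm, "PlogoPwm")) pwmScores(pwm) else pwm
  if (!setequal(residueOrder, aminoAcidAlphabet()) ||
      length(residueOrder) != 20L) {
    stop("residueOrder must be a permutation of the 20-letter alphabet")
  }
  scores[residueOrder, , drop = FALSE]
}

#' Family-wise error of the logo under the null, by simulation
#'
#' Draws foreground window sets from the background distribution and records
#' the fraction of simulated logos containing at least one cell at or above
#' the significance threshold. With the Bonferroni threshold this fraction is
#' controlled at \code{alpha} by construction.
#'
#' @param background 20 x 14 probability matrix.
#' @param nWindows Foreground windows per simulated logo.
#' @param nReps Number of simulated logos (default 200).
#' @param alpha Per-logo significance level (default 0.05).
#' @param threshold Optional explicit threshold.
#' @return List with \code{fraction} (logos with any significant cell) and
#'   \code{nReps}.
#' @export
simulateNullLogos <- function(background, nWindows, nReps = 200L,
                              alpha = 0.05, threshold = NULL) {
  alphabet <- aminoAcidAlphabet()
  thr <- threshold %||% significanceThreshold(alpha, length(alphabet),
                                              ncol(background))
  hits <- logical(nReps)
  for (r in seq_len(nReps)) {
    cols <- vapply(seq_len(ncol(background)), function(j) {
      sample(alphabet, nWindows, replace = TRUE, prob = background[, j])
    }, character(nWindows))
    windows <- apply(cbind(cols[, 1:7, drop = FALSE], "C",
                           cols[, 8:14, drop = FALSE]), 1, paste,
                     collapse = "")
    pwm <- buildPwm(windows, background, threshold = thr)
    hits[r] <- any(pwmScores(pwm) >= thr)
  }
  list(fraction = mean(hits), nReps = nReps)
}
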