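# S4 classes for the central data objects.

#' ModificationMap: mass-tag to redox-label dictionary
#'
#' Maps variable-modification tokens (by name or by monoisotopic delta mass)
#' to a redox label. In the differential alkylation design, free thiols are
#' blocked with N-ethylmaleimide (NEM, +125.05 Da, label \code{"reduced"}),
#' reversibly oxidized thiols are reduced with TCEP and relabeled with
#' biotin-PEAC5-maleimide (BPM, +548.28 Da, label \code{"oxidized"}), so the
#' tag identity encodes the original redox state of the cysteine.
#'
#' @slot labels Named character vector; values in
#'   \code{c("oxidized", "reduced")}, names are accepted modification tokens.
#' @slot masses Named numeric vector (Da) parallel to \code{labels}; \code{NA}
#'   where a token has no canonical mass (aliases share the mass of the
#'   canonical token).
#' @slot tolerance Numeric scalar, mass-matching tolerance in Da.
#'
#' @exportClass ModificationMap
setClass("ModificationMap",
  representation(labels = "character", masses = "numeric",
                 tolerance = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (is.null(names(object@labels)) || anyNA(names(object@labels)) ||
        any(!nzchar(names(object@labels)))) {
      msg <- c(msg, "every label must be named by a modification token")
    }
    if (anyDuplicated(tolower(names(object@labels)))) {
      msg <- c(msg, "modification token names must be unique (case-insensitive)")
    }
    if (!all(object@labels %in% c("oxidized", "reduced"))) {
      msg <- c(msg, "labels must be 'oxidized' or 'reduced'")
    }
    if (length(object@masses) != length(object@labels)) {
      msg <- c(msg, "masses and labels must be parallel")
    }
    if (length(object@tolerance) != 1L || object@tolerance < 0) {
      msg <- c(msg, "tolerance must be a single non-negative number")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ModificationMap
#'
#' @param labels Named character vector mapping token names to
#'   \code{"oxidized"} / \code{"reduced"}.
#' @param masses Named numeric vector of delta masses (Da), same names;
#'   \code{NA} allowed.
#' @param tolerance Mass match tolerance in Da (default 0.02).
#' @return A [ModificationMap-class] object.
#' @export
ModificationMap <- function(labels, masses = setNames(rep(NA_real_,
                            length(labels)), names(labels)),
                            tolerance = 0.02) {
  new("ModificationMap", labels = labels, masses = masses[names(labels)],
      tolerance = tolerance)
}

#' Default modification map for the NEM/BPM differential alkylation design
#'
#' NEM-type tokens map to \code{"reduced"} (+125.05 Da), BPM-type tokens to
#' \code{"oxidized"} (+548.28 Da). Common spelled-out aliases are included.
#'
#' @return A [ModificationMap-class].
#' @export
defaultModificationMap <- function() {
  labels <- c(
    NEM = "reduced",
    "N-ethylmaleimide" = "reduced",
    "Cysteine N-ethylmaleimide" = "reduced",
    BPM = "oxidized",
    "Biotin-PEAC5-maleimide" = "oxidized",
    "Cysteine Biotin-Peac5-maleimide" = "oxidized"
  )
  masses <- c(
    NEM = 125.05, "N-ethylmaleimide" = 125.05,
    "Cysteine N-ethylmaleimide" = 125.05,
    BPM = 548.28, "Biotin-PEAC5-maleimide" = 548.28,
    "Cysteine Biotin-Peac5-maleimide" = 548.28
  )
  ModificationMap(labels, masses)
}

#' Resolve a modification token to a redox label
#'
#' A token is matched first by name (case-insensitive); a purely numeric token
#' is matched by monoisotopic delta mass within the map's tolerance.
#'
#' @param map A [ModificationMap-class].
#' @param token Character scalar: a modification name or a delta mass.
#' @return \code{"oxidized"}, \code{"reduced"}, or \code{NA_character_} if the
#'   token is not recognised.
#' @export
modificationLabel <- function(map, token) {
  stopifnot(is(map, "ModificationMap"))
  hit <- match(tolower(token), tolower(names(map@labels)))
  if (!is.na(hit)) return(unname(map@labels[hit]))
  mass <- suppressWarnings(as.numeric(token))
  if (!is.na(mass)) {
    d <- abs(map@masses - mass)
    ok <- which(!is.na(d) & d <= map@tolerance)
    if (length(ok)) {
      lab <- unique(unname(map@labels[ok]))
      if (length(lab) == 1L) return(lab)
      stop("mass ", token, " matches tokens of both redox classes")
    }
  }
  NA_character_
}

setMethod("show", "ModificationMap", function(object) {
  cat("ModificationMap with", length(object@labels), "tokens",
      sprintf("(mass tolerance %.3g Da)\n", object@tolerance))
  for (i in seq_along(object@labels)) {
    cat(sprintf("  %-32s -> %-8s %s\n", names(object@labels)[i],
                object@labels[i],
                ifelse(is.na(object@masses[i]), "",
                       sprintf("(+%.2f Da)", object@masses[i]))))
  }
})

.SITE_LABELS <- c("oxidized", "reduced", "unlabeled")
.SITE_COLUMNS <- c("accession", "position", "label", "condition",
                   "replicate", "ambiguous")

#' RedoxSiteSet: per-replicate cysteine site observations
#'
#' The atomic unit of the analysis: one row per distinct
#' (accession, position, label, condition, replicate) observation, where
#' position is the 1-based cysteine coordinate on the protein.
#'
#' @slot observations \code{data.frame} with columns \code{accession}
#'   (character), \code{position} (integer, 1-based), \code{label} (one of
#'   oxidized/reduced/unlabeled), \code{condition} (character),
#'   \code{replicate} (integer >= 1), \code{ambiguous} (logical: peptide
#'   matched the protein at more than one offset).
#' @slot log List of character vectors recording skipped/conflicting PSMs.
#'
#' @exportClass RedoxSiteSet
setClass("RedoxSiteSet",
  representation(observations = "data.frame", log = "list"),
  validity = function(object) {
    df <- object@observations
    msg <- character(0)
    if (!all(.SITE_COLUMNS %in% names(df))) {
      msg <- c(msg, paste("observations must have columns:",
                          paste(.SITE_COLUMNS, collapse = ", ")))
    } else if (nrow(df)) {
      if (!all(df$label %in% .SITE_LABELS)) {
        msg <- c(msg, "labels must be oxidized/reduced/unlabeled")
      }
      if (any(df$position < 1L)) msg <- c(msg, "positions must be >= 1")
      if (any(df$replicate < 1L)) msg <- c(msg, "replicates must be >= 1")
      if (anyDuplicated(df[, c("accession", "position", "label",
                               "condition", "replicate")])) {
        msg <- c(msg, "observations must be deduplicated")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RedoxSiteSet
#'
#' @param observations data.frame of site observations (see
#'   [RedoxSiteSet-class]); an \code{ambiguous} column is added (all
#'   \code{FALSE}) if absent, and duplicate rows are collapsed.
#' @param log Optional list of processing log entries.
#' @return A [RedoxSiteSet-class].
#' @export
RedoxSiteSet <- function(observations, log = list()) {
  if (!"ambiguous" %in% names(observations)) observations$ambiguous <- FALSE
  observations$position <- as.integer(observations$position)
  observations$replicate <- as.integer(observations$replicate)
  key <- c("accession", "position", "label", "condition", "replicate")
  observations <- observations[!duplicated(observations[, key]), , drop = FALSE]
  rownames(observations) <- NULL
  new("RedoxSiteSet", observations = observations, log = log)
}

#' Site observation table of a RedoxSiteSet
#'
#' @param x A [RedoxSiteSet-class].
#' @return The underlying observation \code{data.frame}.
#' @export
siteTable <- function(x) {
  stopifnot(is(x, "RedoxSiteSet"))
  x@observations
}

#' Processing log of a RedoxSiteSet
#'
#' @param x A [RedoxSiteSet-class].
#' @return List of log entries (skipped peptides, label conflicts, ...).
#' @export
siteLog <- function(x) {
  stopifnot(is(x, "RedoxSiteSet"))
  x@log
}

setMethod("show", "RedoxSiteSet", function(object) {
  df <- object@observations
  nsite <- nrow(unique(df[, c("accession", "position")]))
  cat("RedoxSiteSet:", nrow(df), "observations over", nsite,
      "distinct cysteine sites\n")
  if (nrow(df)) {
    cat("  conditions:", paste(sort(unique(df$condition)), collapse = ", "),
        "| replicates:", paste(sort(unique(df$replicate)), collapse = ", "),
        "\n")
    print(table(condition = df$condition, label = df$label))
  }
  if (length(object@log)) {
    cat("  log entries:", paste(names(object@log), vapply(object@log, length,
        1L), sep = "=", collapse = ", "), "\n")
  }
})

#' PlogoPwm: signed binomial enrichment scores for a sequence logo
#'
#' Holds, for each of the 20 residues at each of the 14 flanking positions of
#' a cysteine-centered 15-mer window set, the signed -log10 exact binomial
#' tail probability of the observed foreground count against background
#' residue frequencies (positive = enriched, negative = depleted), together
#' with the counts and the Bonferroni significance threshold.
#'
#' @slot scores 20 x 14 numeric matrix of signed scores (rows: residues,
#'   columns: flank positions "-7".."-1","1".."7").
#' @slot counts 20 x 14 integer matrix of foreground residue counts.
#' @slot nForeground Integer vector (14): windows with a non-pad residue at
#'   each position.
#' @slot background 20 x 14 numeric matrix of background probabilities, each
#'   column summing to 1.
#' @slot threshold Numeric scalar: significance threshold on the score scale.
#' @slot nWindows Integer scalar: number of foreground windows.
#'
#' @exportClass PlogoPwm
setClass("PlogoPwm",
  representation(scores = "matrix", counts = "matrix",
                 nForeground = "integer", background = "matrix",
                 threshold = "numeric", nWindows = "integer"),
  validity = function(object) {
    msg <- character(0)
    dims <- c(20L, 14L)
    for (nm in c("scores", "counts", "background")) {
      if (!identical(dim(slot(object, nm)), dims)) {
        msg <- c(msg, paste(nm, "must be a 20 x 14 matrix"))
      }
    }
    if (length(object@nForeground) != 14L) {
      msg <- c(msg, "nForeground must have length 14")
    }
    if (!length(msg)) {
      if (any(abs(colSums(object@counts) - object@nForeground) > 0)) {
        msg <- c(msg, "column count sums must equal nForeground")
      }
      bg <- colSums(object@background)
      if (any(abs(bg - 1) > 1e-6)) {
        msg <- c(msg, "background columns must sum to 1")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Score matrix of a PlogoPwm
#' @param x A [PlogoPwm-class].
#' @return 20 x 14 numeric matrix of signed scores.
#' @export
pwmScores <- function(x) { stopifnot(is(x, "PlogoPwm")); x@scores }

#' Foreground count matrix of a PlogoPwm
#' @param x A [PlogoPwm-class].
#' @return 20 x 14 integer matrix.
#' @export
pwmCounts <- function(x) { stopifnot(is(x, "PlogoPwm")); x@counts }

#' Significance threshold of a PlogoPwm
#' @param x A [PlogoPwm-class].
#' @return Numeric scalar.
#' @export
pwmThreshold <- function(x) { stopifnot(is(x, "PlogoPwm")); x@threshold }

#' Significantly enriched cells of a PlogoPwm
#'
#' @param x A [PlogoPwm-class].
#' @return data.frame with columns residue, position, count, score for every
#'   cell with score >= threshold (enrichment side only).
#' @export
significantCells <- function(x) {
  stopifnot(is(x, "PlogoPwm"))
  hit <- which(x@scores >= x@threshold, arr.ind = TRUE)
  data.frame(
    residue = rownames(x@scores)[hit[, 1]],
    position = as.integer(colnames(x@scores)[hit[, 2]]),
    count = x@counts[hit],
    score = x@scores[hit],
    stringsAsFactors = FALSE
  )
}

setMethod("show", "PlogoPwm", function(object) {
  cat("PlogoPwm:", object@nWindows, "foreground windows,",
      sprintf("threshold %.2f\n", object@threshold))
  sig <- significantCells(object)
  if (nrow(sig)) {
    cat("  enriched cells:\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %s at %+d (k=%d, score %.2f)\n", sig$residue[i],
                  sig$position[i], sig$count[i], sig$score[i]))
    }
  } else {
    cat("  no significantly enriched cells\n")
  }
})
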