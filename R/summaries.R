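# Subcellular localization join and per-compartment redox percentages.

#' Controlled vocabulary of subcellular compartments
#'
#' @return Character vector of the seven compartment names used in the
#'   summaries.
#' @export
compartmentVocabulary <- function() {
  c("nucleus", "mitochondrion", "cytosol", "endoplasmic reticulum",
    "Golgi apparatus", "plasma membrane", "extracellular space")
}

# UniProt-style term variants normalised onto the controlled vocabulary.
.COMPARTMENT_ALIASES <- c(
  "mitochondria" = "mitochondrion",
  "mitochondrial" = "mitochondrion",
  "nucleus" = "nucleus",
  "nuclear" = "nucleus",
  "cytosol" = "cytosol",
  "cytoplasm" = "cytosol",
  "endoplasmic reticulum" = "endoplasmic reticulum",
  "er" = "endoplasmic reticulum",
  "golgi" = "Golgi apparatus",
  "golgi apparatus" = "Golgi apparatus",
  "plasma membrane" = "plasma membrane",
  "plasm membrane" = "plasma membrane",
  "cell membrane" = "plasma membrane",
  "extracellular space" = "extracellular space",
  "extracellular" = "extracellular space",
  "secreted" = "extracellular space"
)

#' Normalise a compartment name onto the controlled vocabulary
#'
#' @param term Character vector of compartment names (any case, common
#'   UniProt variants accepted).
#' @return Character vector of vocabulary terms; \code{NA} where
#'   unrecognised.
#' @export
normalizeCompartment <- function(term) {
  key <- tolower(trimws(term))
  direct <- match(key, tolower(compartmentVocabulary()))
  out <- compartmentVocabulary()[direct]
  alias <- .COMPARTMENT_ALIASES[key]
  out[is.na(out)] <- unname(alias[is.na(out)])
  out
}

#' Read a subcellular localization table
#'
#' TSV with columns \code{accession} and \code{compartments} (semicolon- or
#' comma-separated list). Terms are normalised onto the controlled
#' vocabulary; unrecognised terms are dropped with a warning.
#'
#' @param path TSV path.
#' @return Long data.frame with columns \code{accession},
#'   \code{compartment}, one row per (protein, compartment).
#' @export
readLocalization <- function(path) {
  if (!file.exists(path)) stop("localization table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("accession", "compartments")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("localization table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    terms <- trimws(strsplit(df$compartments[i], "[;,]")[[1]])
    terms <- terms[nzchar(terms)]
    norm <- normalizeCompartment(terms)
    if (anyNA(norm)) {
      warning("unrecognised compartment term(s) for ", df$accession[i], ": ",
              paste(terms[is.na(norm)], collapse = ", "))
    }
    norm <- unique(norm[!is.na(norm)])
    if (!length(norm)) return(NULL)
    data.frame(accession = df$accession[i], compartment = norm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), compartment = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Join site observations to subcellular compartments
#'
#' A site on a protein annotated to m compartments contributes one record
#' per compartment (multi-localised sites are counted in every compartment).
#' Sites on unannotated proteins are collected separately.
#'
#' @param sites A [RedoxSiteSet-class] or site observation data.frame.
#' @param localization Long data.frame from [readLocalization()].
#' @return data.frame of localized observations (site columns plus
#'   \code{compartment}); the unannotated observations are attached as the
#'   \code{"unannotated"} attribute, and a warning reports their count.
#' @export
joinLocalization <- function(sites, localization) {
  df <- if (is(sites, "RedoxSiteSet")) siteTable(sites) else sites
  merged <- merge(df, localization, by = "accession")
  missing <- df[!df$accession %in% localization$accession, , drop = FALSE]
  if (nrow(missing)) {
    warning(nrow(missing), " observation(s) on ",
            length(unique(missing$accession)),
            " unannotated protein(s) excluded from compartment summaries")
  }
  rownames(merged) <- NULL
  attr(merged, "unannotated") <- missing
  merged
}

#' Per-compartment redox percentages and cold-minus-RT shift
#'
#' Within each compartment, condition and replicate, the percentage of
#' oxidized sites among labeled sites is
#' \code{100 * n_ox / (n_ox + n_red)} over distinct
#' (accession, position, label) observations; unlabeled sites are excluded.
#' Group means with SEM, the equal-variance Student's t test between
#' conditions, and the shift in mean percent oxidized
#' (\code{conditions[2] - conditions[1]}) are reported per compartment. A
#' pooled mode aggregates replicates before computing percentages instead.
#'
#' @param localized data.frame from [joinLocalization()].
#' @param conditions Length-2 character vector (default
#'   \code{c("RT", "Cold")}).
#' @param mode \code{"replicate"} (percentages per replicate, then mean and
#'   SEM; default) or \code{"pooled"}.
#' @return List with \code{perReplicate} (NULL in pooled mode),
#'   \code{summary} (compartment x condition means) and \code{shift}
#'   (per-compartment delta percent oxidized with t test in replicate mode).
#' @export
compartmentPercentages <- function(localized, conditions = c("RT", "Cold"),
                                   mode = c("replicate", "pooled")) {
  mode <- match.arg(mode)
  df <- localized[localized$label %in% c("oxidized", "reduced") &
                  localized$condition %in% conditions, , drop = FALSE]
  if (!nrow(df)) stop("no labeled localized observations")
  pct <- function(sub) {
    sub <- unique(sub[, c("accession", "position", "label")])
    nOx <- sum(sub$label == "oxidized")
    nRed <- sum(sub$label == "reduced")
    c(n_oxidized = nOx, n_reduced = nRed,
      pct_oxidized = 100 * nOx / (nOx + nRed),
      pct_reduced = 100 * nRed / (nOx + nRed))
  }
  if (mode == "pooled") {
    keys <- unique(df[, c("compartment", "condition")])
    summary <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sub <- df[df$compartment == keys$compartment[i] &
                df$condition == keys$condition[i], , drop = FALSE]
      cbind(keys[i, , drop = FALSE], as.data.frame(t(pct(sub))))
    }))
    rownames(summary) <- NULL
    shift <- .compartmentShift(summary, conditions)
    return(list(perReplicate = NULL, summary = summary, shift = shift))
  }
  keys <- unique(df[, c("compartment", "condition", "replicate")])
  keys <- keys[order(keys$compartment, keys$condition, keys$replicate), ]
  perRep <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compartment == keys$compartment[i] &
              df$condition == keys$condition[i] &
              df$replicate == keys$replicate[i], , drop = FALSE]
    cbind(keys[i, , drop = FALSE], as.data.frame(t(pct(sub))))
  }))
  rownames(perRep) <- NULL
  comps <- unique(perRep$compartment)
  summary <- do.call(rbind, lapply(comps, function(cp) {
    do.call(rbind, lapply(conditions, function(cond) {
      x <- perRep$pct_oxidized[perRep$compartment == cp &
                               perRep$condition == cond]
      if (!length(x)) return(NULL)
      ms <- meanSem(x)
      data.frame(compartment = cp, condition = cond,
                 mean_pct_oxidized = ms$mean, sem_pct_oxidized = ms$sem,
                 n_replicates = ms$n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  shift <- do.call(rbind, lapply(comps, function(cp) {
    x <- perRep$pct_oxidized[perRep$compartment == cp &
                             perRep$condition == conditions[1]]
    y <- perRep$pct_oxidized[perRep$compartment == cp &
                             perRep$condition == conditions[2]]
    if (!length(x) || !length(y)) return(NULL)
    tt <- studentT(y, x)
    data.frame(compartment = cp,
               delta_pct_oxidized = mean(y) - mean(x),
               t = tt$statistic, p = tt$p.value, stringsAsFactors = FALSE)
  }))
  rownames(shift) <- NULL
  list(perReplicate = perRep, summary = summary, shift = shift)
}

.compartmentShift <- function(summary, conditions) {
  comps <- unique(summary$compartment)
  out <- do.call(rbind, lapply(comps, function(cp) {
    x <- summary$pct_oxidized[summary$compartment == cp &
                              summary$condition == conditions[1]]
    y <- summary$pct_oxidized[summary$compartment == cp &
                              summary$condition == conditions[2]]
    if (!length(x) || !length(y)) return(NULL)
    data.frame(compartment = cp, delta_pct_oxidized = y - x,
               t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
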