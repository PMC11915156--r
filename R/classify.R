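# Per-replicate redox classification of cysteine sites and percentage
# summaries.

#' Classify every peptide cysteine into a redox state
#'
#' Each cysteine in each PSM is mapped to its protein coordinate and assigned
#' a label from its modification token: NEM-type tags mark originally reduced
#' thiols, BPM-type tags mark reversibly oxidized thiols, and a cysteine
#' without a tag is \code{"unlabeled"}. Duplicate observations of the same
#' (site, label, condition, replicate) from different PSMs collapse to one.
#' A site observed with both labels in the same replicate through different
#' PSMs yields one observation per label; a single residue carrying tokens of
#' both redox classes within one PSM is contradictory and is dropped with a
#' log entry.
#'
#' @param psms List of PSM records ([readPsmTable()]), possibly concatenated
#'   over files.
#' @param db Protein database ([readProteinFasta()]).
#' @param modMap A [ModificationMap-class]; default [defaultModificationMap()].
#' @param dropAmbiguous Drop sites whose peptide matches the protein at more
#'   than one offset (default \code{TRUE}).
#' @return A [RedoxSiteSet-class]. The log records skipped peptides,
#'   conflicting residues, and unrecognised modification tokens.
#' @export
classifySites <- function(psms, db, modMap = defaultModificationMap(),
                          dropAmbiguous = TRUE) {
  skipped <- character(0)
  conflicts <- character(0)
  unknown <- character(0)
  rows <- vector("list", length(psms))
  for (i in seq_along(psms)) {
    rec <- psms[[i]]
    mapped <- mapPeptideToProtein(rec, db)
    if (!nrow(mapped)) {
      reason <- attr(mapped, "reason")
      if (!is.null(reason)) skipped <- c(skipped, reason)
      next
    }
    if (dropAmbiguous && any(mapped$ambiguous)) {
      skipped <- c(skipped, paste0("ambiguous multi-offset match dropped: ",
                                   rec$peptide, " in ", rec$accession))
      next
    }
    mods <- rec$modifications
    perC <- lapply(seq_len(nrow(mapped)), function(j) {
      pidx <- mapped$peptide_index[j]
      toks <- mods$name[mods$index == pidx]
      labs <- character(0)
      for (tok in toks) {
        lab <- modificationLabel(modMap, tok)
        if (is.na(lab)) {
          unknown <<- c(unknown, sprintf("unrecognised token '%s' (%s)",
                                         tok, rec$accession))
        } else {
          labs <- c(labs, lab)
        }
      }
      labs <- unique(labs)
      if (length(labs) > 1L) {
        conflicts <<- c(conflicts,
                        sprintf("%s position %d replicate %d carries both labels in one PSM",
                                mapped$accession[j], mapped$position[j],
                                rec$replicate))
        return(NULL)
      }
      data.frame(accession = mapped$accession[j],
                 position = mapped$position[j],
                 label = if (length(labs)) labs else "unlabeled",
                 condition = rec$condition,
                 replicate = as.integer(rec$replicate),
                 ambiguous = mapped$ambiguous[j],
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, perC)
  }
  obs <- do.call(rbind, rows)
  if (is.null(obs)) {
    obs <- data.frame(accession = character(0), position = integer(0),
                      label = character(0), condition = character(0),
                      replicate = integer(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE)
  }
  RedoxSiteSet(obs, log = list(skipped = skipped, conflicts = conflicts,
                               unknown_tokens = unknown))
}

#' Per-replicate redox percentages with group summaries
#'
#' For each replicate of each condition the numbers of oxidized, reduced and
#' unlabeled cysteine observations (distinct (accession, position, label))
#' are divided by the replicate's total, giving percentages that sum to 100.
#' Group means with SEM and an equal-variance two-tailed Student's t test
#' between the two conditions are computed per category.
#'
#' @param sites A [RedoxSiteSet-class].
#' @param conditions Character vector of length 2 naming the two groups to
#'   compare (default \code{c("RT", "Cold")}).
#' @return List with elements \code{perReplicate} (data.frame: condition,
#'   replicate, n_total and pct per category), \code{groupSummary}
#'   (data.frame: condition, category, mean, sem, n) and \code{tests}
#'   (data.frame: category, t, df, p) comparing \code{conditions[1]} vs
#'   \code{conditions[2]}.
#' @export
percentRedox <- function(sites, conditions = c("RT", "Cold")) {
  df <- siteTable(sites)
  df <- df[df$condition %in% conditions, , drop = FALSE]
  if (!nrow(df)) stop("no observations for conditions: ",
                      paste(conditions, collapse = ", "))
  reps <- unique(df[, c("condition", "replicate")])
  reps <- reps[order(reps$condition, reps$replicate), , drop = FALSE]
  perRep <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    sub <- df[df$condition == reps$condition[i] &
              df$replicate == reps$replicate[i], , drop = FALSE]
    sub <- unique(sub[, c("accession", "position", "label")])
    total <- nrow(sub)
    if (!total) {
      warning("replicate ", reps$replicate[i], " of ", reps$condition[i],
              " has no cysteine observations; excluded")
      return(NULL)
    }
    counts <- vapply(.SITE_LABELS, function(l) sum(sub$label == l), 1L)
    data.frame(condition = reps$condition[i], replicate = reps$replicate[i],
               n_total = total,
               pct_oxidized = 100 * counts[["oxidized"]] / total,
               pct_reduced = 100 * counts[["reduced"]] / total,
               pct_unlabeled = 100 * counts[["unlabeled"]] / total,
               stringsAsFactors = FALSE)
  }))
  cats <- c("pct_oxidized", "pct_reduced", "pct_unlabeled")
  groupSummary <- do.call(rbind, lapply(conditions, function(cond) {
    sub <- perRep[perRep$condition == cond, , drop = FALSE]
    do.call(rbind, lapply(cats, function(cat) {
      ms <- meanSem(sub[[cat]])
      data.frame(condition = cond, category = sub("pct_", "", cat),
                 mean = ms$mean, sem = ms$sem, n = ms$n,
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(cats, function(cat) {
    x <- perRep[[cat]][perRep$condition == conditions[1]]
    y <- perRep[[cat]][perRep$condition == conditions[2]]
    tt <- studentT(x, y)
    data.frame(category = sub("pct_", "", cat), t = tt$statistic,
               df = tt$df, p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(perReplicate = perRep, groupSummary = groupSummary, tests = tests)
}
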