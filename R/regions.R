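# Reproducibility filtering and the four-set Venn region algebra.
#
# A reproducible site carries, per condition, a label subset of
# {oxidized, reduced}; the pair of subsets (RT, Cold), not both empty, takes
# one of 15 realizable patterns, lettered A-O. L, M, N are fixed by their
# published definitions (reduced->oxidized shifts under cold); the remaining
# letters follow a documented canonical order. Scientific meaning is carried
# by the classes, not the letters:
#   dynamic   - both conditions non-empty and label sets differ (6 patterns)
#   reactive  - dynamic, shifted toward oxidation under cold (L, M, N)
#   rt_exclusive / cold_exclusive - detected in one condition only (3 + 3)
#   stable    - same non-empty label set in both conditions (3)

.SET_CODES <- list(none = character(0), ox = "oxidized",
                   red = "reduced", oxred = c("oxidized", "reduced"))

.labelSetCode <- function(labels) {
  labels <- sort(unique(labels))
  if (!length(labels)) return("none")
  if (identical(labels, "oxidized")) return("ox")
  if (identical(labels, "reduced")) return("red")
  if (identical(labels, c("oxidized", "reduced"))) return("oxred")
  stop("labels must be subsets of {oxidized, reduced}: ",
       paste(labels, collapse = ","))
}

#' The 15 realizable redox patterns and their region letters
#'
#' Enumerates every pair of label subsets (RT, Cold), not both empty, with
#' its region letter and classes.
#'
#' @return data.frame with columns \code{region}, \code{rt} and \code{cold}
#'   (set codes \code{none}/\code{ox}/\code{red}/\code{oxred}),
#'   \code{rt_labels}, \code{cold_labels} (comma-joined label strings) and
#'   \code{classes} (comma-joined class memberships).
#' @export
regionPatterns <- function() {
  def <- rbind(
    c("A", "ox",    "none"),
    c("B", "oxred", "none"),
    c("C", "red",   "none"),
    c("D", "ox",    "ox"),
    c("E", "ox",    "red"),
    c("F", "red",   "red"),
    c("G", "oxred", "red"),
    c("H", "oxred", "oxred"),
    c("I", "none",  "ox"),
    c("J", "none",  "oxred"),
    c("K", "none",  "red"),
    c("L", "red",   "ox"),
    c("M", "oxred", "ox"),
    c("N", "red",   "oxred"),
    c("O", "ox",    "oxred")
  )
  df <- data.frame(region = def[, 1], rt = def[, 2], cold = def[, 3],
                   stringsAsFactors = FALSE)
  df$rt_labels <- vapply(df$rt, function(s)
    paste(.SET_CODES[[s]], collapse = ","), "")
  df$cold_labels <- vapply(df$cold, function(s)
    paste(.SET_CODES[[s]], collapse = ","), "")
  df$classes <- mapply(function(rt, cold) {
    paste(.patternClasses(.SET_CODES[[rt]], .SET_CODES[[cold]]),
          collapse = ",")
  }, df$rt, df$cold)
  df
}

.REACTIVE_REGIONS <- c("L", "M", "N")

.patternClasses <- function(rtLabels, coldLabels) {
  rt <- sort(unique(rtLabels))
  cold <- sort(unique(coldLabels))
  if (!length(rt) && !length(cold)) stop("pattern with both conditions empty")
  if (!length(cold)) return("rt_exclusive")
  if (!length(rt)) return("cold_exclusive")
  if (identical(rt, cold)) return("stable")
  classes <- "dynamic"
  # Oxidation-direction shifts: reduced-only at RT moving into oxidation, or
  # a mixed RT state resolving to oxidized under cold.
  if ((identical(rt, "reduced") && identical(cold, "oxidized")) ||
      (identical(rt, c("oxidized", "reduced")) && identical(cold, "oxidized")) ||
      (identical(rt, "reduced") && identical(cold, c("oxidized", "reduced")))) {
    classes <- c(classes, "reactive")
  }
  classes
}

#' Assign a redox pattern to its Venn region
#'
#' @param rtLabels Character vector: labels observed reproducibly at RT
#'   (subset of \code{c("oxidized", "reduced")}; empty vector allowed).
#' @param coldLabels Same for the cold condition. Both empty is an error.
#' @return List with elements \code{region} (letter A-O) and \code{classes}
#'   (character vector, subset of dynamic/reactive/rt_exclusive/
#'   cold_exclusive/stable, with reactive implying dynamic).
#' @examples
#' assignRegion("reduced", "oxidized")  # region L: dynamic, reactive
#' assignRegion("reduced", "reduced")   # region F: stable
#' @export
assignRegion <- function(rtLabels, coldLabels) {
  rtCode <- .labelSetCode(rtLabels)
  coldCode <- .labelSetCode(coldLabels)
  if (rtCode == "none" && coldCode == "none") {
    stop("pattern with both conditions empty is not realizable")
  }
  pat <- regionPatterns()
  hit <- pat$region[pat$rt == rtCode & pat$cold == coldCode]
  list(region = hit,
       classes = .patternClasses(.SET_CODES[[rtCode]], .SET_CODES[[coldCode]]))
}

#' Reproducible cysteine site selection
#'
#' A (site, condition, label) is reproducible when detected in at least
#' \code{minReplicates} replicates of that condition under the same redox
#' category. Unlabeled observations never produce reproducible entries.
#'
#' @param sites A [RedoxSiteSet-class] (or its observation data.frame).
#' @param minReplicates Minimum replicates required (default 2, the
#'   2-of-3 rule).
#' @param dropAmbiguous Exclude observations flagged ambiguous (default
#'   \code{TRUE}).
#' @return data.frame with columns accession, position, condition, label,
#'   n_replicates.
#' @export
reproducibleSites <- function(sites, minReplicates = 2L,
                              dropAmbiguous = TRUE) {
  df <- if (is(sites, "RedoxSiteSet")) siteTable(sites) else sites
  minReplicates <- as.integer(minReplicates)
  if (nrow(df)) {
    nReps <- max(vapply(split(df$replicate, df$condition),
                        function(r) length(unique(r)), 1L))
    if (minReplicates > nReps) {
      stop("minReplicates (", minReplicates, ") exceeds the number of ",
           "replicates present (", nReps, ")")
    }
  }
  if (dropAmbiguous && "ambiguous" %in% names(df)) {
    df <- df[!df$ambiguous, , drop = FALSE]
  }
  df <- df[df$label %in% c("oxidized", "reduced"), , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(accession = character(0), position = integer(0),
                      condition = character(0), label = character(0),
                      n_replicates = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(df$accession, df$position, df$condition, df$label, sep = "\r")
  counts <- vapply(split(df$replicate, key),
                   function(r) length(unique(r)), 1L)
  keep <- names(counts)[counts >= minReplicates]
  if (!length(keep)) {
    return(data.frame(accession = character(0), position = integer(0),
                      condition = character(0), label = character(0),
                      n_replicates = integer(0), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
  out <- data.frame(accession = parts[, 1],
                    position = as.integer(parts[, 2]),
                    condition = parts[, 3], label = parts[, 4],
                    n_replicates = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$position, out$condition, out$label), ]
  rownames(out) <- NULL
  out
}

#' Region assignment for every reproducible site
#'
#' Collects, per (accession, position), the reproducible label sets of the
#' two conditions and assigns the Venn region and classes.
#'
#' @param repro data.frame from [reproducibleSites()].
#' @param conditions Length-2 character vector: the RT-like and Cold-like
#'   condition names (default \code{c("RT", "Cold")}).
#' @return data.frame with columns accession, position, region, classes
#'   (comma-joined), rt_labels, cold_labels.
#' @export
siteRegions <- function(repro, conditions = c("RT", "Cold")) {
  if (!nrow(repro)) {
    return(data.frame(accession = character(0), position = integer(0),
                      region = character(0), classes = character(0),
                      rt_labels = character(0), cold_labels = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(repro$accession, repro$position, sep = "\r")
  out <- do.call(rbind, lapply(split(repro, key), function(sub) {
    rt <- sub$label[sub$condition == conditions[1]]
    cold <- sub$label[sub$condition == conditions[2]]
    a <- assignRegion(rt, cold)
    data.frame(accession = sub$accession[1], position = sub$position[1],
               region = a$region, classes = paste(a$classes, collapse = ","),
               rt_labels = paste(sort(unique(rt)), collapse = ","),
               cold_labels = paste(sort(unique(cold)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$accession, out$position), ]
  rownames(out) <- NULL
  out
}

#' Venn region and class counts
#'
#' Site-level counts partition the reproducible site keys over the 15
#' regions; protein-level counts deduplicate per (protein, region), so a
#' protein with several sites in the same category counts once there.
#'
#' @param assignments data.frame from [siteRegions()].
#' @return List with \code{regions} (named integer, A-O), \code{classes}
#'   (named integer over the five classes), \code{proteins} (named integer:
#'   distinct accessions per region), and \code{nSites}.
#' @export
vennCounts <- function(assignments) {
  letters15 <- regionPatterns()$region
  regions <- setNames(integer(length(letters15)), letters15)
  proteins <- regions
  classes <- setNames(integer(5), c("dynamic", "reactive", "rt_exclusive",
                                    "cold_exclusive", "stable"))
  if (nrow(assignments)) {
    tab <- table(assignments$region)
    regions[names(tab)] <- as.integer(tab)
    ptab <- vapply(split(assignments$accession, assignments$region),
                   function(a) length(unique(a)), 1L)
    proteins[names(ptab)] <- as.integer(ptab)
    cl <- strsplit(assignments$classes, ",", fixed = TRUE)
    for (nm in names(classes)) {
      classes[nm] <- sum(vapply(cl, function(x) nm %in% x, TRUE))
    }
  }
  list(regions = regions, classes = classes, proteins = proteins,
       nSites = nrow(assignments))
}

#' Select the reactive cysteine residues
#'
#' Reactive cysteines are the dynamic sites shifted toward oxidation under
#' cold exposure: regions L (reduced at RT, oxidized under cold), M (reduced
#' and oxidized at RT, oxidized under cold) and N (reduced at RT, reduced and
#' oxidized under cold).
#'
#' @param assignments data.frame from [siteRegions()].
#' @return Subset of \code{assignments} with region in L/M/N, sorted by
#'   region, accession, position.
#' @export
reactiveSites <- function(assignments) {
  out <- assignments[assignments$region %in% .REACTIVE_REGIONS, , drop = FALSE]
  out <- out[order(match(out$region, .REACTIVE_REGIONS), out$accession,
                   out$position), ]
  rownames(out) <- NULL
  out
}

#' Expand a region-lettered site list into reproducible site entries
#'
#' The inverse of [siteRegions()] for curated tables that record only the
#' region letter (such as a published reactive-residue table): each row is
#' expanded into its implied per-condition (site, condition, label) entries.
#'
#' @param df data.frame with columns \code{accession}, \code{position},
#'   \code{region}.
#' @param conditions Length-2 character vector (RT-like, Cold-like).
#' @return data.frame in the shape of [reproducibleSites()] output.
#' @export
expandRegionTable <- function(df, conditions = c("RT", "Cold")) {
  pat <- regionPatterns()
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    p <- pat[pat$region == df$region[i], ]
    if (!nrow(p)) stop("unknown region letter: ", df$region[i])
    entries <- rbind(
      if (length(.SET_CODES[[p$rt]]))
        data.frame(condition = conditions[1], label = .SET_CODES[[p$rt]],
                   stringsAsFactors = FALSE),
      if (length(.SET_CODES[[p$cold]]))
        data.frame(condition = conditions[2], label = .SET_CODES[[p$cold]],
                   stringsAsFactors = FALSE)
    )
    data.frame(accession = df$accession[i], position = df$position[i],
               condition = entries$condition, label = entries$label,
               n_replicates = NA_integer_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
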