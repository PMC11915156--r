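# Truth-annotated synthetic data generator emulating the study design:
# two conditions (RT vs acute cold) x three biological replicates, site-level
# redox labels planted per Venn pattern, flanking-motif plants, and a
# log-normal protein abundance matrix with planted differential proteins.

#' Mouse-proteome-like background residue frequencies
#'
#' Approximate amino-acid composition of a mammalian proteome, used to draw
#' synthetic protein sequences so motif nulls are realistic.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
defaultResidueFrequencies <- function() {
  f <- c(A = 0.0682, C = 0.0230, D = 0.0483, E = 0.0710, F = 0.0365,
         G = 0.0630, H = 0.0261, I = 0.0435, K = 0.0572, L = 0.0998,
         M = 0.0222, N = 0.0359, P = 0.0616, Q = 0.0480, R = 0.0559,
         S = 0.0841, T = 0.0531, V = 0.0605, W = 0.0121, Y = 0.0266)
  f / sum(f)
}

#' Simulation configuration
#'
#' Defaults emulate the study design at desk scale: 3 replicates per
#' condition, an oxidized fraction of reproducible sites near 15% in both
#' conditions with a small dynamic subset (12 dynamic sites of which 7
#' reactive), lysine planted at -1 of reactive sites, acidic residues
#' planted around RT-exclusively-reduced sites, and ~10% differential
#' proteins at 2-fold in the abundance matrix.
#'
#' @param nProteins Number of synthetic proteins.
#' @param proteinLength Length-2 integer range of protein lengths.
#' @param patternCounts Named integer vector over the 15 region letters A-O:
#'   number of planted sites per redox pattern.
#' @param nUnlabeledSites Sites emitted without any modification tag.
#' @param detectionProb Per-replicate detection probability of each planted
#'   (site, label), in (0, 1].
#' @param motifPlants List of plant specs: each a list with \code{regions}
#'   (letters whose sites receive the plant), \code{residue}, \code{offset}
#'   (flank position, -7..7, non-zero), \code{fraction} between 0 and 1.
#' @param residueFreqs Background residue frequencies for sequence drawing.
#' @param nDiffProteins Number of proteins with a planted abundance change.
#' @param log2fcEffect Planted |log2 fold change| (half up, half down).
#' @param abundanceSd Log2-scale intensity noise SD.
#' @param conditions Length-2 condition names (reference first).
#' @param replicates Replicates per condition.
#' @param seed Random seed; a fixed seed gives byte-identical outputs.
#' @return A classed list of validated settings.
#' @export
simulationConfig <- function(nProteins = 300L,
                             proteinLength = c(120L, 400L),
                             patternCounts = c(A = 12L, B = 6L, C = 90L,
                                               D = 6L, E = 2L, F = 95L,
                                               G = 2L, H = 3L, I = 6L,
                                               J = 3L, K = 40L, L = 3L,
                                               M = 2L, N = 2L, O = 1L),
                             nUnlabeledSites = 20L,
                             detectionProb = 0.9,
                             motifPlants = list(
                               list(regions = c("L", "M", "N"),
                                    residue = "K", offset = -1L,
                                    fraction = 0.6),
                               list(regions = "C", residue = "D",
                                    offset = -2L, fraction = 0.5),
                               list(regions = "C", residue = "E",
                                    offset = 2L, fraction = 0.5)),
                             residueFreqs = defaultResidueFrequencies(),
                             nDiffProteins = 30L,
                             log2fcEffect = 1,
                             abundanceSd = 0.2,
                             conditions = c("RT", "Cold"),
                             replicates = 3L,
                             seed = 1L) {
  letters15 <- regionPatterns()$region
  stopifnot(setequal(names(patternCounts), letters15),
            all(patternCounts >= 0),
            detectionProb > 0, detectionProb <= 1,
            length(proteinLength) == 2L,
            proteinLength[1] >= 40L,
            length(conditions) == 2L, replicates >= 1L)
  for (pl in motifPlants) {
    stopifnot(pl$fraction >= 0, pl$fraction <= 1,
              pl$offset %in% setdiff(-7:7, 0),
              pl$residue %in% aminoAcidAlphabet(),
              all(pl$regions %in% letters15))
  }
  residueFreqs <- residueFreqs[aminoAcidAlphabet()]
  stopifnot(!anyNA(residueFreqs), all(residueFreqs > 0))
  structure(list(nProteins = as.integer(nProteins),
                 proteinLength = as.integer(proteinLength),
                 patternCounts = patternCounts[letters15],
                 nUnlabeledSites = as.integer(nUnlabeledSites),
                 detectionProb = detectionProb, motifPlants = motifPlants,
                 residueFreqs = residueFreqs / sum(residueFreqs),
                 nDiffProteins = as.integer(nDiffProteins),
                 log2fcEffect = log2fcEffect, abundanceSd = abundanceSd,
                 conditions = conditions, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "redox_sim_config")
}

# Tryptic peptide (cut after K/R) containing protein position pos.
.trypticSpan <- function(chars, pos) {
  kr <- which(chars == "K" | chars == "R")
  left <- kr[kr < pos]
  start <- if (length(left)) max(left) + 1L else 1L
  right <- kr[kr > pos]
  end <- if (length(right)) min(right) else length(chars)
  c(start = start, end = end)
}

#' Generate a complete synthetic redoxome data bundle
#'
#' Emits, under \code{dir}: \code{proteome.fasta}; one PSM TSV per
#' condition x replicate (\code{psm_<cond>_rep<r>.tsv}); a localization TSV;
#' an abundance TSV with its sample sheet; and \code{truth.json} recording
#' every planted site's pattern and motif plants plus every protein's true
#' log2 fold change. Planted sites sit on tryptic-like peptides (cut after
#' K/R) at least 8 residues long and verified unique in the proteome, so the
#' substring mapping of the I/O layer is exercised without ambiguity.
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{paths} (named file paths) and
#'   \code{truth} (list with \code{sites} and \code{proteins} data.frames).
#' @export
simulateRedoxData <- function(config = simulationConfig(), dir = tempfile()) {
  stopifnot(inherits(config, "redox_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  alpha <- aminoAcidAlphabet()
  freqs <- config$residueFreqs
  nonKRC <- setdiff(alpha, c("K", "R", "C"))
  fNonKRC <- freqs[nonKRC] / sum(freqs[nonKRC])

  lens <- sample(config$proteinLength[1]:config$proteinLength[2],
                 config$nProteins, replace = TRUE)
  accs <- sprintf("SYN%04d", seq_len(config$nProteins))
  seqs <- lapply(lens, function(L) sample(alpha, L, replace = TRUE,
                                          prob = freqs))
  names(seqs) <- accs

  # Site placement: margin 15 from each terminus, spacing 25 within a
  # protein.
  capacity <- pmax(0L, (lens - 30L) %/% 25L + 1L)
  nSites <- sum(config$patternCounts) + config$nUnlabeledSites
  if (nSites > sum(capacity)) {
    stop("infeasible config: ", nSites, " sites exceed the capacity (",
         sum(capacity), ") of ", config$nProteins, " proteins")
  }
  slots <- do.call(rbind, lapply(seq_along(accs), function(i) {
    if (capacity[i] == 0L) return(NULL)
    k <- seq_len(capacity[i])
    data.frame(accession = accs[i],
               position = 15L + (k - 1L) * 25L + sample(0:9, capacity[i],
                                                        replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  # Spread sites across proteins: one slot per protein first, then seconds.
  slots <- slots[order(ave(seq_len(nrow(slots)), slots$accession,
                           FUN = seq_along), sample(nrow(slots))), ]
  sites <- slots[seq_len(nSites), , drop = FALSE]
  pat <- regionPatterns()
  regionOf <- c(rep(pat$region, times = config$patternCounts),
                rep("unlabeled", config$nUnlabeledSites))
  sites$region <- regionOf
  rownames(sites) <- NULL

  # Write the cysteines and sanitise the tryptic context: no K/R (and no
  # stray C) within +/-6 of a planted site, so peptides are >= 8 residues.
  for (i in seq_len(nrow(sites))) {
    ch <- seqs[[sites$accession[i]]]
    pos <- sites$position[i]
    ch[pos] <- "C"
    nb <- setdiff(max(1L, pos - 6L):min(length(ch), pos + 6L), pos)
    bad <- nb[ch[nb] %in% c("K", "R", "C")]
    if (length(bad)) {
      ch[bad] <- sample(nonKRC, length(bad), replace = TRUE, prob = fNonKRC)
    }
    seqs[[sites$accession[i]]] <- ch
  }

  # Motif plants.
  sites$planted_motifs <- ""
  for (pl in config$motifPlants) {
    idx <- which(sites$region %in% pl$regions)
    if (!length(idx)) next
    chosen <- idx[stats::runif(length(idx)) < pl$fraction]
    for (i in chosen) {
      ch <- seqs[[sites$accession[i]]]
      tpos <- sites$position[i] + pl$offset
      if (tpos < 1L || tpos > length(ch)) next
      ch[tpos] <- pl$residue
      seqs[[sites$accession[i]]] <- ch
      tag <- sprintf("%s@%+d", pl$residue, pl$offset)
      sites$planted_motifs[i] <- if (nzchar(sites$planted_motifs[i])) {
        paste(sites$planted_motifs[i], tag, sep = ";")
      } else tag
    }
  }

  # Tryptic peptides; enforce proteome-wide uniqueness by point mutation of
  # a non-site residue inside any colliding peptide.
  peptideOf <- function(i) {
    ch <- seqs[[sites$accession[i]]]
    span <- .trypticSpan(ch, sites$position[i])
    list(pep = paste(ch[span["start"]:span["end"]], collapse = ""),
         start = span[["start"]], end = span[["end"]])
  }
  for (pass in 1:5) {
    blob <- paste(vapply(seqs, paste, "", collapse = ""), collapse = "\n")
    collided <- FALSE
    for (i in seq_len(nrow(sites))) {
      info <- peptideOf(i)
      # stray cysteines inside a site peptide would surface as spurious
      # unlabeled observations; replace them so the unlabeled count is the
      # planted one
      ch <- seqs[[sites$accession[i]]]
      sameProt <- sites$position[sites$accession == sites$accession[i]]
      span <- info$start:info$end
      stray <- span[ch[span] == "C" & !span %in% sameProt]
      if (length(stray)) {
        ch[stray] <- sample(nonKRC, length(stray), replace = TRUE,
                            prob = fNonKRC)
        seqs[[sites$accession[i]]] <- ch
        collided <- TRUE
        next
      }
      hits <- gregexpr(info$pep, blob, fixed = TRUE)[[1]]
      if (length(hits) > 1L) {
        collided <- TRUE
        ch <- seqs[[sites$accession[i]]]
        # keep clear of every planted site (and its motif flanks) on this
        # protein, not just the current one
        sameProt <- sites$position[sites$accession == sites$accession[i]]
        protected <- c(info$end, as.vector(outer(sameProt, -7:7, "+")))
        cand <- setdiff(info$start:info$end, protected)
        if (!length(cand)) cand <- setdiff(info$start:info$end,
                                           c(sites$position[i], info$end))
        j <- cand[sample.int(length(cand), 1L)]
        ch[j] <- sample(c("W", "H", "Y", "F"), 1L)
        seqs[[sites$accession[i]]] <- ch
      }
    }
    if (!collided) break
    if (pass == 5L) stop("could not make all site peptides unique")
  }

  db <- Biostrings::AAStringSet(vapply(seqs, paste, "", collapse = ""))
  fastaPath <- file.path(dir, "proteome.fasta")
  Biostrings::writeXStringSet(db, fastaPath)

  # Per-condition label sets per region letter.
  setList <- list(none = character(0), ox = "oxidized", red = "reduced",
                  oxred = c("oxidized", "reduced"))
  rtLabels <- setNames(lapply(pat$rt, function(s) setList[[s]]), pat$region)
  coldLabels <- setNames(lapply(pat$cold, function(s) setList[[s]]),
                         pat$region)
  tokenOf <- c(oxidized = "BPM", reduced = "NEM")

  psmPaths <- character(0)
  for (ci in 1:2) {
    cond <- config$conditions[ci]
    for (r in seq_len(config$replicates)) {
      rows <- list()
      for (i in seq_len(nrow(sites))) {
        reg <- sites$region[i]
        labs <- if (reg == "unlabeled") {
          "unlabeled"
        } else if (ci == 1L) rtLabels[[reg]] else coldLabels[[reg]]
        if (!length(labs)) next
        info <- peptideOf(i)
        idx <- sites$position[i] - info$start + 1L
        for (lab in labs) {
          if (stats::runif(1) >= config$detectionProb) next
          modCell <- if (lab == "unlabeled") "" else {
            sprintf("C%d(%s)", idx, tokenOf[[lab]])
          }
          rows[[length(rows) + 1L]] <- data.frame(
            peptide = info$pep, accession = sites$accession[i],
            modifications = modCell,
            abundance = round(stats::rlnorm(1, log(1e6), 1), 1),
            stringsAsFactors = FALSE)
        }
      }
      df <- do.call(rbind, rows)
      if (is.null(df)) {
        df <- data.frame(peptide = character(0), accession = character(0),
                         modifications = character(0), abundance = numeric(0))
      }
      p <- file.path(dir, sprintf("psm_%s_rep%d.tsv", cond, r))
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      psmPaths[sprintf("%s_rep%d", cond, r)] <- p
    }
  }

  # Localization: 1-3 compartments per protein.
  vocab <- compartmentVocabulary()
  locPath <- file.path(dir, "localization.tsv")
  nComp <- sample(1:3, config$nProteins, replace = TRUE)
  locDf <- data.frame(
    accession = accs,
    compartments = vapply(nComp, function(k)
      paste(sample(vocab, k), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  write.table(locDf, locPath, sep = "\t", quote = FALSE, row.names = FALSE)

  # Abundance: log-normal intensities, planted differential proteins, and
  # unequal sample loading so total-sum normalization has work to do.
  sampleNames <- as.vector(vapply(config$conditions, function(cond)
    sprintf("%s_%d", cond, seq_len(config$replicates)),
    character(config$replicates)))
  sampleDf <- data.frame(
    sample = sampleNames,
    condition = rep(config$conditions, each = config$replicates),
    replicate = rep(seq_len(config$replicates), times = 2L),
    stringsAsFactors = FALSE)
  trueLfc <- numeric(config$nProteins)
  if (config$nDiffProteins > 0L) {
    diffIdx <- sample.int(config$nProteins, min(config$nDiffProteins,
                                                config$nProteins))
    half <- length(diffIdx) %/% 2L
    trueLfc[diffIdx] <- c(rep(config$log2fcEffect, length(diffIdx) - half),
                          rep(-config$log2fcEffect, half))
  }
  base <- stats::runif(config$nProteins, 18, 24)
  isCold <- sampleDf$condition == config$conditions[2]
  mat <- matrix(0, config$nProteins, length(sampleNames),
                dimnames = list(accs, sampleNames))
  depth <- stats::rlnorm(length(sampleNames), 0, 0.15)
  for (s in seq_along(sampleNames)) {
    mu <- base + if (isCold[s]) trueLfc else 0
    mat[, s] <- 2^(mu + stats::rnorm(config$nProteins, 0,
                                     config$abundanceSd)) * depth[s]
  }
  abPath <- file.path(dir, "abundance.tsv")
  write.table(cbind(data.frame(accession = accs), round(mat, 2)), abPath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  samplePath <- file.path(dir, "samples.tsv")
  write.table(sampleDf, samplePath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  classesOf <- setNames(pat$classes, pat$region)
  truthSites <- data.frame(
    accession = sites$accession, position = sites$position,
    region = sites$region,
    classes = ifelse(sites$region == "unlabeled", "",
                     unname(classesOf[sites$region])),
    rt_labels = ifelse(sites$region == "unlabeled", "",
                       vapply(sites$region, function(g)
                         if (g == "unlabeled") "" else
                           paste(rtLabels[[g]], collapse = ","), "")),
    cold_labels = ifelse(sites$region == "unlabeled", "",
                         vapply(sites$region, function(g)
                           if (g == "unlabeled") "" else
                             paste(coldLabels[[g]], collapse = ","), "")),
    planted_motifs = sites$planted_motifs,
    stringsAsFactors = FALSE)
  truthProteins <- data.frame(accession = accs, true_log2fc = trueLfc,
                              stringsAsFactors = FALSE)
  truth <- list(sites = truthSites, proteins = truthProteins,
                conditions = config$conditions,
                replicates = config$replicates,
                detectionProb = config$detectionProb, seed = config$seed)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truthPath, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)

  paths <- c(list(fasta = fastaPath, localization = locPath,
                  abundance = abPath, samples = samplePath,
                  truth = truthPath),
             as.list(psmPaths))
  invisible(list(paths = paths, truth = truth, config = config))
}

#' Audit a synthetic bundle for truth/file consistency
#'
#' Re-reads the emitted files through the package's own I/O layer and checks
#' that every planted site's position holds a cysteine, that all PSM tables
#' parse without modification-token warnings, and that the abundance matrix
#' matches its sample sheet.
#'
#' @param bundle Return value of [simulateRedoxData()].
#' @return \code{TRUE} invisibly; stops on any inconsistency.
#' @export
auditSimulation <- function(bundle) {
  db <- readProteinFasta(bundle$paths$fasta)
  truth <- bundle$truth
  for (i in seq_len(nrow(truth$sites))) {
    acc <- truth$sites$accession[i]
    pos <- truth$sites$position[i]
    if (substr(as.character(db[[acc]]), pos, pos) != "C") {
      stop("truth site ", acc, ":", pos, " is not a cysteine in the FASTA")
    }
  }
  psmKeys <- grep("_rep", names(bundle$paths), value = TRUE)
  for (key in psmKeys) {
    parts <- strsplit(key, "_rep", fixed = TRUE)[[1]]
    recs <- readPsmTable(bundle$paths[[key]], parts[1],
                         as.integer(parts[2]))
    if (length(attr(recs, "parse_warnings"))) {
      stop("PSM table ", key, " produced parse warnings")
    }
    for (rec in recs) {
      m <- mapPeptideToProtein(rec, db)
      if (!nrow(m)) stop("unmappable peptide in ", key, ": ", rec$peptide)
      if (any(m$ambiguous)) stop("ambiguous peptide in ", key, ": ",
                                 rec$peptide)
    }
  }
  se <- readAbundanceMatrix(bundle$paths$abundance, bundle$paths$samples)
  if (!setequal(rownames(se), truth$proteins$accession)) {
    stop("abundance matrix rows do not match truth proteins")
  }
  loc <- readLocalization(bundle$paths$localization)
  if (!all(loc$accession %in% truth$proteins$accession)) {
    stop("localization table names unknown proteins")
  }
  invisible(TRUE)
}
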