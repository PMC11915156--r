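# Small in-code fixtures shared across the suite.

tinyDb <- function() {
  Biostrings::AAStringSet(c(P001 = "MACDEFKG", P002 = "AAKCCRGGAAKW"))
}

makePsm <- function(peptide, accession,
                    mods = data.frame(index = integer(0),
                                      name = character(0),
                                      stringsAsFactors = FALSE),
                    condition = "RT", replicate = 1L,
                    abundance = NA_real_) {
  list(peptide = peptide, accession = accession, modifications = mods,
       condition = condition, replicate = as.integer(replicate),
       abundance = abundance)
}

modsOf <- function(index, name) {
  data.frame(index = as.integer(index), name = name, stringsAsFactors = FALSE)
}

writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# n distinct site observations with the given label, on synthetic accessions.
makeObs <- function(n, label, condition, replicate, offset = 0L) {
  if (n == 0L) return(NULL)
  data.frame(accession = sprintf("OBS%04d", offset + seq_len(n)),
             position = 10L, label = label, condition = condition,
             replicate = as.integer(replicate), ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

# Replicate-level observation set with planted ox/red/unlabeled counts per
# replicate; counts is a list of c(ox, red, unl) per replicate.
plantedSiteSet <- function(counts, condition, startRep = 1L) {
  rows <- list()
  for (r in seq_along(counts)) {
    k <- counts[[r]]
    rows[[r]] <- rbind(
      makeObs(k[1], "oxidized", condition, startRep + r - 1L, offset = 0L),
      makeObs(k[2], "reduced", condition, startRep + r - 1L, offset = 1000L),
      makeObs(k[3], "unlabeled", condition, startRep + r - 1L,
              offset = 2000L))
  }
  do.call(rbind, rows)
}

# Uniform-ish background probability matrix with a given frequency for one
# residue and the rest spread evenly.
spikedBackground <- function(residue = "K", freq = 0.05) {
  alpha <- aminoAcidAlphabet()
  p <- rep((1 - freq) / (length(alpha) - 1), length(alpha))
  names(p) <- alpha
  p[residue] <- freq
  matrix(p, nrow = length(alpha), ncol = 14,
         dimnames = list(alpha, as.character(flankPositions())))
}

# Draw windows from a background probability matrix; optionally force a
# residue at one flank position for the first nPlant windows.
drawWindows <- function(background, n, plantResidue = NULL,
                        plantOffset = NULL, nPlant = 0L) {
  alpha <- rownames(background)
  cols <- vapply(seq_len(ncol(background)), function(j) {
    sample(alpha, n, replace = TRUE, prob = background[, j])
  }, character(n))
  colnames(cols) <- colnames(background)
  if (nPlant > 0L) {
    cols[seq_len(nPlant), as.character(plantOffset)] <- plantResidue
  }
  apply(cbind(cols[, 1:7, drop = FALSE], "C", cols[, 8:14, drop = FALSE]),
        1, paste, collapse = "")
}
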