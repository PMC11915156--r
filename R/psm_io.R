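# Reading/writing PSM tables, protein FASTA, and site tables; peptide to
# protein coordinate mapping.

.MOD_TOKEN_RE <- "^C([0-9]+)\\(([^()]+)\\)$"

#' Read a per-replicate PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches, one row per
#' identified peptide. Required columns: \code{peptide}, \code{accession},
#' \code{modifications}; optional \code{abundance}. The modification cell is
#' a semicolon-separated list of tokens \code{C<idx>(<name>)}, where
#' \code{<idx>} is the 1-based residue index of the modified cysteine within
#' the peptide and \code{<name>} a modification name or delta mass.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label for every record in the file (e.g.
#'   \code{"RT"} or \code{"Cold"}).
#' @param replicate Integer replicate index (>= 1).
#' @return A list of PSM records (lists with elements \code{peptide},
#'   \code{accession}, \code{modifications} -- a data.frame with columns
#'   \code{index}, \code{name} -- \code{condition}, \code{replicate},
#'   \code{abundance}). Malformed modification tokens are dropped and
#'   collected in the \code{"parse_warnings"} attribute.
#' @export
readPsmTable <- function(path, condition, replicate) {
  stopifnot(length(condition) == 1L, length(replicate) == 1L)
  replicate <- as.integer(replicate)
  if (!file.exists(path)) stop("PSM table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("peptide", "accession", "modifications")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(df)) {
    warning("PSM table ", path, " contains no rows")
    out <- list()
    attr(out, "parse_warnings") <- character(0)
    return(out)
  }
  warnings <- character(0)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pep <- toupper(trimws(df$peptide[i]))
    if (!nzchar(pep)) stop("empty peptide sequence at row ", i, " of ", path)
    cell <- trimws(df$modifications[i])
    mods <- data.frame(index = integer(0), name = character(0),
                       stringsAsFactors = FALSE)
    if (nzchar(cell) && !is.na(cell)) {
      toks <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
      toks <- toks[nzchar(toks)]
      for (tok in toks) {
        m <- regmatches(tok, regexec(.MOD_TOKEN_RE, tok))[[1]]
        if (length(m) != 3L) {
          warnings <- c(warnings, sprintf("row %d: malformed token '%s'", i, tok))
          next
        }
        idx <- as.integer(m[2])
        if (idx < 1L || idx > nchar(pep)) {
          warnings <- c(warnings,
                        sprintf("row %d: token '%s' index outside peptide", i, tok))
          next
        }
        mods <- rbind(mods, data.frame(index = idx, name = m[3],
                                       stringsAsFactors = FALSE))
      }
    }
    ab <- if ("abundance" %in% names(df)) {
      suppressWarnings(as.numeric(df$abundance[i]))
    } else NA_real_
    records[[i]] <- list(peptide = pep, accession = trimws(df$accession[i]),
                         modifications = mods, condition = condition,
                         replicate = replicate, abundance = ab)
  }
  attr(records, "parse_warnings") <- warnings
  records
}

#' Write a PSM table
#'
#' Inverse of [readPsmTable()]: serialises PSM records back to the TSV schema.
#'
#' @param records List of PSM records.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writePsmTable <- function(records, path) {
  rows <- lapply(records, function(r) {
    mods <- r$modifications
    cell <- if (nrow(mods)) {
      paste(sprintf("C%d(%s)", mods$index, mods$name), collapse = ";")
    } else ""
    data.frame(peptide = r$peptide, accession = r$accession,
               modifications = cell,
               abundance = r$abundance %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(peptide = character(0), accession = character(0),
                     modifications = character(0), abundance = numeric(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named sequence set
#'
#' Accession is the first whitespace-delimited token of the header; the
#' UniProt \code{db|ACC|name} dialect is reduced to \code{ACC}.
#'
#' @param path FASTA file path.
#' @return An [Biostrings::AAStringSet] named by accession.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  db <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(db), "[ \t]"), `[`, "", 1L)
  pipe <- grepl("^[A-Za-z]+\\|[^|]+\\|", acc)
  acc[pipe] <- sub("^[A-Za-z]+\\|([^|]+)\\|.*$", "\\1", acc[pipe])
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  if (any(Biostrings::width(db) == 0L)) {
    stop("empty sequence(s) in FASTA: ",
         paste(acc[Biostrings::width(db) == 0L], collapse = ", "))
  }
  names(db) <- acc
  db
}

#' Map the cysteines of a peptide to protein coordinates
#'
#' Performs an exact substring search of the peptide within its stated
#' protein and converts every peptide cysteine to a 1-based protein
#' coordinate. If the peptide occurs at multiple offsets, all occurrences are
#' returned and flagged ambiguous.
#'
#' @param record A PSM record (see [readPsmTable()]).
#' @param db Protein database from [readProteinFasta()].
#' @return data.frame with columns \code{accession}, \code{position}
#'   (protein, 1-based), \code{peptide_index} (1-based index of the C within
#'   the peptide), \code{occurrence}, \code{ambiguous}. Zero rows with a
#'   \code{"reason"} attribute if the peptide cannot be mapped.
#' @examples
#' db <- Biostrings::AAStringSet(c(P001 = "MACDEFKG"))
#' rec <- list(peptide = "ACDEFK", accession = "P001",
#'             modifications = data.frame(index = 2, name = "NEM"),
#'             condition = "RT", replicate = 1)
#' mapPeptideToProtein(rec, db)  # C at peptide index 2 -> protein position 3
#' @export
mapPeptideToProtein <- function(record, db) {
  empty <- data.frame(accession = character(0), position = integer(0),
                      peptide_index = integer(0), occurrence = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  acc <- record$accession
  if (!acc %in% names(db)) {
    attr(empty, "reason") <- paste0("accession not in database: ", acc)
    return(empty)
  }
  protein <- as.character(db[[acc]])
  pep <- record$peptide
  starts <- gregexpr(pep, protein, fixed = TRUE)[[1]]
  if (starts[1] == -1L) {
    attr(empty, "reason") <- paste0("peptide not found in ", acc, ": ", pep)
    return(empty)
  }
  cysIdx <- which(strsplit(pep, "")[[1]] == "C")
  if (!length(cysIdx)) return(empty)
  ambiguous <- length(starts) > 1L
  out <- do.call(rbind, lapply(seq_along(starts), function(k) {
    data.frame(accession = acc,
               position = as.integer(starts[k] - 1L + cysIdx),
               peptide_index = as.integer(cysIdx),
               occurrence = k, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a site table
#'
#' @param sites A [RedoxSiteSet-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSiteTable <- function(sites, path) {
  write.table(siteTable(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [writeSiteTable()]
#'
#' @param path TSV path with columns accession, position, label, condition,
#'   replicate (and optionally ambiguous).
#' @return A [RedoxSiteSet-class].
#' @export
readSiteTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("accession", "position", "label", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("site table missing column(s): ", paste(missing, collapse = ", "))
  }
  RedoxSiteSet(df)
}
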