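# Label-free protein abundance comparison: total-sum normalization, fold
# change, per-protein Student's t tests, volcano table.

#' Read a protein abundance matrix with its sample sheet
#'
#' The abundance TSV has proteins in rows (first column \code{accession})
#' and one column per sample; the sample sheet TSV has columns
#' \code{sample}, \code{condition}, \code{replicate}.
#'
#' @param path Abundance TSV path.
#' @param samplePath Sample sheet TSV path.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"intensity"} and colData columns \code{condition},
#'   \code{replicate}.
#' @export
readAbundanceMatrix <- function(path, samplePath) {
  if (!file.exists(path)) stop("abundance matrix not found: ", path)
  if (!file.exists(samplePath)) stop("sample sheet not found: ", samplePath)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"accession" %in% names(df)) {
    stop("abundance matrix must have an 'accession' column")
  }
  samples <- utils::read.delim(samplePath, stringsAsFactors = FALSE)
  required <- c("sample", "condition", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  }
  missingCols <- setdiff(samples$sample, names(df))
  if (length(missingCols)) {
    stop("abundance matrix lacks sample column(s): ",
         paste(missingCols, collapse = ", "))
  }
  mat <- as.matrix(df[, samples$sample, drop = FALSE])
  rownames(mat) <- df$accession
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities in matrix")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    colData = S4Vectors::DataFrame(condition = samples$condition,
                                   replicate = as.integer(samples$replicate),
                                   row.names = samples$sample))
}

#' Total-sum normalization
#'
#' Scales every sample so that all column totals equal the mean raw column
#' total (total peptide/protein amount normalization).
#'
#' @param se SummarizedExperiment from [readAbundanceMatrix()] (or a plain
#'   matrix).
#' @return Object of the same type with normalized intensities (assay
#'   \code{"normalized"} added when a SummarizedExperiment is given).
#' @export
totalSumNormalize <- function(se) {
  mat <- if (is(se, "SummarizedExperiment")) {
    SummarizedExperiment::assay(se, "intensity")
  } else se
  totals <- colSums(mat, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop("sample(s) with non-positive total intensity: ",
         paste(colnames(mat)[totals <= 0], collapse = ", "))
  }
  norm <- sweep(mat, 2, mean(totals) / totals, "*")
  if (is(se, "SummarizedExperiment")) {
    SummarizedExperiment::assays(se)[["normalized"]] <- norm
    return(se)
  }
  norm
}

#' Volcano table: per-protein fold change and t test
#'
#' On normalized intensities, \code{log2FC = log2(mean_cond2 / mean_cond1)}
#' (cold over RT with the defaults) and an equal-variance two-tailed
#' Student's t test per protein, on log2-transformed intensities by default.
#' A protein with a zero group mean (or, in log scale, any non-positive
#' intensity) has an undefined fold change or test and is flagged
#' \code{excluded}. Significance is \code{p < 0.05} and \code{|log2FC| > 0}.
#'
#' @param se SummarizedExperiment with a \code{"normalized"} assay (run
#'   [totalSumNormalize()] first; falls back to \code{"intensity"} with a
#'   warning).
#' @param conditions Length-2 character vector: reference first (default
#'   \code{c("RT", "Cold")}).
#' @param logScale Run the t test on log2 intensities (default \code{TRUE});
#'   \code{FALSE} tests raw normalized intensities.
#' @param pCutoff Significance cutoff on p (default 0.05).
#' @param lfcCutoff Cutoff on |log2FC| (default 0, i.e. any non-zero change).
#' @return data.frame with columns accession, mean_ref, mean_alt, log2fc, t,
#'   p, significant, excluded.
#' @export
volcanoTable <- function(se, conditions = c("RT", "Cold"), logScale = TRUE,
                         pCutoff = 0.05, lfcCutoff = 0) {
  stopifnot(is(se, "SummarizedExperiment"))
  assays <- SummarizedExperiment::assays(se)
  if ("normalized" %in% names(assays)) {
    mat <- assays[["normalized"]]
  } else {
    warning("no 'normalized' assay; using raw intensities")
    mat <- assays[["intensity"]]
  }
  cond <- SummarizedExperiment::colData(se)$condition
  refIdx <- which(cond == conditions[1])
  altIdx <- which(cond == conditions[2])
  if (length(refIdx) < 2L || length(altIdx) < 2L) {
    stop("need >= 2 replicates per condition")
  }
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    ref <- mat[i, refIdx]
    alt <- mat[i, altIdx]
    mRef <- mean(ref)
    mAlt <- mean(alt)
    excluded <- mRef == 0 || mAlt == 0 ||
      (logScale && any(c(ref, alt) <= 0))
    if (excluded) {
      return(data.frame(accession = rownames(mat)[i], mean_ref = mRef,
                        mean_alt = mAlt, log2fc = NA_real_, t = NA_real_,
                        p = NA_real_, significant = FALSE, excluded = TRUE,
                        stringsAsFactors = FALSE))
    }
    lfc <- log2(mAlt / mRef)
    tt <- if (logScale) studentT(log2(alt), log2(ref)) else studentT(alt, ref)
    sig <- !is.na(tt$p.value) && tt$p.value < pCutoff && abs(lfc) > lfcCutoff
    data.frame(accession = rownames(mat)[i], mean_ref = mRef, mean_alt = mAlt,
               log2fc = lfc, t = tt$statistic, p = tt$p.value,
               significant = sig, excluded = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
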