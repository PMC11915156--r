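# End-to-end orchestration: classify -> percentages -> reproducibility ->
# regions/Venn -> motif -> compartments -> volcano, with a run manifest.

.stageLog <- function(logFile, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

#' Validate and normalise a pipeline run configuration
#'
#' @param config A list, or the path to a YAML file with the same keys:
#'   \code{fasta} (path), \code{psm} (list of entries with \code{path},
#'   \code{condition}, \code{replicate}), optional \code{localization},
#'   optional \code{abundance} + \code{abundanceSamples}, \code{outDir},
#'   and optional \code{minReplicates} (2), \code{alpha} (0.05),
#'   \code{pwmThreshold}, \code{conditions} (RT, Cold),
#'   \code{dropAmbiguous} (TRUE), \code{seed}.
#' @return Validated config list.
#' @export
runConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$minReplicates <- config$minReplicates %||% 2L
  config$alpha <- config$alpha %||% 0.05
  config$conditions <- config$conditions %||% c("RT", "Cold")
  config$dropAmbiguous <- config$dropAmbiguous %||% TRUE
  if (is.null(config$outDir)) stop("config must name an outDir")
  if (is.null(config$fasta)) stop("config must name a fasta")
  if (!file.exists(config$fasta)) stop("FASTA not found: ", config$fasta)
  if (is.null(config$psm) || !length(config$psm)) {
    stop("config must list psm tables")
  }
  for (entry in config$psm) {
    if (is.null(entry$path) || is.null(entry$condition) ||
        is.null(entry$replicate)) {
      stop("each psm entry needs path, condition, replicate")
    }
    if (!file.exists(entry$path)) stop("PSM table not found: ", entry$path)
  }
  for (key in c("localization", "abundance", "abundanceSamples")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop(key, " file not found: ", config[[key]])
    }
  }
  config
}

#' Build a pipeline config from a synthetic bundle
#'
#' @param bundle Return value of [simulateRedoxData()].
#' @param outDir Output directory for the pipeline run.
#' @return Config list for [runRedoxPipeline()].
#' @export
pipelineConfigFromBundle <- function(bundle, outDir) {
  psmKeys <- grep("_rep", names(bundle$paths), value = TRUE)
  psm <- lapply(psmKeys, function(key) {
    parts <- strsplit(key, "_rep", fixed = TRUE)[[1]]
    list(path = bundle$paths[[key]], condition = parts[1],
         replicate = as.integer(parts[2]))
  })
  list(fasta = bundle$paths$fasta, psm = psm,
       localization = bundle$paths$localization,
       abundance = bundle$paths$abundance,
       abundanceSamples = bundle$paths$samples,
       conditions = bundle$truth$conditions, outDir = outDir)
}

#' Run the full redoxome analysis
#'
#' Executes all stages in dependency order and writes every result table
#' plus a manifest (row counts per output) into \code{outDir}. Reruns with
#' an identical config produce identical outputs.
#'
#' @param config List or YAML path (see [runConfig()]).
#' @return Invisibly, a list with the in-memory results and \code{manifest}.
#' @export
runRedoxPipeline <- function(config) {
  config <- runConfig(config)
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  if (!is.null(config$seed)) set.seed(config$seed)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  manifest <- list()
  emit <- function(name, df) {
    path <- file.path(outDir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[name]] <<- nrow(df)
  }
  emitJson <- function(name, obj) {
    jsonlite::write_json(obj, file.path(outDir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest[[name]] <<- length(obj)
  }

  .stageLog(logFile, "io", paste("reading FASTA", config$fasta))
  db <- tryCatch(readProteinFasta(config$fasta),
                 error = function(e) stop("stage io failed: ",
                                          conditionMessage(e)))
  psms <- list()
  for (entry in config$psm) {
    recs <- tryCatch(readPsmTable(entry$path, entry$condition,
                                  entry$replicate),
                     error = function(e) stop("stage io failed: ",
                                              conditionMessage(e)))
    nWarn <- length(attr(recs, "parse_warnings"))
    .stageLog(logFile, "io", sprintf("%s: %d PSMs (%d parse warnings)",
                                     entry$path, length(recs), nWarn))
    psms <- c(psms, recs)
  }

  .stageLog(logFile, "classify", sprintf("%d PSMs total", length(psms)))
  sites <- classifySites(psms, db, dropAmbiguous = config$dropAmbiguous)
  emit("site_table.tsv", siteTable(sites))

  pct <- percentRedox(sites, config$conditions)
  emit("percentages.tsv", pct$perReplicate)
  emitJson("group_summary.json",
           list(groupSummary = pct$groupSummary, tests = pct$tests))

  .stageLog(logFile, "regions",
            sprintf("reproducibility filter (>= %d replicates)",
                    config$minReplicates))
  repro <- reproducibleSites(sites, config$minReplicates)
  regions <- siteRegions(repro, config$conditions)
  emit("regions.tsv", regions)
  venn <- vennCounts(regions)
  emitJson("venn_counts.json", lapply(venn, as.list))
  reactive <- reactiveSites(regions)
  emit("reactive_sites.tsv", reactive)

  dynamic <- regions[grepl("dynamic", regions$classes), , drop = FALSE]
  if (nrow(dynamic)) {
    .stageLog(logFile, "motif", sprintf("%d dynamic site windows",
                                        nrow(dynamic)))
    fg <- extractWindows(db, dynamic)
    bg <- backgroundFrequencies(db)
    pwm <- buildPwm(fg, bg, alpha = config$alpha,
                    threshold = config$pwmThreshold)
    scoresDf <- data.frame(
      residue = rep(rownames(pwmScores(pwm)), times = 14L),
      position = rep(as.integer(colnames(pwmScores(pwm))),
                     each = 20L),
      count = as.vector(pwmCounts(pwm)),
      score = as.vector(pwmScores(pwm)),
      significant = as.vector(pwmScores(pwm) >= pwmThreshold(pwm)))
    emit("pwm_scores.tsv", scoresDf)
    hm <- pwmHeatmapMatrix(pwm)
    emit("pwm_heatmap.tsv", data.frame(residue = rownames(hm), hm,
                                       check.names = FALSE))
  } else {
    .stageLog(logFile, "motif", "no dynamic sites; motif stage skipped")
  }

  compartments <- NULL
  if (!is.null(config$localization)) {
    .stageLog(logFile, "summaries", "compartment percentages")
    loc <- readLocalization(config$localization)
    localized <- suppressWarnings(joinLocalization(sites, loc))
    comp <- compartmentPercentages(localized, config$conditions)
    merged <- merge(comp$summary, comp$shift, by = "compartment",
                    all.x = TRUE)
    emit("compartments.tsv", merged)
    compartments <- comp
  }

  volcano <- NULL
  if (!is.null(config$abundance)) {
    .stageLog(logFile, "abundance", "total-sum normalization and t tests")
    se <- readAbundanceMatrix(config$abundance, config$abundanceSamples)
    se <- totalSumNormalize(se)
    volcano <- volcanoTable(se, config$conditions)
    emit("volcano.tsv", volcano)
  }

  emitJson("manifest.json", manifest)
  .stageLog(logFile, "done", sprintf("%d outputs in %s",
                                     length(manifest), outDir))
  invisible(list(sites = sites, percentages = pct, repro = repro,
                 regions = regions, venn = venn, reactive = reactive,
                 compartments = compartments, volcano = volcano,
                 manifest = manifest, outDir = outDir))
}
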